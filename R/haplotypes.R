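#' Haplotype discovery through LD blocks and local genomic breeding values
#'
#' The marker pipeline: curate the SNP set (minor allele frequency and
#' heterozygosity filters), describe population structure (Rogers'
#' distance, principal coordinates, UPGMA clusters), partition each
#' chromosome into linkage-disequilibrium blocks, call the haplotypes
#' present in each block, estimate all marker effects jointly by
#' ridge-regression BLUP, sum them within blocks into local genomic
#' estimated breeding values (localGEBVs), flag high-variance blocks with a
#' scaled min-max variance threshold, and project haplotype stacking in
#' silico.
#'
#' @name haplotypes
NULL

#' Curate a marker set
#'
#' Removes markers with minor allele frequency less than or equal to
#' \code{maf_max_excl} and markers with a heterozygote fraction greater
#' than \code{het_max}; remaining missing dosages are imputed to the
#' marker mean.
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param maf_max_excl MAF threshold (inclusive removal), default 0.05.
#' @param het_max heterozygosity threshold (exclusive removal), default
#'   0.10.
#' @return curated \code{genotype_matrix}; the curation report (markers
#'   removed by each rule) is attached as attribute \code{"report"}.
#' @export
curate_markers <- function(genotypes, maf_max_excl = 0.05, het_max = 0.10) {
  M <- genotypes$dosage
  p <- colMeans(M, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  het <- colMeans(M == 1, na.rm = TRUE)
  drop_maf <- maf <= maf_max_excl
  drop_het <- het > het_max
  keep <- !(drop_maf | drop_het)
  if (!any(keep)) stopf("curation removed every marker")
  M <- M[, keep, drop = FALSE]
  if (anyNA(M)) {
    mu <- colMeans(M, na.rm = TRUE)
    idx <- which(is.na(M), arr.ind = TRUE)
    M[idx] <- mu[idx[, 2]]
  }
  out <- structure(list(dosage = M,
                        map = genotypes$map[keep, , drop = FALSE]),
                   class = "genotype_matrix")
  attr(out, "report") <- list(n_input = length(keep),
                              removed_maf = sum(drop_maf),
                              removed_het = sum(drop_het & !drop_maf),
                              n_kept = sum(keep))
  out
}

#' Rogers' genetic distance
#'
#' Per locus, the Euclidean distance between the two individuals'
#' allele-frequency vectors scaled by \eqn{1/\sqrt{2}}, averaged over loci;
#' for biallelic dosages d the individual frequency vector is
#' \eqn{(1 - d/2, d/2)}.  Identical individuals are at distance 0 and
#' opposite homozygotes at every locus at distance 1.
#'
#' @param genotypes a \code{genotype_matrix} or dosage matrix.
#' @return a symmetric distance matrix.
#' @export
rogers_distance <- function(genotypes) {
  M <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosage else
    as.matrix(genotypes)
  # per-locus distance |p1 - p2| * sqrt(2) / sqrt(2) = |d1 - d2| / 2
  # (both coordinates of the frequency vector differ by |d1-d2|/2)
  P <- M / 2
  n <- nrow(P)
  D <- matrix(0, n, n, dimnames = list(rownames(M), rownames(M)))
  for (i in seq_len(n - 1)) {
    ji <- (i + 1):n
    D[i, ji] <- D[ji, i] <-
      rowMeans(abs(P[ji, , drop = FALSE] -
                     matrix(P[i, ], length(ji), ncol(P), byrow = TRUE)))
  }
  D
}

#' Population structure: principal coordinates and UPGMA clusters
#'
#' Classical multidimensional scaling of the genetic distance matrix with
#' the percentage of variation per axis, and average-linkage (UPGMA)
#' hierarchical clustering cut at \code{k} clusters.
#'
#' @param distance symmetric distance matrix (e.g.
#'   \code{\link{rogers_distance}}).
#' @param k number of clusters.
#' @param n_axes number of principal coordinates to return.
#' @return list with \code{scores}, \code{pct_var} per axis, \code{cluster}
#'   labels and the \code{hclust} tree.
#' @export
diversity_clusters <- function(distance, k = 3, n_axes = 4) {
  n <- nrow(distance)
  if (k > n) stopf("cannot cut %d genotypes into %d clusters", n, k)
  n_axes <- min(n_axes, n - 1)
  mds <- stats::cmdscale(stats::as.dist(distance), k = n_axes, eig = TRUE)
  pos <- pmax(mds$eig, 0)
  pct <- 100 * pos[seq_len(n_axes)] / sum(pos)
  hc <- stats::hclust(stats::as.dist(distance), method = "average")
  cl <- stats::cutree(hc, k = k)
  list(scores = mds$points, pct_var = pct, cluster = cl, tree = hc)
}

#' Build LD blocks by a greedy anchored scan
#'
#' Within each chromosome, markers are scanned in map order.  The current
#' block extends while the candidate marker's squared dosage correlation
#' with the block anchor (the block's first member) reaches
#' \code{r2_threshold}; up to \code{tolerance} below-threshold markers may
#' be absorbed into a block, and the first marker that would exceed the
#' tolerance opens a new block.  Singleton blocks are allowed and the
#' blocks partition the curated marker set.
#'
#' @param genotypes curated \code{genotype_matrix} with map order.
#' @param r2_threshold LD threshold (default 0.7).
#' @param tolerance below-threshold markers allowed per block (default 2).
#' @return data.frame of blocks (id, chromosome, member index range,
#'   center position, tolerance used); the per-marker block assignment is
#'   attached as attribute \code{"marker_block"}.
#' @export
build_ld_blocks <- function(genotypes, r2_threshold = 0.7, tolerance = 2) {
  map <- genotypes$map
  if (is.null(map) || anyNA(map$pos)) stopf("markers must carry map positions")
  M <- genotypes$dosage
  blocks <- list()
  marker_block <- character(ncol(M))
  bid <- 0L
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    idx <- idx[order(map$pos[idx])]
    anchor <- idx[1]
    members <- anchor
    tol_used <- 0L
    flush <- function(members, tol_used) {
      bid <<- bid + 1L
      id <- sprintf("b%06d", bid)
      blocks[[bid]] <<- data.frame(
        block = id, chrom = ch,
        start_idx = members[1], end_idx = members[length(members)],
        n_markers = length(members),
        start_pos = map$pos[members[1]], end_pos = map$pos[members[length(members)]],
        center_pos = mean(range(map$pos[members])),
        tolerance_used = tol_used, stringsAsFactors = FALSE)
      marker_block[members] <<- id
    }
    for (j in idx[-1]) {
      r2 <- dosage_r2(M[, anchor], M[, j])
      if (r2 >= r2_threshold) {
        members <- c(members, j)
      } else if (tol_used < tolerance) {
        members <- c(members, j)
        tol_used <- tol_used + 1L
      } else {
        flush(members, tol_used)
        anchor <- j
        members <- j
        tol_used <- 0L
      }
    }
    flush(members, tol_used)
  }
  out <- do.call(rbind, blocks)
  attr(out, "marker_block") <- marker_block
  out
}

#' Call haplotypes within LD blocks
#'
#' Per genotype and block, the haplotype is the string of dosage states at
#' the member markers; the distinct strings observed in the panel are
#' enumerated with carrier counts, and strings containing heterozygous
#' calls are flagged.
#'
#' @param genotypes curated \code{genotype_matrix}.
#' @param blocks output of \code{\link{build_ld_blocks}} (or a compatible
#'   block table).
#' @return list with \code{calls} (genotype x block matrix of haplotype
#'   strings) and \code{table} (block, haplotype, carrier count, het flag).
#' @export
call_haplotypes <- function(genotypes, blocks) {
  M <- genotypes$dosage
  calls <- matrix(NA_character_, nrow(M), nrow(blocks),
                  dimnames = list(rownames(M), blocks$block))
  tabs <- list()
  for (b in seq_len(nrow(blocks))) {
    idx <- blocks$start_idx[b]:blocks$end_idx[b]
    H <- M[, idx, drop = FALSE]
    str <- apply(round(H), 1, paste, collapse = "")
    calls[, b] <- str
    tt <- table(str)
    tabs[[b]] <- data.frame(block = blocks$block[b], haplotype = names(tt),
                            carriers = as.integer(tt),
                            het = grepl("1", names(tt)),
                            stringsAsFactors = FALSE)
  }
  list(calls = calls, table = do.call(rbind, tabs))
}

#' Ridge-regression BLUP marker effects
#'
#' Solves \eqn{u = (Z'Z + \lambda I)^{-1} Z' y} on column-centered dosages
#' with the shrinkage \eqn{\lambda = \sigma^2_e / \sigma^2_u} estimated by
#' REML of the equivalent mixed model (through the eigendecomposition of
#' \eqn{ZZ'}), unless a fixed \code{lambda} is supplied.
#'
#' @param genotypes curated \code{genotype_matrix} (or dosage matrix).
#' @param trait named vector of one value per genotype, or a trait table
#'   filtered to one trait.
#' @param lambda optional fixed ridge parameter.
#' @return list with marker effects \code{u}, \code{lambda}, variance
#'   components, the intercept, fitted GEBVs and the column centers used.
#' @export
rrblup_effects <- function(genotypes, trait, lambda = NULL) {
  M <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosage else
    as.matrix(genotypes)
  y <- if (is.data.frame(trait)) {
    stats::setNames(trait$value, trait$genotype)
  } else trait
  ids <- intersect(rownames(M), names(y))
  if (length(ids) < 3) stopf("too few genotypes with trait values")
  M <- M[ids, , drop = FALSE]
  y <- as.numeric(y[ids])
  if (stats::sd(y) == 0) stopf("trait has zero variance")
  centers <- colMeans(M)
  Z <- sweep(M, 2, centers)
  n <- nrow(Z); m <- ncol(Z)

  varcomp <- NULL
  if (is.null(lambda)) {
    K <- tcrossprod(Z)
    eg <- eigen(K, symmetric = TRUE)
    U <- eg$vectors; dvals <- pmax(eg$values, 0)
    zy <- drop(crossprod(U, y))
    x1 <- drop(crossprod(U, rep(1, n)))
    neg2reml <- function(ldelta) {
      delta <- exp(ldelta)
      w <- dvals + delta
      XtViX <- sum(x1^2 / w)
      mu <- sum(x1 * zy / w) / XtViX
      r <- zy - mu * x1
      quad <- sum(r^2 / w)
      s2u <- quad / (n - 1)
      (n - 1) * log(s2u) + sum(log(w)) + log(XtViX)
    }
    op <- stats::optimize(neg2reml, c(-12, 12))
    delta <- exp(op$minimum)
    w <- dvals + delta
    mu <- sum(x1 * zy / w) / sum(x1^2 / w)
    s2u <- sum((zy - mu * x1)^2 / w) / (n - 1)
    lambda <- delta
    varcomp <- c(sigma2_u = s2u, sigma2_e = s2u * delta)
  } else {
    mu <- mean(y)
  }
  yc <- y - mu
  u <- if (n <= m) {
    drop(crossprod(Z, solve(tcrossprod(Z) + diag(lambda, n), yc)))
  } else {
    drop(solve(crossprod(Z) + diag(lambda, m), crossprod(Z, yc)))
  }
  names(u) <- colnames(Z)
  gebv <- drop(Z %*% u)
  names(gebv) <- ids
  list(u = u, lambda = lambda, varcomp = varcomp, intercept = mu,
       gebv = gebv, centers = centers)
}

#' Local genomic estimated breeding values per haplotype
#'
#' A haplotype's effect is the sum over the block's markers of the marker
#' effect times the centered dosage its string encodes.  Per block, the
#' variance of effects across the distinct observed (non-heterozygous)
#' haplotypes is scaled genome-wide to min 0 / max 1, blocks at or above
#' \code{sig_threshold} are flagged significant, and haplotypes are marked
#' beneficial by the trait sign rule (positive effect for scsAUC, negative
#' for rAUC).
#'
#' @param effects output of \code{\link{rrblup_effects}}.
#' @param blocks output of \code{\link{build_ld_blocks}}.
#' @param haplotypes output of \code{\link{call_haplotypes}}.
#' @param trait_direction \code{"positive"} (scsAUC: larger is beneficial)
#'   or \code{"negative"} (rAUC).
#' @param sig_threshold scaled min-max variance threshold (default 0.3).
#' @param weighted use carrier-frequency-weighted block variances instead
#'   of the unweighted variance across distinct haplotypes.
#' @return a \code{haplotype_effect_table}: per-block-haplotype effects
#'   with carrier counts, block variances, scaled variances, significance
#'   and beneficial flags; block summary as attribute \code{"blocks"}.
#' @export
local_gebv <- function(effects, blocks, haplotypes,
                       trait_direction = c("positive", "negative"),
                       sig_threshold = 0.3, weighted = FALSE) {
  trait_direction <- match.arg(trait_direction)
  tab <- haplotypes$table
  u <- effects$u
  centers <- effects$centers
  eff <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    b <- match(tab$block[i], blocks$block)
    idx <- blocks$start_idx[b]:blocks$end_idx[b]
    dos <- as.integer(strsplit(tab$haplotype[i], "")[[1]])
    eff[i] <- sum(u[idx] * (dos - centers[idx]))
  }
  tab$effect <- eff

  bvar <- vapply(blocks$block, function(b) {
    rows <- tab$block == b & !tab$het
    if (sum(rows) < 2) return(0)
    if (weighted) {
      w <- tab$carriers[rows]
      e <- tab$effect[rows]
      sum(w * (e - stats::weighted.mean(e, w))^2) / sum(w)
    } else stats::var(tab$effect[rows])
  }, numeric(1))
  rng <- range(bvar)
  scaled <- if (length(bvar) == 1) {
    warnf("single block: scaled variance undefined, reported as 1")
    stats::setNames(1, blocks$block)
  } else if (diff(rng) == 0) {
    warnf("all block variances equal; scaled variances reported as 0")
    stats::setNames(rep(0, length(bvar)), blocks$block)
  } else (bvar - rng[1]) / diff(rng)

  tab$block_variance <- bvar[tab$block]
  tab$scaled_variance <- scaled[tab$block]
  tab$significant <- tab$scaled_variance >= sig_threshold
  tab$beneficial <- if (trait_direction == "positive") tab$effect > 0
  else tab$effect < 0

  attr(tab, "blocks") <- data.frame(block = blocks$block,
                                    chrom = blocks$chrom,
                                    center_pos = blocks$center_pos,
                                    variance = unname(bvar),
                                    scaled_variance = unname(scaled),
                                    significant = unname(scaled >= sig_threshold))
  class(tab) <- c("haplotype_effect_table", "data.frame")
  tab
}

#' In-silico haplotype stacking
#'
#' Counts, per genotype, the significant blocks at which it carries a
#' beneficial haplotype; groups genotypes by that count and summarizes the
#' group mean trait value, with a linear-trend slope (regression of the
#' genotype trait value on the count, equivalent to the size-weighted
#' regression of group means).
#'
#' @param effect_table output of \code{\link{local_gebv}}.
#' @param haplotypes output of \code{\link{call_haplotypes}}.
#' @param trait named trait vector per genotype (same trait used for
#'   detection, or any trait to summarize).
#' @return list with per-genotype counts, the per-count group summary and
#'   the fitted slope.
#' @export
stack_haplotypes <- function(effect_table, haplotypes, trait) {
  sig_blocks <- unique(effect_table$block[effect_table$significant])
  ids <- rownames(haplotypes$calls)
  if (!length(sig_blocks)) {
    warnf("no significant blocks; stacking summary is empty")
    return(list(counts = stats::setNames(integer(length(ids)), ids),
                groups = data.frame(), slope = NA_real_))
  }
  ben <- effect_table[effect_table$significant & effect_table$beneficial, ]
  key <- paste(ben$block, ben$haplotype)
  counts <- integer(length(ids))
  for (b in sig_blocks) {
    counts <- counts + as.integer(paste(b, haplotypes$calls[, b]) %in% key)
  }
  names(counts) <- ids
  y <- if (is.data.frame(trait)) stats::setNames(trait$value, trait$genotype) else trait
  y <- y[ids]
  groups <- do.call(rbind, lapply(sort(unique(counts)), function(k) {
    sel <- counts == k
    data.frame(n_beneficial = k, n_genotypes = sum(sel),
               mean_trait = mean(y[sel], na.rm = TRUE))
  }))
  slope <- if (length(unique(counts)) > 1)
    unname(stats::coef(stats::lm(y ~ counts))[2]) else NA_real_
  list(counts = counts, groups = groups, slope = slope,
       n_significant = length(sig_blocks))
}
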