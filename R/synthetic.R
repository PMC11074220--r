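#' Configuration for the synthetic stay-green trial generator
#'
#' The generator emulates the data structure of a commercial spring barley
#' breeding panel evaluated for post-flowering canopy senescence: ~400
#' inbred genotypes in three ancestry clusters, several thousand curated
#' SNPs on seven chromosomes arranged in tight LD blocks, six rain-fed
#' environments with 3--7 post-flowering UAV flights each, partially
#' replicated randomized-block field layouts with smooth spatial trends and
#' autocorrelated residuals, factor-analytic genotype-by-environment
#' structure for the senescence trait, and a positive genetic correlation
#' between stay-green and yield.
#'
#' Defaults are the study conditions: 397 genotypes, 7 chromosomes with
#' 765 two-marker LD blocks each (so that roughly 6--7 thousand markers and
#' ~2,850 blocks survive minor-allele-frequency curation), 6 environments
#' with 3, 3, 3, 4, 7 and 3 flights, 30% plot replication, and a target
#' stay-green/yield genetic correlation of 0.7 (the study reports 0.33 to
#' 0.79 across environments).
#'
#' @param n_genotypes number of inbred genotypes.
#' @param n_chromosomes,blocks_per_chromosome,markers_per_block genome
#'   layout; blocks are contiguous marker runs in perfect founder LD.
#' @param n_clusters number of ancestry clusters (cluster-specific founder
#'   haplotype frequencies).
#' @param copy_prob probability that a gamete copies its founder allele at
#'   a marker (1 = intact founder haplotypes; lower values erode
#'   within-block LD).
#' @param het_rate probability that a genotype is heterozygous at a block
#'   (two independently drawn founder gametes).
#' @param rare_frac fraction of blocks whose founder-1 frequency is drawn
#'   near zero in every cluster, emulating the sub-threshold-MAF markers
#'   removed by curation.
#' @param founder_freq_range interval into which non-rare founder-1
#'   frequencies are drawn; narrow it (e.g. \code{c(0.15, 0.85)}) to
#'   guarantee polymorphic, well-separated blocks for LD-recovery
#'   scenarios.
#' @param n_environments,env_names,timepoints_per_env trial structure; the
#'   flight counts default to the per-trial values of the study.
#' @param field_dims optional list of \code{c(rows, cols)} per environment;
#'   derived from the plot count when \code{NULL}.
#' @param replicate_fraction fraction of genotypes grown on two plots.
#' @param causal_blocks data.frame with columns \code{block} (block id),
#'   \code{effect} (scsAUC units per carried beneficial haplotype) and
#'   \code{rauc_sign}; \code{NULL} selects one mid-chromosome block on each
#'   of six chromosomes with effect +2.5.
#' @param polygenic_sd standard deviation (scsAUC units) of the genome-wide
#'   polygenic marker background.
#' @param fa_loadings_true environment x factor loading matrix of the
#'   simulated G x E deviations (scsAUC units).
#' @param fa_psi_true environment-specific variances of the G x E
#'   deviations.
#' @param spatial_amplitude standard deviation (NDRE units) of the smooth
#'   field surface added to every flight.
#' @param ar1_rho temporal AR1 correlation of plot residuals across
#'   flights.
#' @param resid_model \code{"ar1time"} (default), \code{"iid"}, or
#'   \code{"ar1space"} (separable AR1 row/column field per flight, with
#'   correlations \code{spatial_rho}).
#' @param spatial_rho length-2 AR1 row/column residual correlations used
#'   when \code{resid_model = "ar1space"}.
#' @param residual_sd residual standard deviation of a single NDRE
#'   observation.
#' @param gy_genetic_corr target genetic correlation between scsAUC and
#'   yield (imposed exactly on the simulated marker-genetic values).
#' @param yield_mean,yield_genetic_sd,yield_resid_sd,yield_spatial_amplitude
#'   yield model (t/ha); the defaults give a plot-level yield heritability
#'   of 0.8.
#' @param curve list of senescence-curve constants: \code{upper} and
#'   \code{lower} NDRE asymptotes, mean inflection thermal time \code{t0}
#'   (GDD), logistic scale \code{s} (GDD), and the grain-filling
#'   \code{window}.
#' @param flight_window thermal-time span of the flight schedule, a
#'   length-2 vector (all environments) or per-environment list; by
#'   default flights track each trial's own phenology (as scheduled off a
#'   check cultivar's growth stage): dense schedules (>= 6 flights) span
#'   the trial inflection -270 to +300 GDD and sparse ones -200 to
#'   +200 GDD.
#' @param n_flowering_groups number of equal-size flowering groups.
#' @param seed master seed; all stages derive their streams from it.
#' @return a \code{sim_config} list, validated.
#' @export
sim_config <- function(n_genotypes = 397,
                       n_chromosomes = 7,
                       blocks_per_chromosome = 765,
                       markers_per_block = 2,
                       n_clusters = 3,
                       copy_prob = 1,
                       het_rate = 0.01,
                       rare_frac = 0.47,
                       founder_freq_range = c(0, 1),
                       n_environments = 6,
                       env_names = c("21CGN", "21DND", "22CGN",
                                     "22DND", "22GAT", "22YRK"),
                       timepoints_per_env = c(3, 3, 3, 4, 7, 3),
                       field_dims = NULL,
                       replicate_fraction = 0.3,
                       causal_blocks = NULL,
                       polygenic_sd = 4,
                       fa_loadings_true = NULL,
                       fa_psi_true = NULL,
                       spatial_amplitude = 0.02,
                       ar1_rho = 0.3,
                       resid_model = c("ar1time", "iid", "ar1space"),
                       spatial_rho = c(0.5, 0.5),
                       residual_sd = 0.015,
                       gy_genetic_corr = 0.7,
                       yield_mean = 3.5,
                       yield_genetic_sd = 0.35,
                       yield_resid_sd = 0.175,
                       yield_spatial_amplitude = 0.2,
                       curve = list(upper = 0.45, lower = 0.05, t0 = 1750,
                                    s = 60, window = c(1500, 1950)),
                       flight_window = NULL,
                       n_flowering_groups = 3,
                       seed = 1) {
  resid_model <- match.arg(resid_model)
  cfg <- as.list(environment())
  counts <- c(n_genotypes, n_chromosomes, blocks_per_chromosome,
              markers_per_block, n_clusters, n_environments)
  if (any(counts < 1)) stopf("all counts must be >= 1")
  if (length(timepoints_per_env) != n_environments)
    stopf("timepoints_per_env must have one entry per environment")
  if (any(timepoints_per_env < 1)) stopf("each environment needs >= 1 flight")
  if (length(env_names) != n_environments)
    stopf("env_names must have one entry per environment")
  if (replicate_fraction <= 0 || replicate_fraction > 1)
    stopf("replicate_fraction must be in (0, 1]")
  if (abs(ar1_rho) >= 1) stopf("ar1_rho must lie in (-1, 1)")
  if (abs(gy_genetic_corr) > 1) stopf("|gy_genetic_corr| must be <= 1")
  if (copy_prob < 0 || copy_prob > 1) stopf("copy_prob must be in [0, 1]")
  if (is.null(cfg$fa_loadings_true)) {
    L1 <- c(8, 10, 6, 12, 8, 8)
    L2 <- c(4, -4, 2, -3, 4, -2)
    cfg$fa_loadings_true <- cbind(L1, L2)[seq_len(n_environments), , drop = FALSE]
  }
  cfg$fa_loadings_true <- as.matrix(cfg$fa_loadings_true)
  if (nrow(cfg$fa_loadings_true) != n_environments)
    stopf("fa_loadings_true must have one row per environment")
  if (is.null(cfg$fa_psi_true)) cfg$fa_psi_true <- rep(3, n_environments)
  if (any(cfg$fa_psi_true < 0)) stopf("fa_psi_true must be non-negative")
  n_blocks <- n_chromosomes * blocks_per_chromosome
  if (is.null(cfg$causal_blocks)) {
    ch <- seq_len(min(6, n_chromosomes))
    idx <- (ch - 1) * blocks_per_chromosome + ceiling(blocks_per_chromosome / 2)
    cfg$causal_blocks <- data.frame(block = sprintf("b%06d", idx),
                                    effect = rep(2.5, length(idx)),
                                    rauc_sign = rep(-1, length(idx)))
  }
  structure(cfg, class = "sim_config")
}

#' Simulate an inbred genotype panel with LD-block and cluster structure
#'
#' Each block carries two complementary founder haplotypes whose
#' frequencies differ between ancestry clusters; genotypes draw one founder
#' per block (both gametes identical with probability
#' \code{1 - het_rate}), so within-block markers are in near-perfect LD
#' while between-block draws are independent given cluster.  Dosages are
#' recoded to minor-allele counts.
#'
#' @param config a \code{sim_config}.
#' @return list with \code{genotypes} (a \code{genotype_matrix}: dosage
#'   matrix plus marker map) and \code{truth} (block boundaries, founder
#'   haplotypes, cluster labels, causal-carrier counts).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 101))
  n <- config$n_genotypes
  m_blk <- config$markers_per_block
  n_blocks <- config$n_chromosomes * config$blocks_per_chromosome
  M <- n_blocks * m_blk

  cluster <- sort(rep_len(seq_len(config$n_clusters), n))
  geno_ids <- sprintf("G%04d", seq_len(n))

  dosage <- matrix(0L, n, M)
  map <- data.frame(marker = character(M), chrom = integer(M), pos = numeric(M),
                    block = character(M), stringsAsFactors = FALSE)
  founders <- vector("list", n_blocks)
  bounds <- data.frame(block = character(n_blocks), chrom = integer(n_blocks),
                       start_idx = integer(n_blocks), end_idx = integer(n_blocks),
                       center_pos = numeric(n_blocks), rare = logical(n_blocks),
                       stringsAsFactors = FALSE)
  carrier <- matrix(0L, n, n_blocks)  # copies of founder haplotype 1

  b <- 0L
  col <- 0L
  for (ch in seq_len(config$n_chromosomes)) {
    pos <- 0
    for (bb in seq_len(config$blocks_per_chromosome)) {
      b <- b + 1L
      bid <- sprintf("b%06d", b)
      f1 <- stats::rbinom(m_blk, 1, 0.5)
      f2 <- 1L - f1
      rare <- stats::runif(1) < config$rare_frac
      fr <- config$founder_freq_range %||% c(0, 1)
      q <- if (rare) stats::runif(config$n_clusters, 0.002, 0.05)
           else fr[1] + diff(fr) * stats::rbeta(config$n_clusters, 0.8, 0.8)
      qg <- q[cluster]
      g1 <- stats::rbinom(n, 1, qg)                 # gamete 1 founder-1?
      g2 <- ifelse(stats::runif(n) < config$het_rate,
                   stats::rbinom(n, 1, qg), g1)     # gamete 2
      carrier[, b] <- g1 + g2
      hap <- function(gam) {
        H <- matrix(rep(f2, each = n), n, m_blk)
        H[gam == 1, ] <- matrix(rep(f1, each = sum(gam == 1)),
                                sum(gam == 1), m_blk)
        if (config$copy_prob < 1) {
          noise <- matrix(stats::runif(n * m_blk) > config$copy_prob, n, m_blk)
          H[noise] <- stats::rbinom(sum(noise), 1, 0.5)
        }
        H
      }
      D <- hap(g1) + hap(g2)
      pos <- pos + round(stats::runif(1, 8e5, 2e6))
      mpos <- pos + cumsum(c(0, round(stats::runif(m_blk - 1, 200, 2000))))
      pos <- mpos[m_blk]
      idx <- col + seq_len(m_blk)
      dosage[, idx] <- D
      map$chrom[idx] <- ch
      map$pos[idx] <- mpos
      map$block[idx] <- bid
      map$marker[idx] <- sprintf("M%d_%09d", ch, mpos)
      founders[[b]] <- rbind(f1 = 2L * f1, f2 = 2L * f2)
      bounds[b, c("block", "chrom")] <- list(bid, ch)
      bounds$start_idx[b] <- idx[1]
      bounds$end_idx[b] <- idx[m_blk]
      bounds$center_pos[b] <- mean(range(mpos))
      bounds$rare[b] <- rare
      col <- col + m_blk
    }
  }

  # recode to minor-allele dosage
  p_alt <- colMeans(dosage) / 2
  flip <- p_alt > 0.5
  dosage[, flip] <- 2L - dosage[, flip]
  for (b in seq_len(n_blocks)) {
    idx <- bounds$start_idx[b]:bounds$end_idx[b]
    fl <- flip[idx]
    founders[[b]][, fl] <- 2L - founders[[b]][, fl]
  }
  names(founders) <- bounds$block
  dimnames(dosage) <- list(geno_ids, map$marker)

  genotypes <- structure(list(dosage = dosage, map = map),
                         class = "genotype_matrix")
  truth <- list(block_bounds = bounds, founders = founders,
                cluster = stats::setNames(cluster, geno_ids),
                carrier = `dimnames<-`(carrier, list(geno_ids, bounds$block)),
                config = config)
  list(genotypes = genotypes, truth = truth)
}

# Marker-based genetic values shared by all environments: causal-block
# effects plus a polygenic background for scsAUC, and a yield component
# constructed so the sample correlation with the scsAUC marker value equals
# gy_genetic_corr exactly.
build_genetic_values <- function(genotypes, truth, config) {
  set.seed(derive_seed(config$seed, 202))
  n <- nrow(genotypes$dosage)
  Zc <- scale(genotypes$dosage, center = TRUE, scale = FALSE)
  cb <- config$causal_blocks
  miss <- setdiff(cb$block, colnames(truth$carrier))
  if (length(miss)) stopf("causal blocks not in genome: %s",
                          paste(miss, collapse = ", "))
  s_caus <- drop(truth$carrier[, cb$block, drop = FALSE] %*% (cb$effect / 2))
  beta <- stats::rnorm(ncol(Zc))
  m_poly <- drop(Zc %*% beta)
  if (stats::sd(m_poly) > 0)
    m_poly <- m_poly / stats::sd(m_poly) * config$polygenic_sd
  m_s <- s_caus + m_poly

  w <- drop(Zc %*% stats::rnorm(ncol(Zc)))
  w_perp <- stats::residuals(stats::lm(w ~ m_s))
  std <- function(x) (x - mean(x)) / stats::sd(x)
  rho <- config$gy_genetic_corr
  m_y <- config$yield_genetic_sd *
    (rho * std(m_s) + sqrt(1 - rho^2) * std(w_perp))

  k <- ncol(config$fa_loadings_true)
  fscore <- matrix(stats::rnorm(n * k), n, k)
  delta <- sapply(seq_len(config$n_environments),
                  function(j) stats::rnorm(n, 0, sqrt(config$fa_psi_true[j])))
  u_ge <- fscore %*% t(config$fa_loadings_true) + delta
  g_scs <- matrix(m_s, n, config$n_environments) + u_ge
  colnames(g_scs) <- config$env_names
  rownames(g_scs) <- rownames(genotypes$dosage)

  flowering <- stats::rnorm(n, 1000, 30)
  Sigma_true <- stats::var(m_s) + tcrossprod(config$fa_loadings_true) +
    diag(config$fa_psi_true, nrow = config$n_environments)
  dimnames(Sigma_true) <- list(config$env_names, config$env_names)

  list(m_s = m_s, m_y = m_y, g_scs = g_scs, fscore = fscore,
       flowering = stats::setNames(flowering, rownames(genotypes$dosage)),
       Sigma_true = Sigma_true, Sigma_realized = stats::cov(g_scs))
}

# smooth random surface on the field grid, standardized to sd = amplitude
random_surface <- function(row, col, nr, nc, amplitude) {
  if (amplitude == 0) return(rep(0, length(row)))
  a <- stats::rnorm(5)
  w <- stats::runif(2, 0.5, 1.5)
  ph <- stats::runif(2, 0, 2 * pi)
  u <- row / nr
  v <- col / nc
  s <- a[1] * cos(2 * pi * w[1] * u + ph[1]) +
    a[2] * cos(2 * pi * w[2] * v + ph[2]) +
    a[3] * u * v + a[4] * u + a[5] * v
  s <- s - mean(s)
  if (stats::sd(s) > 0) s <- s / stats::sd(s)
  s * amplitude
}

#' Simulate field trials: NDRE time series, plot table and yield
#'
#' Builds, for each requested environment, a partially replicated
#' randomized-block layout on a row/column grid, assigns each genotype a
#' logistic senescence curve in thermal time whose inflection point carries
#' the marker-based and factor-analytic genetic effects, and observes NDRE
#' at the configured flight times with a smooth spatial surface and
#' autocorrelated residual noise.  Yield is simulated with the genetic
#' component built in \code{build_genetic_values}.
#'
#' @param genotypes,truth output of \code{simulate_genotypes}.
#' @param config the \code{sim_config} used throughout.
#' @param env environment indices to simulate (default: all).
#' @return list with \code{ndre} (long data.frame), \code{plots},
#'   \code{yield}, and the updated \code{truth} (genetic values, curve
#'   parameters, spatial surfaces, true windowed scsAUC per
#'   genotype x environment).
#' @export
simulate_trial <- function(genotypes, truth, config, env = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(env)) env <- seq_len(config$n_environments)
  if (any(env < 1 | env > config$n_environments))
    stopf("environment index outside configuration (1..%d)",
          config$n_environments)
  if (is.null(truth$gen)) truth$gen <- build_genetic_values(genotypes, truth, config)
  gen <- truth$gen
  n <- nrow(genotypes$dosage)
  ids <- rownames(genotypes$dosage)
  cv <- config$curve
  span <- cv$upper - cv$lower

  fg <- if (config$n_flowering_groups > 1)
    cut(rank(gen$flowering, ties.method = "first"),
        breaks = config$n_flowering_groups, labels = FALSE)
  else rep(1L, n)
  names(fg) <- ids

  ndre_all <- list(); plots_all <- list(); yield_all <- list()
  truth$env <- truth$env %||% list()
  for (j in env) {
    set.seed(derive_seed(config$seed, 1000 + j))
    ename <- config$env_names[j]
    n_rep <- max(1, round(config$replicate_fraction * n))
    rep_ids <- sample(ids, n_rep)
    n_plots <- n + n_rep
    dims <- if (!is.null(config$field_dims)) config$field_dims[[j]]
            else { nr <- floor(sqrt(n_plots)); c(nr, ceiling(n_plots / nr)) }
    nr <- dims[1]; nc <- dims[2]
    if (nr * nc < n_plots) stopf("field_dims too small for %d plots", n_plots)
    cells <- expand.grid(row = seq_len(nr), col = seq_len(nc))
    left <- which(cells$col <= ceiling(nc / 2))
    right <- setdiff(seq_len(nr * nc), left)
    size1 <- max(n_plots - length(right), min(ceiling(n_plots / 2), length(left)))
    c1 <- sample(left, size1)
    c2 <- sample(right, n_plots - size1)
    # replicated genotypes: one plot in each half-block; singles fill the rest
    singles <- setdiff(ids, rep_ids)
    occ1 <- c(rep_ids, sample(singles, length(c1) - n_rep))
    occ2 <- setdiff(c(rep_ids, singles), setdiff(occ1, rep_ids))
    occ2 <- c(rep_ids, setdiff(occ2, rep_ids))
    stopifnot(length(occ2) == length(c2))
    plot_geno <- c(sample(occ1), sample(occ2))
    cell_idx <- c(c1, c2)
    rep_id <- rep(1:2, c(length(c1), length(c2)))
    plots <- data.frame(trial = ename,
                        plot = sprintf("%s_P%03d", ename, seq_len(n_plots)),
                        row = cells$row[cell_idx], col = cells$col[cell_idx],
                        replicate = rep_id, genotype = plot_geno,
                        flowering_group = fg[plot_geno],
                        stringsAsFactors = FALSE)

    # trial phenology: environment-level inflection shift
    t0_env <- cv$t0 + stats::rnorm(1, 0, 40)

    # flight thermal times track the trial's own development (flights are
    # scheduled off the check cultivar's growth stage): dense schedules
    # span anthesis to maturity, sparse ones the grain-filling decline
    tp <- config$timepoints_per_env[j]
    fw <- config$flight_window %||%
      (if (tp >= 6) t0_env + c(-270, 300) else t0_env + c(-200, 200))
    if (is.list(fw)) fw <- fw[[j]]
    flights <- if (tp == 1) mean(fw) else
      round(seq(fw[1], fw[2], length.out = tp) + stats::runif(tp, -15, 15))
    flights <- sort(flights)

    # genotype curves: env mean inflection plus genetic shifts (GDD)
    gshift <- (gen$g_scs[, j] - mean(gen$g_scs[, j])) / span
    t0_g <- t0_env + gshift
    true_scs <- vapply(ids, function(g)
      logistic_decline_auc(cv$window[1], cv$window[2], cv$upper, cv$lower,
                           t0_g[g], cv$s), numeric(1))

    surf <- random_surface(plots$row, plots$col, nr, nc, config$spatial_amplitude)
    mu <- outer(seq_len(n_plots), seq_along(flights), function(i, k)
      logistic_decline(flights[k], cv$upper, cv$lower,
                       t0_g[plots$genotype[i]], cv$s))
    eps <- matrix(0, n_plots, tp)
    if (config$residual_sd > 0) {
      if (config$resid_model == "ar1time") {
        rho <- config$ar1_rho
        eps[, 1] <- stats::rnorm(n_plots, 0, config$residual_sd)
        if (tp > 1) for (k in 2:tp)
          eps[, k] <- rho * eps[, k - 1] +
            stats::rnorm(n_plots, 0, config$residual_sd * sqrt(1 - rho^2))
      } else if (config$resid_model == "ar1space") {
        for (k in seq_len(tp))
          eps[, k] <- ar1_field(plots$row, plots$col,
                                config$spatial_rho[1], config$spatial_rho[2],
                                config$residual_sd)
      } else {
        eps[] <- stats::rnorm(n_plots * tp, 0, config$residual_sd)
      }
    }
    ndre <- mu + surf + eps

    ysurf <- random_surface(plots$row, plots$col, nr, nc,
                            config$yield_spatial_amplitude)
    yld <- config$yield_mean + stats::rnorm(1, 0, 0.3) +
      gen$m_y[plots$genotype] + ysurf +
      stats::rnorm(n_plots, 0, config$yield_resid_sd)

    ndre_all[[ename]] <- data.frame(
      plots[rep(seq_len(n_plots), each = tp), ],
      thermal_time = rep(flights, n_plots),
      ndre = as.vector(t(ndre)), row.names = NULL)
    plots_all[[ename]] <- plots
    yield_all[[ename]] <- data.frame(plots, yield = yld, row.names = NULL)
    truth$env[[ename]] <- list(flights = flights, t0 = t0_g, t0_env = t0_env,
                               s = cv$s, upper = cv$upper, lower = cv$lower,
                               surface = stats::setNames(surf, plots$plot),
                               yield_surface = stats::setNames(ysurf, plots$plot),
                               true_scsAUC = true_scs)
  }
  truth$flowering_group <- fg
  list(ndre = do.call(rbind, ndre_all),
       plots = do.call(rbind, plots_all),
       yield = do.call(rbind, yield_all),
       truth = truth)
}

# separable AR1 x AR1 Gaussian field sampled at plot coordinates
ar1_field <- function(row, col, rho_r, rho_c, sd) {
  nr <- max(row); nc <- max(col)
  Lr <- chol(rho_r^abs(outer(seq_len(nr), seq_len(nr), `-`)))
  Lc <- chol(rho_c^abs(outer(seq_len(nc), seq_len(nc), `-`)))
  E <- t(Lr) %*% matrix(stats::rnorm(nr * nc), nr, nc) %*% Lc
  sd * E[cbind(row, col)]
}

#' One-call synthetic study: genotypes plus all trials
#'
#' @param config a \code{sim_config}.
#' @return list with \code{genotypes}, \code{ndre}, \code{plots},
#'   \code{yield} and \code{truth}.
#' @export
simulate_study <- function(config = sim_config()) {
  g <- simulate_genotypes(config)
  tr <- simulate_trial(g$genotypes, g$truth, config)
  c(list(genotypes = g$genotypes), tr)
}

#' Thermal time from daily temperature extremes
#'
#' Accumulates growing degree days as the mean of daily minimum and maximum
#' temperature above a base (default 0 degrees C, the common barley
#' convention), clipped below at the base.
#'
#' @param tmin,tmax daily minimum and maximum temperatures.
#' @param base base temperature.
#' @return cumulative growing degree days, one value per day.
#' @export
growing_degree_days <- function(tmin, tmax, base = 0) {
  stopifnot(length(tmin) == length(tmax))
  cumsum(pmax((tmin + tmax) / 2 - base, 0))
}

#' Simulate multi-environment trait data with a known genetic covariance
#'
#' Draws iid genotype effect vectors from \eqn{N(\mu, \Sigma)} across
#' environments -- the sampling model of the second-stage MET analysis --
#' for parameter-recovery testing of the covariance-structure fits.
#'
#' @param Sigma true environment covariance matrix.
#' @param n number of genotypes.
#' @param mu environment means.
#' @param seed RNG seed.
#' @return matrix of dimension \code{n} x \code{ncol(Sigma)}.
#' @export
simulate_met_data <- function(Sigma, n, mu = NULL, seed = 1) {
  set.seed(seed)
  E <- ncol(Sigma)
  if (is.null(mu)) mu <- rep(0, E)
  L <- chol(Sigma)
  Y <- matrix(stats::rnorm(n * E), n, E) %*% L +
    matrix(mu, n, E, byrow = TRUE)
  colnames(Y) <- colnames(Sigma) %||% paste0("E", seq_len(E))
  rownames(Y) <- sprintf("G%04d", seq_len(n))
  Y
}
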