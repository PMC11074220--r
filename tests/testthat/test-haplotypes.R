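toy_genotypes <- function(M, chrom = NULL, pos = NULL) {
  n <- nrow(M); m <- ncol(M)
  if (is.null(rownames(M))) rownames(M) <- sprintf("g%03d", seq_len(n))
  if (is.null(colnames(M))) colnames(M) <- sprintf("m%03d", seq_len(m))
  structure(list(dosage = M,
                 map = data.frame(marker = colnames(M),
                                  chrom = chrom %||% rep(1L, m),
                                  pos = pos %||% seq_len(m) * 1000,
                                  stringsAsFactors = FALSE)),
            class = "genotype_matrix")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("curation applies the MAF and heterozygosity rules at their boundaries", {
  n <- 100
  mk <- function(n0, n1, n2) sample(rep(c(0, 1, 2), c(n0, n1, n2)))
  M <- cbind(maf05 = mk(95, 0, 5),    # MAF exactly 0.05 -> removed
             het10 = mk(60, 10, 30),  # het exactly 0.10 -> retained
             het11 = mk(59, 11, 30),  # het 0.11 -> removed
             clean = mk(60, 0, 40))
  set.seed(71)
  g <- toy_genotypes(M)
  cur <- curate_markers(g)
  expect_setequal(colnames(cur$dosage), c("het10", "clean"))
  rep_ <- attr(cur, "report")
  expect_equal(rep_$removed_maf, 1)
  expect_equal(rep_$removed_het, 1)
  # 10-marker toy: 3 low-MAF, 2 high-het, 5 clean -> 5 survive
  M10 <- cbind(sapply(1:3, function(i) mk(96, 0, 4)),
               sapply(1:2, function(i) mk(50, 20, 30)),
               sapply(1:5, function(i) mk(50, 0, 50)))
  expect_equal(ncol(curate_markers(toy_genotypes(M10))$dosage), 5)
  expect_error(curate_markers(toy_genotypes(M10[, 1:2, drop = FALSE])),
               "every marker")
})

test_that("Rogers' distance matches the frequency-vector formula", {
  M <- rbind(a = c(0, 0, 0), b = c(0, 0, 0), c = c(2, 2, 2), d = c(1, 0, 0))
  D <- rogers_distance(M)
  expect_equal(D["a", "b"], 0)
  expect_equal(D["a", "c"], 1)            # opposite homozygotes everywhere
  expect_equal(diag(D), rep(0, 4), ignore_attr = TRUE)
  expect_equal(D, t(D))
  # het vs hom at a single-locus genome: frequency vectors (.5,.5) vs (1,0)
  D1 <- rogers_distance(rbind(a = 0, b = 1))
  expect_equal(D1["a", "b"], 0.5)
  expect_true(all(D >= 0 & D <= 1))
})

test_that("diversity clustering recovers simulated ancestry groups", {
  cfg <- sim_config(n_genotypes = 120, blocks_per_chromosome = 25,
                    n_chromosomes = 3, n_clusters = 3, rare_frac = 0,
                    n_environments = 1, timepoints_per_env = 3,
                    env_names = "E1", seed = 72)
  g <- simulate_genotypes(cfg)
  D <- rogers_distance(g$genotypes)
  dc <- diversity_clusters(D, k = 3)
  expect_gte(mclust::adjustedRandIndex(dc$cluster, g$truth$cluster), 0.9)
  expect_lte(sum(dc$pct_var), 100 + 1e-8)
  # duplicated genotypes share coordinates and cluster
  M <- g$genotypes$dosage[c(1, 1, 2:30), ]
  rownames(M) <- sprintf("x%02d", 1:31)
  dc2 <- diversity_clusters(rogers_distance(M), k = 3)
  expect_equal(dc2$scores[1, ], dc2$scores[2, ], ignore_attr = TRUE)
  expect_equal(dc2$cluster[[1]], dc2$cluster[[2]])
  expect_error(diversity_clusters(D[1:2, 1:2], k = 5), "clusters")
})

test_that("the LD-block scan follows the anchored tolerance rule", {
  set.seed(73)
  n <- 200
  # perfectly correlated markers: one block per chromosome
  base <- rbinom(n, 1, 0.5) * 2
  M1 <- matrix(base, n, 6)
  g1 <- toy_genotypes(M1, chrom = rep(1:2, each = 3))
  b1 <- build_ld_blocks(g1, 0.7, 2)
  expect_equal(nrow(b1), 2)
  # independent markers: tolerance 2 caps blocks at 3; tolerance 0 -> singletons
  M2 <- sapply(1:9, function(i) rbinom(n, 1, 0.5) * 2)
  g2 <- toy_genotypes(M2)
  expect_true(all(build_ld_blocks(g2, 0.7, 2)$n_markers <= 3))
  expect_true(all(build_ld_blocks(g2, 0.7, 0)$n_markers == 1))
  # blocks partition the marker set
  b2 <- build_ld_blocks(g2, 0.7, 2)
  expect_identical(sort(unlist(Map(seq, b2$start_idx, b2$end_idx))), 1:9)
})

test_that("true simulated block boundaries are recovered exactly", {
  cfg <- sim_config(n_genotypes = 250, blocks_per_chromosome = 10,
                    markers_per_block = 3, n_chromosomes = 2, n_clusters = 1,
                    rare_frac = 0, het_rate = 0,
                    founder_freq_range = c(0.15, 0.85), n_environments = 1,
                    timepoints_per_env = 3, env_names = "E1", seed = 74)
  g <- simulate_genotypes(cfg)
  found <- build_ld_blocks(g$genotypes, 0.7, 0)
  truth <- g$truth$block_bounds
  expect_equal(nrow(found), nrow(truth))
  expect_equal(found$start_idx, truth$start_idx)
  expect_equal(found$end_idx, truth$end_idx)
})

test_that("haplotype calling enumerates founder strings with carrier counts", {
  cfg <- sim_config(n_genotypes = 100, blocks_per_chromosome = 6,
                    markers_per_block = 2, n_chromosomes = 2,
                    rare_frac = 0, het_rate = 0.05, n_environments = 1,
                    timepoints_per_env = 3, env_names = "E1", seed = 75)
  g <- simulate_genotypes(cfg)
  blocks <- build_ld_blocks(g$genotypes, 0.7, 0)
  haps <- call_haplotypes(g$genotypes, blocks)
  expect_equal(sum(haps$table$carriers),
               nrow(g$genotypes$dosage) * nrow(blocks))
  # observed strings are founders or het composites
  for (b in sample(blocks$block, 5)) {
    F2 <- g$truth$founders[[b]]
    legal <- c(paste(F2[1, ], collapse = ""), paste(F2[2, ], collapse = ""),
               paste((F2[1, ] + F2[2, ]) / 2, collapse = ""))
    expect_true(all(haps$table$haplotype[haps$table$block == b] %in% legal))
  }
  # n identical genotypes: exactly one haplotype per block
  M <- matrix(rep(c(0, 2, 2, 0), each = 7), 7, 4)
  gi <- toy_genotypes(M)
  bi <- build_ld_blocks(gi, 0.7, 2)
  hi <- call_haplotypes(gi, bi)
  expect_true(all(tapply(hi$table$carriers, hi$table$block, length) == 1))
})

test_that("ridge-regression BLUP matches its closed-form oracle and limits", {
  set.seed(76)
  M <- matrix(rbinom(50 * 100, 2, 0.4), 50, 100,
              dimnames = list(sprintf("g%02d", 1:50), NULL))
  y <- stats::setNames(rnorm(50), rownames(M))
  for (lam in c(0.5, 5, 50)) {
    fit <- rrblup_effects(M, y, lambda = lam)
    expect_lt(max(abs(fit$u - ridge_oracle(M, y, lam))), 1e-8)
  }
  # shrinkage limit
  expect_lt(max(abs(rrblup_effects(M, y, lambda = 1e12)$u)), 1e-9)
  # OLS limit with n > m
  M2 <- matrix(rnorm(60 * 20), 60, 20, dimnames = list(sprintf("g%02d", 1:60), NULL))
  y2 <- stats::setNames(drop(M2 %*% rnorm(20)) + rnorm(60, 0, 0.1), rownames(M2))
  f0 <- rrblup_effects(M2, y2, lambda = 1e-10)
  Zc <- scale(M2, scale = FALSE)
  ols <- drop(solve(crossprod(Zc), crossprod(Zc, y2 - mean(y2))))
  expect_lt(max(abs(f0$u - ols)), 1e-6)
  # REML-estimated lambda gives finite variance components
  fr <- rrblup_effects(M2, y2)
  expect_true(all(is.finite(c(fr$lambda, fr$varcomp))))
  expect_error(rrblup_effects(M2, stats::setNames(rep(1, 60), rownames(M2))),
               "zero variance")
})

test_that("localGEBVs decompose the genomic breeding value over blocks", {
  cfg <- sim_config(n_genotypes = 120, blocks_per_chromosome = 8,
                    markers_per_block = 2, n_chromosomes = 3, rare_frac = 0,
                    het_rate = 0, n_environments = 1, timepoints_per_env = 3,
                    env_names = "E1", seed = 77)
  g <- simulate_genotypes(cfg)
  blocks <- build_ld_blocks(g$genotypes, 0.7, 0)
  haps <- call_haplotypes(g$genotypes, blocks)
  set.seed(78)
  y <- stats::setNames(rnorm(120), rownames(g$genotypes$dosage))
  eff <- rrblup_effects(g$genotypes, y)
  et <- local_gebv(eff, blocks, haps)
  # per-genotype sum of block effects equals the full GEBV
  ids <- rownames(g$genotypes$dosage)
  key <- stats::setNames(et$effect, paste(et$block, et$haplotype))
  sums <- vapply(ids, function(gid)
    sum(key[paste(blocks$block, haps$calls[gid, blocks$block])]), numeric(1))
  expect_lt(max(abs(sums - eff$gebv[ids])), 1e-10)
  # scaled variances span [0, 1] with both endpoints attained
  bl <- attr(et, "blocks")
  expect_equal(min(bl$scaled_variance), 0)
  expect_equal(max(bl$scaled_variance), 1)
  # a whole-genome single block reproduces the GEBV directly
  one <- data.frame(block = "b000001", chrom = 1, start_idx = 1,
                    end_idx = ncol(g$genotypes$dosage), n_markers = ncol(g$genotypes$dosage),
                    start_pos = 1, end_pos = 2, center_pos = 1.5,
                    tolerance_used = 0)
  h1 <- call_haplotypes(g$genotypes, one)
  e1 <- suppressWarnings(local_gebv(eff, one, h1))
  key1 <- stats::setNames(e1$effect, e1$haplotype)
  expect_lt(max(abs(key1[h1$calls[ids, 1]] - eff$gebv[ids])), 1e-10)
  # zero-effect markers give zero block effect and variance
  eff0 <- eff; eff0$u[] <- 0
  et0 <- suppressWarnings(local_gebv(eff0, blocks, haps))
  expect_true(all(abs(et0$effect) < 1e-12))
  expect_true(all(attr(et0, "blocks")$variance == 0))
})

test_that("stacking counts beneficial haplotypes and recovers additive slopes", {
  slopes <- sapply(1:3, function(r) {
    cfg <- sim_config(n_genotypes = 400, blocks_per_chromosome = 8,
                      markers_per_block = 2, rare_frac = 0, het_rate = 0,
                      n_environments = 1, timepoints_per_env = 3,
                      env_names = "E1", polygenic_sd = 0.5, seed = 80 + r)
    g <- simulate_genotypes(cfg)
    tr <- simulate_trial(g$genotypes, g$truth, cfg)
    gen <- tr$truth$gen
    set.seed(90 + r)
    y <- gen$m_s + rnorm(length(gen$m_s), 0, 1)
    names(y) <- names(gen$m_s)
    cur <- g$genotypes
    blocks <- build_ld_blocks(cur, 0.7, 0)
    haps <- call_haplotypes(cur, blocks)
    eff <- rrblup_effects(cur, y)
    et <- local_gebv(eff, blocks, haps)
    st <- stack_haplotypes(et, haps, y)
    # group means increase with the number of beneficial haplotypes
    expect_gt(st$slope, 0)
    st$slope
  })
  # per-block simulated effect is 2.5; slope within 20%
  expect_lt(abs(stats::median(slopes) - 2.5) / 2.5, 0.2)
})

test_that("stacking handles edge cases", {
  et <- data.frame(block = c("b1", "b1", "b2", "b2"),
                   haplotype = c("0", "2", "0", "2"),
                   effect = c(-1, 1, -2, 2),
                   significant = c(TRUE, TRUE, TRUE, TRUE),
                   beneficial = c(FALSE, TRUE, FALSE, TRUE))
  calls <- rbind(gA = c(b1 = "2", b2 = "2"), gB = c(b1 = "0", b2 = "2"),
                 gC = c(b1 = "0", b2 = "0"))
  haps <- list(calls = calls)
  y <- c(gA = 3, gB = 1, gC = 0)
  st <- stack_haplotypes(et, haps, y)
  expect_equal(unname(st$counts[c("gA", "gB", "gC")]), c(2, 1, 0))
  expect_equal(st$groups$mean_trait, c(0, 1, 3))
  # carrier of every beneficial haplotype reaches the block count
  expect_equal(max(st$counts), st$n_significant)
  et$significant <- FALSE
  expect_warning(st0 <- stack_haplotypes(et, haps, y), "no significant")
  expect_equal(nrow(st0$groups), 0)
})
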