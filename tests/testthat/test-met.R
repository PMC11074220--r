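test_that("free-parameter counts follow the documented rules", {
  expect_equal(staygreen:::met_par_count("DIAG", 6), 6)
  expect_equal(staygreen:::met_par_count("CorV", 6), 2)
  expect_equal(staygreen:::met_par_count("CorH", 6), 7)
  expect_equal(staygreen:::met_par_count("FA", 6, 3), 6 * 3 - 3 + 6)
  expect_equal(staygreen:::met_par_count("FA", 6, 1), 12)
})

test_that("AIC equals -2 logL + 2p exactly", {
  Y <- simulate_met_data(diag(c(1, 2, 3)), 80, seed = 41)
  f <- fit_met(Y, "DIAG", n_starts = 1)
  expect_equal(f$AIC, -2 * f$loglik + 2 * f$n_par, tolerance = 1e-10)
  expect_equal(f$n_par, 3)
})

test_that("variance accounting matches hand computation and printed totals", {
  # one loaded factor, no specific variance: 100% on factor 1
  fit <- list(Lambda = matrix(c(1, 0, 0), 1, 3), Psi = 0)
  va <- variance_accounted(fit)
  expect_equal(va$factor1, 100)
  expect_equal(va$total, 100)
  # printed per-factor values reproduce the printed totals
  expect_equal(variance_total(rbind(c(40.59, 5.38, 1.21))), 47.18,
               tolerance = 1e-9)
  expect_equal(variance_total(rbind(c(93.05, 6.93, 0.02))), 100.00,
               tolerance = 1e-9)
})

test_that("iClass polarity strings match the published loading triples", {
  L <- table3_loadings()
  ic <- assign_iclasses(L)
  expect_equal(ic$iclass,
               c("PNP", "PNN", "PNN", "PPP", "PNN", "PNP"))
  expect_equal(sort(unique(ic$iclass)), c("PNN", "PNP", "PPP"))
  # zero loading counts as positive polarity
  expect_equal(assign_iclasses(matrix(c(0, -1), 1, 2))$iclass, "PN")
})

test_that("nested covariance structures have non-decreasing REML log-likelihood", {
  E <- 5
  L <- matrix(c(2, 3, 2.5, 2, 3), E, 1)
  Sig <- tcrossprod(L) + diag(rep(1.5, E))
  Y <- simulate_met_data(Sig, 250, seed = 42)
  fd <- fit_met(Y, "DIAG", n_starts = 1)
  fh <- fit_met(Y, "CorH", n_starts = 2)
  f1 <- fit_met(Y, "FA1", n_starts = 2)
  expect_gte(fh$loglik, fd$loglik - 1e-3)
  expect_gte(f1$loglik, fh$loglik - 1e-3)
})

test_that("the restricted likelihood is invariant to factor rotation", {
  E <- 4
  L <- matrix(c(1, 2, 1.5, 0.5, 0.5, -1, 0.8, 0.2), E, 2)
  Psi <- c(0.5, 0.8, 0.3, 0.6)
  Y <- simulate_met_data(tcrossprod(L) + diag(Psi), 60, seed = 43)
  th <- runif(1, 0, 2 * pi)
  Q <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  l1 <- staygreen:::met_reml_loglik(Y, tcrossprod(L) + diag(Psi))
  l2 <- staygreen:::met_reml_loglik(Y, tcrossprod(L %*% Q) + diag(Psi))
  expect_lt(abs(as.numeric(l1) - as.numeric(l2)), 1e-8)
})

test_that("diagonal-covariance data are identified as uncorrelated", {
  res <- lapply(1:3, function(r) {
    Y <- simulate_met_data(diag(c(1, 1.5, 2, 2.5)), 150, seed = 50 + r)
    list(d = fit_met(Y, "DIAG", n_starts = 1),
         h = fit_met(Y, "CorH", n_starts = 1))
  })
  rho <- sapply(res, function(x) {
    R <- stats::cov2cor(x$h$Sigma)
    mean(abs(R[upper.tri(R)]))
  })
  expect_lte(stats::median(rho), 0.1)
  daic <- sapply(res, function(x) x$d$AIC - x$h$AIC)
  expect_lte(stats::median(daic), 2)
})

test_that("a rank-1 + diagonal covariance is recovered by FA1", {
  E <- 6
  L <- matrix(c(4, 5, 3, 6, 4, 4), E, 1)
  Sig <- tcrossprod(L) + diag(rep(2, E))
  Y <- simulate_met_data(Sig, 400, mu = rep(100, E), seed = 44)
  f <- fit_met(Y, "FA1", n_starts = 2)
  expect_lt(norm(f$Sigma - Sig, "F") / norm(Sig, "F"), 0.15)
})

test_that("model selection prefers variance accounted within the AIC window", {
  Y <- simulate_met_data(diag(3) + 1, 100, seed = 45)
  f1 <- fit_met(Y, "FA1", n_starts = 1)
  # single candidate returns itself
  expect_identical(select_met_model(list(f1))$structure, f1$structure)
  # equal AIC: higher %VAF wins
  fa <- f1; fb <- f1
  fa$AIC <- fb$AIC
  fa$Psi <- fa$Psi * 4        # lowers fa's variance accounted
  sel <- select_met_model(list(fa, fb))
  expect_equal(attr(variance_accounted(fb), "overall") >=
                 attr(variance_accounted(fa), "overall"), TRUE)
  expect_identical(sel$Psi, fb$Psi)
  # a far-worse-AIC candidate is excluded even with higher %VAF
  fc <- fb; fc$AIC <- fb$AIC + 100; fc$Psi <- fc$Psi * 0
  expect_identical(select_met_model(list(fb, fc))$AIC, fb$AIC)
})

test_that("the selected factor order matches the simulated rank", {
  hits <- sapply(1:3, function(r) {
    E <- 6
    set.seed(60 + r)
    L <- cbind(c(4, 5, 3, 6, 4, 4), c(2, -2, 1, -1.5, 2, -1))
    Sig <- tcrossprod(L) + diag(rep(1, E))
    Y <- simulate_met_data(Sig, 300, seed = 70 + r)
    fits <- lapply(c("FA1", "FA2", "FA3"), function(s)
      fit_met(Y, s, n_starts = 1, seed = r))
    sel <- select_met_model(fits)
    sel$structure == "FA2"
  })
  expect_gte(mean(hits), 2 / 3)
})

test_that("iClass BLUEs average the predicted environment effects", {
  E <- 4
  L <- cbind(c(3, 3, 2, 2), c(1, 1, -1, -1))
  Sig <- tcrossprod(L) + diag(rep(0.8, E))
  Y <- simulate_met_data(Sig, 200, mu = c(10, 12, 9, 11), seed = 46)
  f <- fit_met(Y, "FA2", n_starts = 2)
  ic <- assign_iclasses(f)
  icb <- iclass_blues(f, ic)
  # single-environment iClass equals that environment's prediction
  one <- names(which(table(ic$iclass) == 1))
  if (length(one)) {
    env1 <- ic$env[ic$iclass == one[1]]
    v <- icb$value[icb$env == one[1]]
    expect_equal(v, unname(f$u[, env1] + f$tau[env1]), tolerance = 1e-10)
  }
  # forcing all environments into one class gives the across-env mean
  all_one <- data.frame(env = f$env, iclass = "ALL")
  icb_all <- iclass_blues(f, all_one)
  expect_equal(icb_all$value,
               unname(rowMeans(f$u + matrix(f$tau, nrow(f$u), E, byrow = TRUE))),
               tolerance = 1e-10)
  # iClass means track the data means over member environments
  for (cl in unique(ic$iclass)) {
    envs <- ic$env[ic$iclass == cl]
    obs_mean <- rowMeans(Y[, envs, drop = FALSE])
    expect_gte(cor(icb$value[icb$env == cl], obs_mean), 0.99)
  }
})

test_that("the VanRaden relationship matrix has the expected structure", {
  # identical genotypes: off-diagonal equals diagonal
  M <- rbind(a = c(0, 2, 2, 0), b = c(0, 2, 2, 0), c = c(2, 0, 0, 2))
  G <- grm_vanraden(M)
  # equal up to the stabilizing ridge on the diagonal
  expect_equal(G["a", "b"], G["a", "a"], tolerance = 1e-4)
  # two opposite homozygotes at p = 0.5: G12 = -G11
  M2 <- rbind(a = rep(0, 6), b = rep(2, 6))
  G2 <- grm_vanraden(M2)
  expect_equal(G2["a", "b"], -G2["a", "a"], tolerance = 1e-4)
  # inbred panel: mean diagonal near 2 (= 1 + inbreeding ~ 1)
  cfg <- sim_config(n_genotypes = 150, blocks_per_chromosome = 10,
                    n_environments = 1, timepoints_per_env = 3,
                    env_names = "E1", het_rate = 0.01, rare_frac = 0,
                    seed = 47)
  g <- simulate_genotypes(cfg)
  G3 <- grm_vanraden(g$genotypes)
  expect_lt(abs(mean(diag(G3)) - 2), 0.1)
  expect_error(grm_vanraden(rbind(a = c(0, 0), b = c(0, 0))), "monomorphic")
})

test_that("genetic and phenotypic correlations are recovered from kinship models", {
  run_one <- function(seed, rho) {
    cfg <- sim_config(n_genotypes = 300, blocks_per_chromosome = 20,
                      n_environments = 1, timepoints_per_env = 3,
                      env_names = "E1", gy_genetic_corr = rho, rare_frac = 0.2,
                      causal_blocks = data.frame(block = "b000001", effect = 0,
                                                 rauc_sign = -1),
                      seed = seed)
    g <- simulate_genotypes(cfg)
    gen <- simulate_trial(g$genotypes, g$truth, cfg)$truth$gen
    G <- grm_vanraden(g$genotypes)
    set.seed(seed + 1)
    h2 <- 0.8
    noise <- function(v) rnorm(length(v), 0, sqrt(stats::var(v) * (1 - h2) / h2))
    y1 <- gen$m_s + noise(gen$m_s); names(y1) <- names(gen$m_s)
    y2 <- gen$m_y + noise(gen$m_y); names(y2) <- names(gen$m_y)
    list(rg = genetic_correlation(y1, y2, G)$r_g, y1 = y1)
  }
  est <- sapply(1:3, function(r) run_one(48 + r, 0.7)$rg)
  expect_lt(abs(stats::median(est) - 0.7), 0.1)
  # identical vectors: phenotypic correlation is exactly one
  y1 <- run_one(48, 0.7)$y1
  expect_equal(phenotypic_correlation(y1, y1), 1)
  # genetically independent traits: correlation near zero
  est0 <- sapply(1:3, function(r) run_one(148 + r, 0)$rg)
  expect_lt(abs(stats::median(est0)), 0.15)
})
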