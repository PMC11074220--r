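test_that("corrected values reconstruct the observations exactly", {
  st <- small_trial(n_genotypes = 60, timepoints = 3, seed = 12)
  d <- st$ndre
  t1 <- sort(unique(d$thermal_time))[2]
  dd <- d[abs(d$thermal_time - t1) < 1e-8, ]
  for (fit in list(fit_spats_timepoint(d, t1), fit_lmm_ar1_timepoint(d, t1))) {
    expect_equal(unname(fit$corrected + fit$spatial), dd$ndre,
                 tolerance = 1e-10)
    expect_true(all(is.finite(fit$corrected)))
    expect_gte(fit$h2, 0); expect_lte(fit$h2, 1)
  }
})

test_that("the estimated surface recovers the simulated field trend", {
  st <- small_trial(n_genotypes = 150, spatial_amplitude = 0.05,
                    residual_sd = 0.02, timepoints = 3, seed = 5)
  d <- st$ndre
  t1 <- sort(unique(d$thermal_time))[2]
  dd <- d[abs(d$thermal_time - t1) < 1e-8, ]
  fs <- fit_spats_timepoint(d, t1)
  expect_gte(cor(fs$surface, st$truth$env$E1$surface[dd$plot]), 0.9)
})

test_that("a null surface is estimated as (near) flat", {
  st <- small_trial(n_genotypes = 60, spatial_amplitude = 0,
                    residual_sd = 0.01, timepoints = 3, seed = 13)
  d <- st$ndre
  t1 <- sort(unique(d$thermal_time))[2]
  fs <- fit_spats_timepoint(d, t1)
  expect_lt(stats::sd(fs$surface), 0.01)
})

test_that("noise-free genotype signal yields heritability near one", {
  st <- small_trial(n_genotypes = 40, spatial_amplitude = 0,
                    residual_sd = 1e-5, timepoints = 3, seed = 14,
                    flight_window = c(1650, 1850), n_flowering_groups = 1)
  d <- st$ndre
  t1 <- sort(unique(d$thermal_time))[2]
  expect_gte(fit_spats_timepoint(d, t1)$h2, 0.99)
  expect_gte(fit_lmm_ar1_timepoint(d, t1)$h2, 0.99)
})

test_that("AR1 parameters fixed at zero reduce to the independent-residual fit", {
  st <- small_trial(n_genotypes = 50, timepoints = 3, seed = 15)
  d <- st$ndre
  t1 <- sort(unique(d$thermal_time))[2]
  dd <- d[abs(d$thermal_time - t1) < 1e-8, ]
  f0 <- fit_lmm_ar1_timepoint(d, t1, fix_rho = c(0, 0))
  X <- stats::model.matrix(~ factor(flowering_group), dd)
  f_iid <- reml_lmm(dd$ndre, X,
                    list(genotype = factor(dd$genotype),
                         rowf = factor(dd$row), colf = factor(dd$col),
                         repf = factor(dd$replicate)))
  expect_lt(abs(f0$loglik - f_iid$loglik), 1e-6)
})

test_that("AR1 residual correlation is recovered on a full grid", {
  err <- replicate(3, {
    seed <- sample.int(1000, 1)
    cfg <- sim_config(n_genotypes = 200, blocks_per_chromosome = 4,
                      n_environments = 1, timepoints_per_env = 3,
                      env_names = "E1", spatial_amplitude = 0,
                      resid_model = "ar1space", spatial_rho = c(0.5, 0.5),
                      residual_sd = 0.03, replicate_fraction = 0.3,
                      field_dims = list(c(20, 13)), seed = seed,
                      flight_window = c(1650, 1850))
    st <- simulate_study(cfg)
    fit <- fit_lmm_ar1_timepoint(st$ndre, sort(unique(st$ndre$thermal_time))[2])
    mean(fit$rho) - 0.5
  })
  expect_lt(abs(stats::median(err)), 0.15)
})

test_that("the spline surface constrained to zero equals the row/column model", {
  st <- small_trial(n_genotypes = 40, timepoints = 3, seed = 16)
  d <- st$ndre
  t1 <- sort(unique(d$thermal_time))[2]
  dd <- d[abs(d$thermal_time - t1) < 1e-8, ]
  f1 <- fit_spats_timepoint(d, t1, engine = "reml", surface = FALSE)
  X <- stats::model.matrix(~ factor(flowering_group), dd)
  f2 <- reml_lmm(dd$ndre, X,
                 list(genotype = factor(dd$genotype),
                      rowf = factor(dd$row), colf = factor(dd$col)))
  expect_lt(abs(f1$loglik - f2$loglik), 1e-6)
})

test_that("generalized heritability follows the PEV formula and its bounds", {
  expect_equal(heritability_generalized(A_tt = 2, gamma_v = 1), 0)
  expect_equal(heritability_generalized(A_tt = 0, gamma_v = 3), 1)
  expect_equal(heritability_generalized(A_tt = 1, gamma_v = 1), 0.5)
  expect_warning(h0 <- heritability_generalized(A_tt = 1, gamma_v = 0))
  expect_equal(h0, 0)
})

test_that("yield heritability and BLUE accuracy are recovered at scale", {
  cfg <- sim_config(n_genotypes = 300, blocks_per_chromosome = 6,
                    n_environments = 1, timepoints_per_env = 3,
                    env_names = "E1", yield_spatial_amplitude = 0.1,
                    replicate_fraction = 0.5, seed = 17)
  st <- simulate_study(cfg)
  yb <- yield_blues(st$yield)
  # configured plot-level yield h2 is 0.8
  expect_lt(abs(attr(yb, "h2") - 0.8), 0.1)
  expect_gte(cor(yb$blue, st$truth$gen$m_y[yb$genotype]), 0.9)
})

test_that("yield BLUEs equal genotype means in a balanced orthogonal design", {
  # 6x6 Latin square: every genotype once per row and column, no trend
  set.seed(18)
  n <- 6
  sq <- outer(1:n, 1:n, function(i, j) ((i + j - 2) %% n) + 1)
  d <- data.frame(row = rep(1:n, n), col = rep(1:n, each = n),
                  replicate = rep(1:2, each = n * n / 2),
                  genotype = sprintf("g%02d", as.vector(sq)),
                  yield = 0)
  gmeans <- stats::setNames(rnorm(n, 4, 0.5), sprintf("g%02d", 1:n))
  d$yield <- gmeans[d$genotype] + rnorm(n * n, 0, 0.1)
  b <- yield_blues(d, ar1 = FALSE)
  obs_means <- tapply(d$yield, d$genotype, mean)
  expect_equal(b$blue, as.numeric(obs_means[b$genotype]), tolerance = 1e-8)
  # translation equivariance: adding a constant shifts every BLUE by it
  d2 <- d; d2$yield <- d$yield + 1.7
  b2 <- yield_blues(d2, ar1 = FALSE)
  expect_equal(b2$blue - b$blue[match(b2$genotype, b$genotype)],
               rep(1.7, n), tolerance = 1e-6)
})

test_that("model selection follows the heritability vote and its tie-breaks", {
  mk <- function(h2s, model) lapply(seq_along(h2s), function(i)
    structure(list(model = model, t = i, h2 = h2s[i]), class = "spatial_fit"))
  # clear 3-0 vote
  sel <- select_spatial_model(mk(c(0.8, 0.7, 0.6), "SpATS"),
                              mk(c(0.5, 0.5, 0.5), "LMM-AR1"))
  expect_equal(sel$model, "SpATS")
  # 2-2 split, higher mean goes to the AR1 model
  sel <- select_spatial_model(mk(c(0.9, 0.8, 0.1, 0.1), "SpATS"),
                              mk(c(0.2, 0.2, 0.85, 0.9), "LMM-AR1"))
  expect_equal(sel$model, "LMM-AR1")
  # full tie goes to SpATS
  sel <- select_spatial_model(mk(c(0.5, 0.6), "SpATS"),
                              mk(c(0.6, 0.5), "LMM-AR1"))
  expect_equal(sel$model, "SpATS")
  expect_error(select_spatial_model(mk(0.5, "SpATS"), list()), "identical")
})

test_that("auto selection returns the vote winner with corrected values", {
  st <- small_trial(n_genotypes = 50, timepoints = 3, seed = 19)
  res <- spatial_correct_trial(st$ndre, model = "auto")
  expect_equal(res$model, res$selection$model)
  expect_equal(nrow(res$corrected), nrow(st$ndre))
  expect_true(all(c("ndre_corrected") %in% names(res$corrected)))
})

test_that("degenerate designs are rejected", {
  st <- small_trial(n_genotypes = 20, timepoints = 3, seed = 20)
  d <- st$ndre
  d1 <- d; d1$genotype <- d1$genotype[1]
  expect_error(fit_spats_timepoint(d1, sort(unique(d$thermal_time))[1]),
               "one genotype")
  d2 <- d; d2$ndre[1] <- NA
  expect_error(fit_spats_timepoint(d2, d2$thermal_time[1]), "non-finite")
  d3 <- d[abs(d$thermal_time - d$thermal_time[1]) < 1e-8, ]
  d3$row[2] <- d3$row[1]; d3$col[2] <- d3$col[1]
  expect_error(fit_lmm_ar1_timepoint(d3), "unique")
})

test_that("increasing noise does not raise the median estimated heritability", {
  meds <- sapply(c(0.01, 0.04, 0.1), function(sd_) {
    h2 <- sapply(1:3, function(r) {
      st <- small_trial(n_genotypes = 60, spatial_amplitude = 0.02,
                        residual_sd = sd_, timepoints = 3,
                        seed = 100 + r, flight_window = c(1650, 1850))
      fit_spats_timepoint(st$ndre, sort(unique(st$ndre$thermal_time))[2])$h2
    })
    stats::median(h2)
  })
  expect_true(all(diff(meds) <= 1e-8))
})
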