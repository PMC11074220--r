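# shared fixtures and independent oracles

# small single-environment study for spatial-stage tests
small_trial <- function(n_genotypes = 80, spatial_amplitude = 0.05,
                        residual_sd = 0.02, timepoints = 4, seed = 5, ...) {
  cfg <- sim_config(n_genotypes = n_genotypes, blocks_per_chromosome = 6,
                    n_environments = 1, timepoints_per_env = timepoints,
                    env_names = "E1", spatial_amplitude = spatial_amplitude,
                    residual_sd = residual_sd, seed = seed, ...)
  simulate_study(cfg)
}

# closed-form ridge oracle: u = (Z'Z + lambda I)^-1 Z'y on centered data
ridge_oracle <- function(M, y, lambda) {
  Z <- scale(M, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  drop(solve(crossprod(Z) + diag(lambda, ncol(Z)), crossprod(Z, yc)))
}

# build a growth_curve_set by hand from a coefficient vector (no deviations)
curve_set_from_coef <- function(basis, coef, genotype = "g1") {
  cg <- matrix(0, basis$K, 1, dimnames = list(NULL, genotype))
  structure(list(basis = basis, coef_pop = coef, coef_geno = cg,
                 coef_indiv = NULL, plot_genotype = NULL,
                 lambda = NULL, sigma2 = 0, loglik = NA_real_,
                 genotypes = genotype, individual = FALSE),
            class = "growth_curve_set")
}

# B-spline coefficients representing a polynomial exactly (collocation at
# distinct points; exact for degree <= basis degree)
poly_coef <- function(basis, f) {
  pts <- seq(basis$domain[1], basis$domain[2], length.out = basis$K)
  # perturb interior points off knots for a well-conditioned system
  B <- basis_eval(basis, pts)
  qr.solve(B, f(pts))
}

# Table of FA loadings printed for the six trials of the stay-green study
# (factors 1-3 of the selected three-factor model)
table3_loadings <- function() {
  L <- rbind(`21CGN` = c(2.72, -1.74, 2.28),
             `21DND` = c(7.99, -2.91, -1.38),
             `22CGN` = c(0.37, -0.37, -0.22),
             `22DND` = c(12.29, 3.35, 0.18),
             `22GAT` = c(3.53, -1.28, -0.25),
             `22YRK` = c(5.49, -1.57, 0.65))
  colnames(L) <- paste0("F", 1:3)
  L
}
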