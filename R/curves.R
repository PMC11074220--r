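#' Hierarchical P-spline growth curves of canopy senescence
#'
#' Stage 2 of the pipeline models spatially corrected NDRE over thermal
#' time with a three-level nested hierarchical P-spline: a population curve
#' (the trial mean trajectory), genotype-level smooth deviations, and
#' individual (plot) smooth deviations, each with its own REML-estimated
#' smoothing.  Curves at every level are plain B-spline coefficient
#' vectors, so derivatives and integrals are available analytically.
#'
#' @name growth_curves
NULL

# Sparse penalized least squares in mixed-model form.  The population
# penalty null space (constant + linear) is fixed; every other coefficient
# is a proper random effect after a Demmler-Reinsch rotation of the
# difference penalty, so the restricted likelihood is available in closed
# form from one sparse Cholesky factorization per smoothing candidate.

#' Fit the three-level hierarchical growth model
#'
#' @param data data.frame with columns \code{thermal_time}, \code{value}
#'   (spatially corrected NDRE), \code{genotype} and \code{plot}, for a
#'   single population (typically one trial).
#' @param basis optional \code{\link{spline_basis}}; by default a cubic
#'   basis with a second-order difference penalty and \code{n_knots}
#'   interior knots on the observed thermal-time range.
#' @param n_knots interior knots of the default (population-level) basis.
#' @param dev_knots interior knots of the deviation-level basis; by
#'   default the largest of 7, 3, 1 not exceeding the number of distinct
#'   timepoints minus two, so sparsely flown trials get deviation curves
#'   their data can support (the knots nest inside the population basis,
#'   so deviation coefficients convert exactly to population-basis
#'   coefficients).
#' @param individual include the plot-level deviation smooths (default);
#'   disable for strictly genotype-level fits.
#' @param control list with optimizer settings (\code{maxit}).
#' @return a \code{growth_curve_set}: B-spline coefficients of the
#'   population curve, per-genotype and per-plot deviations, smoothing
#'   parameters, residual variance and restricted log-likelihood.
#' @export
fit_hierarchical_curves <- function(data, basis = NULL, n_knots = 7,
                                    dev_knots = NULL, individual = TRUE,
                                    control = list(maxit = 400)) {
  d <- as.data.frame(data)
  need <- c("thermal_time", "value", "genotype")
  if (!all(need %in% names(d)))
    stopf("data must have columns %s", paste(need, collapse = ", "))
  if (!"plot" %in% names(d)) d$plot <- paste0(d$genotype, "_1")
  if (any(!is.finite(d$value)) || any(!is.finite(d$thermal_time)))
    stopf("non-finite values in growth-curve input")
  ts <- sort(unique(d$thermal_time))
  if (length(ts) < 3) stopf("need >= 3 distinct timepoints to fit curves")
  if (is.null(basis)) {
    pad <- 0.001 * diff(range(ts))
    basis <- spline_basis(range(ts) + c(-pad, pad), n_knots = n_knots)
  }
  K <- basis$K
  n <- nrow(d)
  geno <- factor(d$genotype)
  plotf <- factor(d$plot)
  G <- nlevels(geno)
  P <- nlevels(plotf)
  use_ind <- individual && P > G
  nt <- length(ts)

  # deviation-level basis: nested knots, sized to the flight count
  if (is.null(dev_knots)) {
    cand <- c(7, 3, 1)
    dev_knots <- cand[cand <= max(1, nt - 2)][1]
    if (is.na(dev_knots)) dev_knots <- 1
  }
  dev_knots <- min(dev_knots, basis$n_knots)
  basis_dev <- spline_basis(basis$domain, n_knots = dev_knots,
                            degree = basis$degree,
                            penalty_order = basis$penalty_order)
  Kd <- basis_dev$K

  B <- basis_eval(basis, d$thermal_time)
  ep <- eigen(basis$P, symmetric = TRUE)
  ord <- order(ep$values)                     # null space first
  U <- ep$vectors[, ord]
  dvals <- pmax(ep$values[ord], 0)
  null_dim <- basis$penalty_order
  wig <- (null_dim + 1):K
  BU <- B %*% U

  Bd <- basis_eval(basis_dev, d$thermal_time)
  epd <- eigen(basis_dev$P, symmetric = TRUE)
  ordd <- order(epd$values)
  Ud <- epd$vectors[, ordd]
  dvals_d <- pmax(epd$values[ordd], 0)
  BUd <- Bd %*% Ud

  X <- cbind(1, d$thermal_time)
  p_fix <- 2L
  # population wiggle columns, scaled so the prior is iid
  Zpop <- BU[, wig, drop = FALSE] %*% diag(1 / sqrt(dvals[wig]))

  sparse_level <- function(fac) {
    i <- rep(seq_len(n), Kd)
    j <- rep((as.integer(fac) - 1L) * Kd, Kd) + rep(seq_len(Kd), each = n)
    Matrix::sparseMatrix(i = i, j = j, x = as.vector(BUd),
                         dims = c(n, nlevels(fac) * Kd))
  }
  Zg <- sparse_level(geno)
  Zi <- if (use_ind) sparse_level(plotf) else NULL

  A <- cbind(Matrix::Matrix(cbind(X, Zpop), sparse = TRUE), Zg,
             if (use_ind) Zi)
  AtA <- Matrix::crossprod(A)
  Aty <- Matrix::crossprod(A, d$value)
  yty <- sum(d$value^2)
  q_pop <- K - null_dim
  idx_pop <- p_fix + seq_len(q_pop)
  idx_g <- p_fix + q_pop + seq_len(G * Kd)
  idx_i <- if (use_ind) p_fix + q_pop + G * Kd + seq_len(P * Kd)

  sdiag <- function(lam) {
    # prior precisions for [pop wiggle | genotype coefs | plot coefs]
    pg <- lam["g_wig"] * dvals_d + lam["g_null"]
    out <- c(rep(0, p_fix), rep(lam["pop"], q_pop), rep(pg, G))
    if (use_ind) out <- c(out, rep(lam["i_wig"] * dvals_d + lam["i_null"], P))
    out
  }

  chol_template <- NULL
  neg2reml <- function(lpar, details = FALSE) {
    lam <- exp(lpar)
    names(lam) <- par_names
    sd_ <- sdiag(lam)
    M <- AtA + Matrix::Diagonal(x = sd_)
    ch <- tryCatch({
      if (is.null(chol_template))
        chol_template <<- Matrix::Cholesky(M, LDL = FALSE, perm = TRUE)
      update(chol_template, M)
    }, error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    ldM <- sum(log(diag(ch)))   # diag(CHMfactor) gives the squared L diagonal
    b <- Matrix::solve(ch, Aty, system = "A")
    r <- yty - sum(Aty * b)
    if (r <= 0) r <- max(r, 1e-12 * yty, 1e-300)
    sigma2 <- r / (n - p_fix)
    ldS <- sum(log(sd_[-seq_len(p_fix)]))
    val <- (n - p_fix) * log(2 * pi * sigma2) + (n - p_fix) - ldS + ldM
    if (!is.finite(val)) return(1e10)
    if (!details) return(val)
    list(val = val, b = as.numeric(b), sigma2 = sigma2, lam = lam, ch = ch)
  }

  par_names <- c("pop", "g_wig", "g_null", if (use_ind) c("i_wig", "i_null"))
  np <- length(par_names)
  if (!is.null(control$lambda_fixed)) {
    lf <- log(control$lambda_fixed[par_names])
    op <- list(par = lf, value = neg2reml(lf))
  } else {
  op <- NULL
  for (start in list(rep(0, np), rep(4, np))) {
    cand <- suppressWarnings(
      stats::optim(stats::setNames(start, par_names), neg2reml,
                   method = "L-BFGS-B", lower = -20, upper = 20,
                   control = list(maxit = control$maxit %||% 400,
                                  factr = 1e9)))
    if (is.null(op) || cand$value < op$value) op <- cand
  }
  }
  fit <- neg2reml(op$par, details = TRUE)
  b <- fit$b

  grev <- greville(basis)
  coef_pop <- b[1] + b[2] * grev +
    drop(U[, wig, drop = FALSE] %*% (b[idx_pop] / sqrt(dvals[wig])))
  # exact change of basis: deviation knots nest inside the population
  # knots, so collocation at the population Greville points is exact
  Conv <- solve(basis_eval(basis, grev), basis_eval(basis_dev, grev))
  coef_g <- Conv %*% Ud %*% matrix(b[idx_g], Kd, G)
  colnames(coef_g) <- levels(geno)
  coef_i <- if (use_ind) {
    ci <- Conv %*% Ud %*% matrix(b[idx_i], Kd, P)
    colnames(ci) <- levels(plotf)
    ci
  }
  plot_geno <- stats::setNames(
    as.character(d$genotype[!duplicated(d$plot)]),
    as.character(d$plot[!duplicated(d$plot)]))

  structure(list(basis = basis, coef_pop = coef_pop, coef_geno = coef_g,
                 coef_indiv = coef_i, plot_genotype = plot_geno,
                 lambda = fit$lam, sigma2 = fit$sigma2,
                 loglik = -fit$val / 2, genotypes = levels(geno),
                 individual = use_ind),
            class = "growth_curve_set")
}

# total B-spline coefficients of a genotype (or plot-level) curve
curve_coef <- function(curves, genotype = NULL, plot = NULL) {
  co <- curves$coef_pop
  if (!is.null(genotype)) {
    if (!genotype %in% colnames(curves$coef_geno))
      stopf("unknown genotype '%s'", genotype)
    co <- co + curves$coef_geno[, genotype]
  }
  if (!is.null(plot)) {
    if (is.null(curves$coef_indiv) || !plot %in% colnames(curves$coef_indiv))
      stopf("no individual-level curve for plot '%s'", plot)
    co <- co + curves$coef_geno[, curves$plot_genotype[plot]] +
      curves$coef_indiv[, plot]
  }
  co
}

#' Evaluate fitted growth curves
#'
#' @param object a \code{growth_curve_set}.
#' @param t thermal times.
#' @param genotype genotype id (\code{NULL} for the population curve).
#' @param plot plot id for the individual-level curve.
#' @param deriv derivative order (0 or 1).
#' @param ... unused.
#' @return numeric vector of curve values.
#' @export
predict.growth_curve_set <- function(object, t, genotype = NULL, plot = NULL,
                                     deriv = 0, ...) {
  co <- curve_coef(object, genotype, plot)
  if (deriv == 0) drop(basis_eval(object$basis, t) %*% co)
  else spline_derivative(object$basis, co)$eval(t)
}

#' Analytic first derivative of a fitted curve
#'
#' Returns the senescence-rate curve as an exact B-spline derivative (one
#' degree lower, same knots) of the fitted genotype curve.
#'
#' @param curves a \code{growth_curve_set}.
#' @param genotype genotype id (\code{NULL} for the population curve).
#' @return list with the derivative coefficients and an \code{eval(t)}
#'   function.
#' @export
curve_first_derivative <- function(curves, genotype = NULL) {
  spline_derivative(curves$basis, curve_coef(curves, genotype))
}

#' Extract stay-green traits from fitted curves
#'
#' Per genotype, over the grain-filling window \code{[a, b]}:
#' \code{scsAUC}, the area under the fitted NDRE curve; \code{d1AUC}, the
#' (signed) area under the first derivative, identically
#' \code{f(b) - f(a)}; \code{rAUC}, the area under the absolute senescence
#' rate (so larger values mean more total senescence; the signed variant is
#' reported as \code{rAUC_signed}); and \code{mean_rate = rAUC / (b - a)}.
#' All integrals are computed exactly from the B-spline coefficients.
#'
#' @param curves a \code{growth_curve_set}.
#' @param window numeric length-2 thermal-time interval inside the fitted
#'   domain.
#' @param env optional environment label attached to the output.
#' @return a trait table: one row per (genotype, trait).
#' @export
extract_traits <- function(curves, window, env = NA_character_) {
  if (length(window) != 2 || window[2] <= window[1])
    stopf("window must be an interval (a, b) with b > a")
  dom <- curves$basis$domain
  if (window[1] < dom[1] - 1e-8 || window[2] > dom[2] + 1e-8)
    stopf("window [%g, %g] outside fitted domain [%g, %g]",
          window[1], window[2], dom[1], dom[2])
  a <- max(window[1], dom[1]); b <- min(window[2], dom[2])
  rows <- lapply(curves$genotypes, function(g) {
    co <- curve_coef(curves, g)
    f_ab <- drop(basis_eval(curves$basis, c(a, b)) %*% co)
    scs <- spline_integral(curves$basis, co, a, b)
    d1 <- f_ab[2] - f_ab[1]
    rabs <- spline_abs_deriv_integral(curves$basis, co, a, b)
    data.frame(genotype = g, env = env,
               trait = c("scsAUC", "d1AUC", "rAUC", "rAUC_signed", "mean_rate"),
               value = c(scs, d1, rabs, d1, rabs / (b - a)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fit growth curves and extract traits for every trial
#'
#' @param corrected corrected NDRE long table (column
#'   \code{ndre_corrected}) across trials.
#' @param window grain-filling window; \code{NULL} uses each trial's
#'   observed range.
#' @param ... passed to \code{\link{fit_hierarchical_curves}}.
#' @return list with per-trial \code{growth_curve_set}s and the combined
#'   trait table.
#' @export
growth_curves_by_trial <- function(corrected, window = NULL, ...) {
  trials <- unique(corrected$trial)
  sets <- list(); traits <- list()
  for (tr in trials) {
    d <- corrected[corrected$trial == tr, , drop = FALSE]
    dd <- data.frame(thermal_time = d$thermal_time,
                     value = d$ndre_corrected, genotype = d$genotype,
                     plot = d$plot)
    set <- fit_hierarchical_curves(dd, ...)
    w <- window %||% set$basis$domain
    w <- c(max(w[1], set$basis$domain[1]), min(w[2], set$basis$domain[2]))
    sets[[tr]] <- set
    traits[[tr]] <- extract_traits(set, w, env = tr)
  }
  list(curves = sets, traits = do.call(rbind, traits))
}
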