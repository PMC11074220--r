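#' Linear mixed model by dense REML with optional separable AR1 residuals
#'
#' A direct restricted-maximum-likelihood fitter for the plot-level models
#' used in stage-1 spatial analysis: fixed effects, any number of iid random
#' effect terms (genotype, row, column, replicate), and either independent
#' residuals or a separable first-order autoregressive correlation over the
#' field grid, \eqn{corr(e_i, e_j) = \rho_r^{|row_i - row_j|}
#' \rho_c^{|col_i - col_j|}}.  The variance ratios are profiled against the
#' residual variance and maximized numerically.
#'
#' @param y numeric response (one value per plot).
#' @param X fixed-effect design matrix (aliased columns are dropped).
#' @param random named list of factors (or design matrices) for iid random
#'   intercept terms.
#' @param resid either \code{list(type = "iid")} or
#'   \code{list(type = "ar1xar1", row = <integer>, col = <integer>)} giving
#'   1-based grid indices per observation.
#' @param fix_rho optional length-2 numeric fixing the AR1 parameters
#'   (e.g. \code{c(0, 0)} collapses to the independent-residual model).
#' @param pev_term name of the random term for which the prediction error
#'   variance matrix is returned (default \code{"genotype"} when present).
#' @param n_starts number of optimizer starts.
#' @return an object of class \code{staygreen_lmm}.
#' @export
reml_lmm <- function(y, X, random, resid = list(type = "iid"),
                     fix_rho = NULL, fix_gamma = NULL, pev_term = NULL,
                     n_starts = 1L) {
  y <- as.numeric(y)
  n <- length(y)
  X <- as.matrix(X)
  stopifnot(nrow(X) == n)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  p <- ncol(X)
  if (n - p < 1) stopf("degenerate design: no residual degrees of freedom")

  Zs <- lapply(random, function(z) {
    if (is.factor(z) || is.character(z)) {
      f <- factor(z)
      M <- stats::model.matrix(~ f - 1)
      colnames(M) <- levels(f)
      M
    } else as.matrix(z)
  })
  K <- length(Zs)
  ZZt <- lapply(Zs, tcrossprod)

  fixed_idx <- if (is.null(fix_gamma)) integer(0) else
    match(names(fix_gamma), names(Zs))
  if (anyNA(fixed_idx)) stopf("fix_gamma names must match random terms")
  free_idx <- setdiff(seq_len(K), fixed_idx)

  ar1 <- identical(resid$type, "ar1xar1")
  if (ar1) {
    dr <- abs(outer(resid$row, resid$row, `-`))
    dc <- abs(outer(resid$col, resid$col, `-`))
  }
  n_rho <- if (ar1 && is.null(fix_rho)) 2L else 0L

  build_R <- function(rho) {
    if (!ar1) return(diag(n))
    (rho[1]^dr) * (rho[2]^dc)
  }

  nfree <- length(free_idx)
  neg2reml <- function(par, details = FALSE) {
    gam <- numeric(K)
    gam[free_idx] <- exp(par[seq_len(nfree)])
    gam[fixed_idx] <- unlist(fix_gamma)
    rho <- if (ar1) {
      if (is.null(fix_rho)) tanh(par[nfree + 1:2]) * 0.98 else fix_rho
    } else c(0, 0)
    V0 <- build_R(rho)
    for (k in seq_len(K)) V0 <- V0 + gam[k] * ZZt[[k]]
    ch <- tryCatch(chol(V0), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    ldV <- 2 * sum(log(diag(ch)))
    ViX <- backsolve(ch, forwardsolve(t(ch), X))
    Viy <- backsolve(ch, forwardsolve(t(ch), y))
    XtViX <- crossprod(X, ViX)
    chx <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(chx)) return(1e10)
    XtViy <- crossprod(X, Viy)
    beta <- backsolve(chx, forwardsolve(t(chx), XtViy))
    yPy <- sum(y * Viy) - sum(XtViy * beta)
    if (yPy <= 0) return(1e10)
    sigma2 <- yPy / (n - p)
    val <- (n - p) * log(2 * pi * sigma2) + ldV +
      2 * sum(log(diag(chx))) + (n - p)
    if (!details) return(val)
    list(val = val, gam = gam, rho = rho, sigma2 = sigma2, beta = drop(beta),
         V0 = V0, ch = ch, chx = chx, ViX = ViX, Viy = Viy)
  }

  starts <- list(rep(log(0.1), nfree), rep(log(1), nfree))
  if (n_starts > 2) for (s in 3:n_starts) starts[[s]] <- stats::rnorm(nfree, -1, 1)
  starts <- lapply(starts[seq_len(max(1, min(n_starts, length(starts))))],
                   function(s) c(s, rep(0, n_rho)))
  best <- NULL
  if (nfree + n_rho == 0) {
    best <- list(par = numeric(0), value = neg2reml(numeric(0)))
  } else {
    for (st in starts) {
      op <- suppressWarnings(
        stats::optim(st, neg2reml, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-10)))
      if (is.null(best) || op$value < best$value) best <- op
    }
    polish <- tryCatch(suppressWarnings(
      stats::optim(best$par, neg2reml, method = "BFGS",
                   control = list(maxit = 200, reltol = 1e-12))),
      error = function(e) NULL)
    if (!is.null(polish) && polish$value < best$value) best <- polish
  }
  fit <- neg2reml(best$par, details = TRUE)

  # BLUPs and the PEV matrix for the requested term
  r <- y - drop(X %*% fit$beta)
  Vir <- backsolve(fit$ch, forwardsolve(t(fit$ch), r))
  blups <- lapply(seq_len(K), function(k) {
    u <- fit$gam[k] * drop(crossprod(Zs[[k]], Vir))
    names(u) <- colnames(Zs[[k]])
    u
  })
  names(blups) <- names(Zs)

  if (is.null(pev_term) && "genotype" %in% names(Zs)) pev_term <- "genotype"
  pev <- NULL
  if (!is.null(pev_term) && pev_term %in% names(Zs)) {
    k <- match(pev_term, names(Zs))
    Z <- Zs[[k]]
    ViZ <- backsolve(fit$ch, forwardsolve(t(fit$ch), Z))
    XtViZ <- crossprod(X, ViZ)
    W <- backsolve(fit$chx, forwardsolve(t(fit$chx), XtViZ))
    ZP0Z <- crossprod(Z, ViZ) - crossprod(XtViZ, W)
    g <- fit$gam[k]
    pev <- fit$sigma2 * (g * diag(ncol(Z)) - g^2 * ZP0Z)
    dimnames(pev) <- list(colnames(Z), colnames(Z))
  }

  varcomp <- fit$sigma2 * fit$gam
  names(varcomp) <- names(Zs)
  structure(list(loglik = -best$value / 2, n = n, p = p,
                 beta = stats::setNames(fit$beta, colnames(X)),
                 sigma2 = fit$sigma2, varcomp = varcomp,
                 rho = if (ar1) fit$rho else NULL,
                 blups = blups, pev = pev, pev_term = pev_term,
                 fitted_fixed = drop(X %*% fit$beta),
                 X = X, Zs = Zs, residual = resid$type),
            class = "staygreen_lmm")
}

# Average pairwise prediction error variance of differences between the
# levels of a random term (the quantity entering generalized heritability).
mean_pairwise_pev <- function(pev) {
  q <- nrow(pev)
  if (q < 2) return(2 * mean(diag(pev)))
  2 * (q * sum(diag(pev)) - sum(pev)) / (q * (q - 1))
}

#' Generalized (prediction-error-variance based) heritability
#'
#' Computes \eqn{h^2_g = 1 - A_{tt} / (2 \gamma_v)}, where \eqn{A_{tt}} is
#' the average prediction error variance of genotype-difference BLUPs and
#' \eqn{\gamma_v} the genetic variance.  The result is clipped to
#' \code{[0, 1]}; a zero genetic variance returns 0 with a warning.
#'
#' @param fit a \code{staygreen_lmm} with genotype fitted as random, or
#'   \code{NULL} if \code{A_tt} and \code{gamma_v} are supplied directly.
#' @param A_tt,gamma_v optional direct inputs to the formula.
#' @return heritability in \code{[0, 1]}.
#' @export
heritability_generalized <- function(fit = NULL, A_tt = NULL, gamma_v = NULL) {
  if (!is.null(fit)) {
    if (is.null(fit$pev)) stopf("fit carries no PEV matrix for genotype")
    A_tt <- mean_pairwise_pev(fit$pev)
    gamma_v <- unname(fit$varcomp[fit$pev_term])
  }
  if (gamma_v <= 0) {
    warnf("genetic variance is zero; heritability reported as 0")
    return(0)
  }
  min(1, max(0, 1 - A_tt / (2 * gamma_v)))
}
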