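#' Multi-environment covariance modeling of stay-green traits
#'
#' The second-stage MET analysis treats each genotype's vector of
#' environment BLUEs as an iid draw from \eqn{N(\tau, \Sigma)} (spatial
#' correction has already been done, so no trial-specific design effects
#' enter) and estimates the across-environment genetic covariance
#' \eqn{\Sigma} by REML under several structures: diagonal (DIAG), a
#' common correlation with homogeneous (CorV) or heterogeneous (CorH)
#' variances, and factor-analytic FA(k) with \eqn{\Sigma = \Lambda\Lambda'
#' + \Psi}.  Missing genotype-by-environment cells are marginalized out of
#' the likelihood.
#'
#' @name met_analysis
NULL

met_par_count <- function(structure, E, k = 0) {
  switch(structure,
         DIAG = E,
         CorV = 2,
         CorH = E + 1,
         FA = E * k - k * (k - 1) / 2 + E,
         stopf("unknown structure '%s'", structure))
}

# map unconstrained parameters to Sigma per structure
met_build_sigma <- function(structure, par, E, k = 0) {
  lo <- -0.99 / (E - 1)          # lower bound keeping CorV/CorH PSD
  if (structure == "DIAG") {
    diag(exp(par[seq_len(E)]), E)
  } else if (structure == "CorV") {
    s2 <- exp(par[1])
    rho <- lo + (0.999 - lo) * stats::plogis(par[2])
    s2 * ((1 - rho) * diag(E) + rho)
  } else if (structure == "CorH") {
    s <- exp(par[seq_len(E)] / 2)
    rho <- lo + (0.999 - lo) * stats::plogis(par[E + 1])
    R <- matrix(rho, E, E); diag(R) <- 1
    diag(s) %*% R %*% diag(s)
  } else { # FA(k)
    L <- matrix(0, E, k)
    L[!upper.tri(matrix(0, E, k))] <- par[seq_len(E * k - k * (k - 1) / 2)]
    psi <- exp(par[(E * k - k * (k - 1) / 2) + seq_len(E)])
    tcrossprod(L) + diag(psi, E)
  }
}

met_extract <- function(structure, par, E, k = 0) {
  if (structure != "FA") return(list(Sigma = met_build_sigma(structure, par, E, k)))
  nL <- E * k - k * (k - 1) / 2
  L <- matrix(0, E, k)
  L[!upper.tri(matrix(0, E, k))] <- par[seq_len(nL)]
  psi <- exp(par[nL + seq_len(E)])
  list(Sigma = tcrossprod(L) + diag(psi, E), Lambda = L, Psi = psi)
}

# restricted log-likelihood of iid genotype rows under N(tau, Sigma) with
# missing cells; tau profiled by GLS, with the REML determinant adjustment.
met_reml_loglik <- function(Y, Sigma) {
  E <- ncol(Y)
  obs <- !is.na(Y)
  pat <- apply(obs, 1, function(o) paste(as.integer(o), collapse = ""))
  ll <- 0
  XtViX <- matrix(0, E, E)
  XtViy <- numeric(E)
  quads <- list()
  n_obs <- 0L
  for (p in unique(pat)) {
    rows <- which(pat == p)
    o <- obs[rows[1], ]
    if (!any(o)) next
    S <- Sigma[o, o, drop = FALSE]
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    Si <- chol2inv(ch)
    Yp <- Y[rows, o, drop = FALSE]
    n_obs <- n_obs + length(rows) * sum(o)
    ll <- ll - length(rows) * sum(log(diag(ch)))
    XtViX[o, o] <- XtViX[o, o] + length(rows) * Si
    XtViy[o] <- XtViy[o] + colSums(Yp %*% Si)
    quads[[p]] <- list(rows = rows, o = o, Si = Si, Yp = Yp)
  }
  chx <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(chx)) return(-Inf)
  tau <- backsolve(chx, forwardsolve(t(chx), XtViy))
  qsum <- 0
  for (q in quads) {
    Rc <- sweep(q$Yp, 2, tau[q$o])
    qsum <- qsum + sum((Rc %*% q$Si) * Rc)
  }
  ll <- ll - qsum / 2 - sum(log(diag(chx))) -
    (n_obs - E) / 2 * log(2 * pi)
  attr(ll, "tau") <- tau
  ll
}

# moment-based starting values per structure
met_start <- function(structure, Y, E, k, jitter = 0) {
  S <- stats::cov(Y, use = "pairwise.complete.obs")
  S[!is.finite(S)] <- 0
  v <- pmax(diag(S), 1e-4)
  par <- if (structure == "DIAG") log(v)
  else if (structure == "CorV") {
    r <- mean(stats::cov2cor(S + diag(1e-6, E))[upper.tri(S)], na.rm = TRUE)
    c(log(mean(v)), stats::qlogis(min(0.95, max(0.05, (r + 0.2) / 1.2))))
  } else if (structure == "CorH") {
    r <- mean(stats::cov2cor(S + diag(1e-6, E))[upper.tri(S)], na.rm = TRUE)
    c(log(v), stats::qlogis(min(0.95, max(0.05, (r + 0.2) / 1.2))))
  } else {
    e <- eigen(S, symmetric = TRUE)
    L <- e$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(pmax(e$values[seq_len(k)], 1e-4)), k)
    psi <- pmax(v - rowSums(L^2), 0.05 * v)
    c(L[!upper.tri(L)], log(psi))
  }
  par + stats::rnorm(length(par), 0, jitter)
}

#' Fit a MET covariance structure by REML
#'
#' @param blues either a trait table (columns \code{genotype}, \code{env},
#'   \code{value}) or a genotype x environment matrix (NAs allowed).
#' @param structure one of \code{"DIAG"}, \code{"CorV"}, \code{"CorH"},
#'   \code{"FA1"} .. \code{"FA5"} (or \code{"FA"} with \code{k}).
#' @param k number of factors for \code{structure = "FA"}.
#' @param n_starts optimizer starts (first is moment-based, the rest
#'   jittered).
#' @param seed seed for the jittered starts.
#' @return a \code{met_fit}: estimated \code{Sigma}, FA loadings
#'   \code{Lambda} (SVD-rotated, sign convention: the largest-magnitude
#'   entry of each factor is positive) and specific variances \code{Psi},
#'   REML log-likelihood, \code{AIC} with the documented parameter count,
#'   environment means \code{tau}, genotype effect predictions \code{u}
#'   (all environments), factor scores \code{scores} and residuals
#'   \code{delta}.
#' @export
fit_met <- function(blues, structure = "FA3", k = NULL, n_starts = 3,
                    seed = 1) {
  Y <- met_as_matrix(blues)
  E <- ncol(Y)
  if (E < 2) stopf("MET analysis needs >= 2 environments")
  vy <- apply(Y, 2, stats::var, na.rm = TRUE)
  if (any(vy < 1e-10))
    stopf("environment(s) with (near) zero variance: %s",
          paste(colnames(Y)[vy < 1e-10], collapse = ", "))
  if (grepl("^FA[0-9]+$", structure)) {
    k <- as.integer(sub("^FA", "", structure))
    structure <- "FA"
  }
  if (structure == "FA") {
    if (is.null(k)) stopf("FA structure needs a factor count k")
    if (k >= E) stopf("FA(%d) with %d environments is not identifiable", k, E)
  }
  tag <- if (structure == "FA") paste0("FA", k) else structure

  objective <- function(par) {
    Sg <- met_build_sigma(structure, par, E, k %||% 0)
    ll <- met_reml_loglik(Y, Sg)
    if (!is.finite(ll)) return(1e10)
    -as.numeric(ll)
  }
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    st <- met_start(structure, Y, E, k %||% 0,
                    jitter = if (s == 1) 0 else 0.4)
    op <- tryCatch(suppressWarnings(
      stats::optim(st, objective, method = "BFGS",
                   control = list(maxit = 300, reltol = 1e-10))),
      error = function(e) NULL)
    if (is.null(op)) next
    op <- suppressWarnings(
      stats::optim(op$par, objective, method = "Nelder-Mead",
                   control = list(maxit = 800, reltol = 1e-10)))
    if (is.null(best) || op$value < best$value) best <- op
  }
  if (is.null(best)) stopf("all optimizer starts failed for %s", tag)
  converged <- best$value < 1e9
  ex <- met_extract(structure, best$par, E, k %||% 0)
  Sigma <- ex$Sigma
  dimnames(Sigma) <- list(colnames(Y), colnames(Y))
  ll <- met_reml_loglik(Y, Sigma)
  tau <- stats::setNames(attr(ll, "tau"), colnames(Y))
  npar <- met_par_count(structure, E, k %||% 0)
  aic <- -2 * as.numeric(ll) + 2 * npar

  Lambda <- Psi <- NULL
  if (structure == "FA") {
    # rotate to principal orientation; flip each factor so its
    # largest-magnitude loading is positive (iClass polarity convention)
    sv <- svd(ex$Lambda)
    Lambda <- sv$u %*% diag(sv$d, k)
    for (j in seq_len(k)) {
      i <- which.max(abs(Lambda[, j]))
      if (Lambda[i, j] < 0) Lambda[, j] <- -Lambda[, j]
    }
    rownames(Lambda) <- colnames(Y)
    Psi <- stats::setNames(ex$Psi, colnames(Y))
  }

  # genotype effect predictions for all environments (conditional means),
  # factor scores and residuals
  u <- matrix(NA_real_, nrow(Y), E, dimnames = dimnames(Y))
  for (g in seq_len(nrow(Y))) {
    o <- !is.na(Y[g, ])
    if (!any(o)) next
    Si <- solve(Sigma[o, o, drop = FALSE])
    u[g, ] <- Sigma[, o, drop = FALSE] %*% Si %*% (Y[g, o] - tau[o])
  }
  scores <- delta <- NULL
  if (!is.null(Lambda)) {
    # regression factor scores from the predicted effects
    Wt <- t(Lambda) %*% solve(Sigma)
    scores <- t(Wt %*% t(u))
    colnames(scores) <- paste0("F", seq_len(k))
    delta <- u - scores %*% t(Lambda)
  }

  res <- list(structure = tag, env = colnames(Y), Sigma = Sigma,
              Lambda = Lambda, Psi = Psi, loglik = as.numeric(ll),
              AIC = aic, n_par = npar, tau = tau, u = u,
              scores = scores, delta = delta, converged = converged,
              n_genotypes = nrow(Y))
  class(res) <- "met_fit"
  res
}

met_as_matrix <- function(blues) {
  if (is.matrix(blues)) return(blues)
  d <- as.data.frame(blues)
  stopifnot(all(c("genotype", "env", "value") %in% names(d)))
  stats::xtabs(value ~ genotype + env, data = d, addNA = FALSE) ->
    tab
  Y <- matrix(NA_real_, nrow(tab), ncol(tab), dimnames = dimnames(tab))
  cnt <- stats::xtabs(~ genotype + env, data = d)
  Y[cnt > 0] <- tab[cnt > 0] / cnt[cnt > 0]
  Y
}

#' Per-environment variance accounted for by each factor
#'
#' For environment j and factor k the share is
#' \eqn{100 \lambda_{jk}^2 / (\sum_k \lambda_{jk}^2 + \psi_j)}; the total
#' column is the sum over factors and the overall percentage is the mean of
#' the totals over environments.
#'
#' @param fit a \code{met_fit} with an FA structure, or a list with
#'   \code{Lambda} and \code{Psi}.
#' @return data.frame with one row per environment, per-factor percentages,
#'   and the total; overall \%VAF as attribute \code{"overall"}.
#' @export
variance_accounted <- function(fit) {
  if (is.null(fit$Lambda)) stopf("variance accounting needs an FA fit")
  L <- as.matrix(fit$Lambda)
  psi <- fit$Psi
  denom <- rowSums(L^2) + psi
  if (any(denom == 0)) {
    warnf("environment with zero loadings and zero specific variance; reported as 0")
    denom[denom == 0] <- Inf
  }
  shares <- 100 * L^2 / denom
  out <- data.frame(env = rownames(L) %||% paste0("E", seq_len(nrow(L))),
                    shares, total = variance_total(shares),
                    row.names = NULL)
  names(out)[1 + seq_len(ncol(L))] <- paste0("factor", seq_len(ncol(L)))
  attr(out, "overall") <- mean(out$total)
  out
}

#' Total variance accounted from per-factor percentages
#'
#' The total-variance column of the FA summary is the plain sum of the
#' per-factor percentages for each environment.
#'
#' @param shares matrix or data.frame of per-factor percentages (rows =
#'   environments).
#' @return numeric vector of totals.
#' @export
variance_total <- function(shares) {
  rowSums(as.matrix(shares))
}

#' Interaction classes from factor-loading polarity
#'
#' Each environment is labelled by the string of loading signs over the
#' factors ('P' for a non-negative loading, 'N' for negative); environments
#' sharing a string form one iClass.
#'
#' @param fit a \code{met_fit} with FA structure, or a loading matrix.
#' @return data.frame with environment, polarity string and iClass id.
#' @export
assign_iclasses <- function(fit) {
  L <- if (is.matrix(fit)) fit else fit$Lambda
  if (is.null(L) || ncol(L) < 1) stopf("iClasses need an FA fit with >= 1 factor")
  pol <- apply(L, 1, function(r) paste(ifelse(r >= 0, "P", "N"), collapse = ""))
  data.frame(env = rownames(L) %||% paste0("E", seq_len(nrow(L))),
             iclass = unname(pol),
             stringsAsFactors = FALSE)
}

#' Per-iClass genotype BLUEs
#'
#' Averages the model-predicted environment-level genotype effects (plus
#' environment means) over the environments of each iClass.
#'
#' @param fit a converged \code{met_fit}.
#' @param assignment output of \code{\link{assign_iclasses}}.
#' @return trait table with one row per (genotype, iClass).
#' @export
iclass_blues <- function(fit, assignment = assign_iclasses(fit)) {
  out <- list()
  for (ic in unique(assignment$iclass)) {
    envs <- assignment$env[assignment$iclass == ic]
    envs <- intersect(envs, colnames(fit$u))
    if (!length(envs)) { warnf("iClass %s has no environments; skipped", ic); next }
    vals <- fit$u[, envs, drop = FALSE] +
      matrix(fit$tau[envs], nrow(fit$u), length(envs), byrow = TRUE)
    out[[ic]] <- data.frame(genotype = rownames(fit$u), env = ic,
                            trait = "scsAUC_iclass",
                            value = rowMeans(vals), stringsAsFactors = FALSE,
                            row.names = NULL)
  }
  do.call(rbind, out)
}

#' Select the MET covariance model
#'
#' Among candidate fits within an AIC window of the best fit, returns the
#' one accounting for the most genetic variance (FA fits); non-FA fits
#' compete on AIC alone.  Because the percent variance accounted is
#' monotone non-decreasing in the number of factors, a smaller model whose
#' variance accounted is within \code{vaf_tol} percentage points of the
#' best is preferred -- this keeps the selected factor order at the
#' simulated rank instead of drifting upward by fractions of a point.
#'
#' @param fits list of \code{met_fit} objects on the same data.
#' @param aic_window AIC tolerance around the minimum (default 10).
#' @param vaf_tol variance-accounted tolerance (percentage points) within
#'   which the more parsimonious structure wins.
#' @return the selected fit, with the comparison table as attribute
#'   \code{"comparison"}.
#' @export
select_met_model <- function(fits, aic_window = 10, vaf_tol = 2) {
  fits <- Filter(function(f) isTRUE(f$converged), fits)
  if (!length(fits)) stopf("no converged MET fits to select from")
  tab <- data.frame(
    model = vapply(fits, function(f) f$structure, character(1)),
    AIC = vapply(fits, function(f) f$AIC, numeric(1)),
    logLik = vapply(fits, function(f) f$loglik, numeric(1)),
    pct_var = vapply(fits, function(f) {
      if (is.null(f$Lambda)) NA_real_
      else attr(variance_accounted(f), "overall")
    }, numeric(1)))
  tab$n_par <- vapply(fits, function(f) f$n_par, numeric(1))
  ok <- which(tab$AIC <= min(tab$AIC) + aic_window)
  vaf <- ifelse(is.na(tab$pct_var[ok]), -Inf, tab$pct_var[ok])
  pick <- if (all(!is.finite(vaf))) ok[which.min(tab$AIC[ok])]
  else {
    # among near-tied variance-accounted, prefer the most parsimonious
    near <- ok[vaf >= max(vaf) - vaf_tol]
    near[order(tab$n_par[near], tab$AIC[near])][1]
  }
  out <- fits[[pick]]
  attr(out, "comparison") <- tab
  out
}

#' VanRaden genomic relationship matrix
#'
#' Centered cross-product of dosages scaled by \eqn{2\sum p_j(1-p_j)};
#' missing dosages are mean-imputed, and a small ridge is added if the
#' matrix is numerically singular.
#'
#' @param genotypes a \code{genotype_matrix} or dosage matrix (genotypes x
#'   markers, values 0/1/2).
#' @param ridge ridge added to the diagonal when needed.
#' @return the relationship matrix (class \code{grm}).
#' @export
grm_vanraden <- function(genotypes, ridge = 1e-6) {
  M <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosage else
    as.matrix(genotypes)
  if (anyNA(M)) {
    mu <- colMeans(M, na.rm = TRUE)
    idx <- which(is.na(M), arr.ind = TRUE)
    M[idx] <- mu[idx[, 2]]
  }
  p <- colMeans(M) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stopf("all markers are monomorphic; GRM undefined")
  M <- M[, poly, drop = FALSE]
  p <- p[poly]
  W <- sweep(M, 2, 2 * p)
  G <- tcrossprod(W) / (2 * sum(p * (1 - p)))
  ev <- min(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < 1e-8) G <- G + diag(ridge, nrow(G))
  structure(G, class = c("grm", "matrix"), method = "vanraden")
}

#' Genetic correlation between two traits from a bivariate kinship model
#'
#' REML fit of the bivariate mixed model \eqn{y_t = \mu_t + g_t + e_t} with
#' \eqn{(g_1, g_2) \sim N(0, \Sigma_g \otimes G)} and a free 2 x 2
#' residual covariance, via the eigendecomposition of the relationship
#' matrix.  Returns \eqn{r_g = \sigma_{g12} / \sqrt{\sigma^2_{g1}
#' \sigma^2_{g2}}}, clipped to \eqn{[-1, 1]}.
#'
#' @param y1,y2 named genotype vectors (e.g. per-environment BLUEs of
#'   scsAUC and yield).
#' @param grm relationship matrix covering the shared genotypes.
#' @return list with \code{r_g}, the variance components and the
#'   log-likelihood; \code{r_g} is \code{NA} with a warning when either
#'   genetic variance is estimated near zero.
#' @export
genetic_correlation <- function(y1, y2, grm) {
  ids <- intersect(intersect(names(y1), names(y2)), rownames(grm))
  if (length(ids) < 10) stopf("too few shared genotypes (%d)", length(ids))
  y1 <- y1[ids]; y2 <- y2[ids]
  G <- unclass(grm)[ids, ids]
  eg <- eigen(G, symmetric = TRUE)
  U <- eg$vectors
  dvals <- pmax(eg$values, 1e-9)
  z1 <- drop(crossprod(U, y1))
  z2 <- drop(crossprod(U, y2))
  x <- drop(crossprod(U, rep(1, length(ids))))
  n <- length(ids)

  neg2ll <- function(par) {
    sg <- exp(par[1:2]); rg <- tanh(par[3]) * 0.999; se <- exp(par[4:5])
    re <- tanh(par[6]) * 0.999
    covg <- rg * sqrt(sg[1] * sg[2])
    cove <- re * sqrt(se[1] * se[2])
    ll <- 0
    XtViX <- matrix(0, 2, 2); XtViy <- numeric(2)
    dets <- 0; quad <- 0
    # per eigencomponent: C_i = d_i * Sigma_g + Sigma_e
    a <- dvals * sg[1] + se[1]
    b <- dvals * covg + cove
    cc <- dvals * sg[2] + se[2]
    det2 <- a * cc - b^2
    if (any(det2 <= 0)) return(1e10)
    # inverse entries
    ia <- cc / det2; ib <- -b / det2; ic <- a / det2
    XtViX[1, 1] <- sum(x^2 * ia); XtViX[2, 2] <- sum(x^2 * ic)
    XtViX[1, 2] <- XtViX[2, 1] <- sum(x^2 * ib)
    XtViy[1] <- sum(x * (ia * z1 + ib * z2))
    XtViy[2] <- sum(x * (ib * z1 + ic * z2))
    mu <- tryCatch(solve(XtViX, XtViy), error = function(e) NULL)
    if (is.null(mu)) return(1e10)
    r1 <- z1 - mu[1] * x; r2 <- z2 - mu[2] * x
    quad <- sum(ia * r1^2 + 2 * ib * r1 * r2 + ic * r2^2)
    dets <- sum(log(det2))
    val <- dets + quad + log(det(XtViX)) + (2 * n - 2) * log(2 * pi)
    if (!is.finite(val)) return(1e10)
    val
  }
  v1 <- stats::var(y1); v2 <- stats::var(y2)
  r12 <- stats::cor(y1, y2)
  start <- c(log(v1 / 2), log(v2 / 2), atanh(0.9 * r12),
             log(v1 / 2), log(v2 / 2), atanh(0.5 * r12))
  op <- suppressWarnings(stats::optim(start, neg2ll, method = "Nelder-Mead",
                                      control = list(maxit = 4000,
                                                     reltol = 1e-12)))
  op2 <- tryCatch(suppressWarnings(
    stats::optim(op$par, neg2ll, method = "BFGS",
                 control = list(maxit = 200, reltol = 1e-12))),
    error = function(e) NULL)
  if (!is.null(op2) && op2$value < op$value) op <- op2
  sg <- exp(op$par[1:2]); rg <- tanh(op$par[3]) * 0.999
  if (any(sg < 1e-8 * c(v1, v2))) {
    warnf("near-zero genetic variance; genetic correlation undefined")
    rg <- NA_real_
  }
  list(r_g = max(-1, min(1, rg)), sigma_g = sg, sigma_e = exp(op$par[4:5]),
       r_e = tanh(op$par[6]) * 0.999, loglik = -op$value / 2,
       n = length(ids))
}

#' Phenotypic correlation of two trait vectors
#'
#' Pearson correlation of the per-genotype BLUEs (equivalently the
#' standardized slope of the linear regression of one on the other).
#'
#' @param y1,y2 named genotype vectors.
#' @return the correlation.
#' @export
phenotypic_correlation <- function(y1, y2) {
  ids <- intersect(names(y1), names(y2))
  stats::cor(y1[ids], y2[ids])
}
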