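#' Stage-1 spatial correction of plot-level NDRE and yield
#'
#' Two candidate spatial models are fitted per flight: a SpATS-style model
#' with a two-dimensional tensor-product P-spline surface plus random row,
#' column and genotype effects, and a linear mixed model with random row,
#' column, replicate and genotype effects and a separable AR1 x AR1
#' residual correlation over the field grid.  Flowering group enters both
#' models as a fixed effect.  The model with the higher broad-sense
#' heritability across the most flights is retained and its spatially
#' corrected plot values feed the growth-curve stage.
#'
#' @name spatial_stage
NULL

check_plot_table <- function(d) {
  need <- c("row", "col", "genotype", "ndre")
  miss <- setdiff(need, names(d))
  if (length(miss)) stopf("plot table lacks columns: %s", paste(miss, collapse = ", "))
  if (any(!is.finite(d$ndre))) stopf("non-finite NDRE values in plot table")
  if (length(unique(d$row)) < 2 || length(unique(d$col)) < 2)
    stopf("need at least 2 rows and 2 columns")
  if (length(unique(d$genotype)) < 2)
    stopf("degenerate design: all plots carry one genotype")
  invisible(d)
}

# PS-ANOVA decomposition of a 2-D P-spline surface into fixed polynomial
# parts and iid-variance random blocks (mixed-model representation of the
# tensor-product penalty), for use with the dense REML engine.
psanova_blocks <- function(row, col, k = c(8, 8), degree = 3, pord = 2) {
  marg <- function(x, kk) {
    x01 <- (x - min(x)) / max(1e-12, diff(range(x)))
    bs <- spline_basis(c(-0.02, 1.02), n_knots = max(2, kk - degree - 1),
                       degree = degree, penalty_order = pord)
    B <- basis_eval(bs, x01)
    e <- eigen(bs$P, symmetric = TRUE)
    pos <- e$values > max(e$values) * 1e-10
    Z <- B %*% e$vectors[, pos] %*% diag(1 / sqrt(e$values[pos]))
    list(Z = Z, x = x01)
  }
  mu <- marg(row, k[1]); mv <- marg(col, k[2])
  u <- mu$x; v <- mv$x
  rowkron <- function(A, B) {
    out <- matrix(0, nrow(A), ncol(A) * ncol(B))
    for (i in seq_len(ncol(A))) out[, (i - 1) * ncol(B) + seq_len(ncol(B))] <- A[, i] * B
    out
  }
  list(X = cbind(u = u, v = v, uv = u * v),
       blocks = list(f_u = mu$Z, f_v = mv$Z,
                     v_f_u = v * mu$Z, u_f_v = u * mv$Z,
                     f_uv = rowkron(mu$Z, mv$Z)))
}

#' SpATS-style P-spline spatial model for one flight
#'
#' Fits intercept + flowering-group (fixed) + random genotype, row and
#' column effects + a tensor-product 2-D P-spline surface, by REML.  The
#' default engine is \pkg{mgcv}; \code{engine = "reml"} uses the package's
#' own dense REML engine on the PS-ANOVA mixed-model representation
#' (useful for likelihood comparisons against other fits of that engine).
#'
#' @param plots data.frame with one NDRE value per plot (columns \code{row},
#'   \code{col}, \code{genotype}, \code{ndre}, optionally
#'   \code{flowering_group}); typically a single-flight slice of the NDRE
#'   long table.
#' @param t thermal time of the flight; if \code{plots} has a
#'   \code{thermal_time} column it is subset to \code{t}.
#' @param engine \code{"mgcv"} or \code{"reml"}.
#' @param surface set \code{FALSE} to constrain the spline surface to zero
#'   (row/column-effects-only model).
#' @param knot_density surface knots per grid index; the default places
#'   about one marginal knot per two rows/columns.
#' @return a \code{spatial_fit} slice: genotype effects, corrected plot
#'   values, the estimated spatial components, heritabilities (effective
#'   dimension based and PEV-based) and variance components.
#' @export
fit_spats_timepoint <- function(plots, t = NULL, engine = c("mgcv", "reml"),
                                surface = TRUE, knot_density = 0.5) {
  engine <- match.arg(engine)
  d <- as.data.frame(plots)
  if (!is.null(t) && "thermal_time" %in% names(d))
    d <- d[abs(d$thermal_time - t) < 1e-8, , drop = FALSE]
  check_plot_table(d)
  if (!"flowering_group" %in% names(d)) d$flowering_group <- 1L
  d$genof <- factor(d$genotype)
  d$rowf <- factor(d$row)
  d$colf <- factor(d$col)
  d$fg <- factor(d$flowering_group)
  n_geno <- nlevels(d$genof)
  has_fg <- nlevels(d$fg) > 1

  if (engine == "mgcv") {
    kr <- min(length(unique(d$row)), max(5, ceiling(length(unique(d$row)) * knot_density)))
    kc <- min(length(unique(d$col)), max(5, ceiling(length(unique(d$col)) * knot_density)))
    rhs <- "s(genof, bs = \"re\") + s(rowf, bs = \"re\") + s(colf, bs = \"re\")"
    if (surface)
      rhs <- paste0(rhs, sprintf(" + te(row, col, bs = \"ps\", k = c(%d, %d), m = 2)", kr, kc))
    if (has_fg) rhs <- paste("fg +", rhs)
    fit <- mgcv::gam(stats::as.formula(paste("ndre ~", rhs)), data = d,
                     method = "REML")
    tl <- sapply(fit$smooth, function(s) s$label)
    terms <- stats::predict(fit, type = "terms")
    tcols <- colnames(terms)
    pick <- function(what) if (what %in% tcols) terms[, what] else rep(0, nrow(d))
    spat <- pick("te(row,col)") + pick("s(rowf)") + pick("s(colf)")
    fgterm <- if (has_fg) rowSums(terms[, grep("^fg", tcols), drop = FALSE]) else rep(0, nrow(d))
    corrected <- d$ndre - spat - fgterm
    # genotype BLUPs from the random-effect smooth coefficients
    gi <- which(tl == "s(genof)")
    par_idx <- fit$smooth[[gi]]$first.para:fit$smooth[[gi]]$last.para
    geno_eff <- stats::setNames(stats::coef(fit)[par_idx], levels(d$genof))
    ed_geno <- sum(fit$edf[par_idx])
    h2_ed <- min(1, max(0, ed_geno / (n_geno - 1)))
    Vp <- fit$Vp[par_idx, par_idx, drop = FALSE]
    sp <- fit$sp[grep("genof", names(fit$sp))]
    gamma_v <- if (length(sp) == 1 && sp > 0) fit$sig2 / sp else NA_real_
    h2_pev <- if (is.finite(gamma_v) && gamma_v > 0)
      min(1, max(0, 1 - mean_pairwise_pev(Vp) / (2 * gamma_v))) else h2_ed
    out <- list(model = "SpATS", t = t, engine = engine,
                genotype_effects = geno_eff,
                corrected = corrected, spatial = spat + fgterm,
                surface = pick("te(row,col)"),
                h2 = h2_pev, h2_ed = h2_ed, h2_pev = h2_pev,
                ed_genotype = ed_geno, sigma2 = fit$sig2,
                gamma_v = gamma_v, loglik = as.numeric(stats::logLik(fit)),
                plots = d[, c("row", "col", "genotype")], fit = fit)
  } else {
    ps <- psanova_blocks(d$row, d$col)
    X <- cbind(`(Intercept)` = 1,
               if (has_fg) stats::model.matrix(~fg, d)[, -1, drop = FALSE],
               if (surface) ps$X)
    random <- c(list(genotype = d$genof, rowf = d$rowf, colf = d$colf),
                ps$blocks)
    fix_gamma <- if (!surface)
      stats::setNames(as.list(rep(0, length(ps$blocks))), names(ps$blocks))
    fit <- reml_lmm(d$ndre, X, random, fix_gamma = fix_gamma,
                    pev_term = "genotype")
    Xf <- fit$X
    surf_cols <- intersect(colnames(Xf), c("u", "v", "uv"))
    spat_fixed <- drop(Xf[, surf_cols, drop = FALSE] %*%
                         fit$beta[surf_cols])
    spat_rand <- rep(0, nrow(d))
    for (nm in c("rowf", "colf", names(ps$blocks)))
      spat_rand <- spat_rand + drop(fit$Zs[[nm]] %*% fit$blups[[nm]])
    fgterm <- if (has_fg) {
      fgnm <- grep("^fg", colnames(Xf), value = TRUE)
      drop(Xf[, fgnm, drop = FALSE] %*% fit$beta[fgnm])
    } else rep(0, nrow(d))
    spat <- spat_fixed + spat_rand
    corrected <- d$ndre - spat - fgterm
    h2 <- heritability_generalized(fit)
    out <- list(model = "SpATS", t = t, engine = engine,
                genotype_effects = fit$blups$genotype,
                corrected = corrected, spatial = spat + fgterm,
                surface = spat_fixed + spat_rand -
                  drop(fit$Zs$rowf %*% fit$blups$rowf) -
                  drop(fit$Zs$colf %*% fit$blups$colf),
                h2 = h2, h2_ed = NA_real_, h2_pev = h2,
                sigma2 = fit$sigma2, gamma_v = unname(fit$varcomp["genotype"]),
                loglik = fit$loglik,
                plots = d[, c("row", "col", "genotype")], fit = fit)
  }
  class(out) <- "spatial_fit"
  out
}

#' AR1 x AR1 linear mixed model for one flight
#'
#' REML fit of NDRE on fixed intercept + flowering group with random
#' genotype, row, column and replicate effects and a separable
#' first-order autoregressive residual correlation across the row/column
#' grid.
#'
#' @inheritParams fit_spats_timepoint
#' @param fix_rho optional fixed AR1 parameters, e.g. \code{c(0, 0)} for
#'   the independent-residual fit.
#' @return a \code{spatial_fit} slice (same contract as
#'   \code{\link{fit_spats_timepoint}}).
#' @export
fit_lmm_ar1_timepoint <- function(plots, t = NULL, fix_rho = NULL) {
  d <- as.data.frame(plots)
  if (!is.null(t) && "thermal_time" %in% names(d))
    d <- d[abs(d$thermal_time - t) < 1e-8, , drop = FALSE]
  check_plot_table(d)
  if (anyDuplicated(d[, c("row", "col")]))
    stopf("AR1 residual model requires unique (row, column) plot positions")
  if (!"flowering_group" %in% names(d)) d$flowering_group <- 1L
  if (!"replicate" %in% names(d)) d$replicate <- 1L
  d$fg <- factor(d$flowering_group)
  has_fg <- nlevels(d$fg) > 1
  X <- if (has_fg) stats::model.matrix(~fg, d) else
    matrix(1, nrow(d), 1, dimnames = list(NULL, "(Intercept)"))
  random <- list(genotype = factor(d$genotype), rowf = factor(d$row),
                 colf = factor(d$col))
  if (length(unique(d$replicate)) > 1) random$repf <- factor(d$replicate)
  fit <- reml_lmm(d$ndre, X, random,
                  resid = list(type = "ar1xar1", row = d$row, col = d$col),
                  fix_rho = fix_rho, pev_term = "genotype")
  spat_rand <- rep(0, nrow(d))
  for (nm in setdiff(names(fit$Zs), "genotype"))
    spat_rand <- spat_rand + drop(fit$Zs[[nm]] %*% fit$blups[[nm]])
  fgterm <- if (has_fg) {
    fgnm <- grep("^fg", colnames(fit$X), value = TRUE)
    drop(fit$X[, fgnm, drop = FALSE] %*% fit$beta[fgnm])
  } else rep(0, nrow(d))
  h2 <- heritability_generalized(fit)
  structure(list(model = "LMM-AR1", t = t,
                 genotype_effects = fit$blups$genotype,
                 corrected = d$ndre - spat_rand - fgterm,
                 spatial = spat_rand + fgterm, surface = spat_rand,
                 h2 = h2, h2_ed = NA_real_, h2_pev = h2,
                 rho = fit$rho, sigma2 = fit$sigma2,
                 gamma_v = unname(fit$varcomp["genotype"]),
                 loglik = fit$loglik,
                 plots = d[, c("row", "col", "genotype")], fit = fit),
            class = "spatial_fit")
}

#' Choose the spatial model by per-flight heritability vote
#'
#' The model with the higher broad-sense heritability at the greater number
#' of flights wins; a tied vote goes to the higher mean heritability, and a
#' remaining tie to the P-spline (SpATS) model.
#'
#' @param spats_fits,ar1_fits lists of \code{spatial_fit} slices over the
#'   same flights.
#' @return list with the winning \code{model} tag and the per-flight
#'   heritability table.
#' @export
select_spatial_model <- function(spats_fits, ar1_fits) {
  if (length(spats_fits) != length(ar1_fits))
    stopf("candidate fits must cover identical timepoints")
  h2 <- data.frame(
    t = vapply(spats_fits, function(f) f$t %||% NA_real_, numeric(1)),
    spats = vapply(spats_fits, function(f) f$h2, numeric(1)),
    ar1 = vapply(ar1_fits, function(f) f$h2, numeric(1)))
  votes_spats <- sum(h2$spats > h2$ar1)
  votes_ar1 <- sum(h2$ar1 > h2$spats)
  model <- if (votes_spats > votes_ar1) "SpATS"
  else if (votes_ar1 > votes_spats) "LMM-AR1"
  else if (mean(h2$spats) >= mean(h2$ar1)) "SpATS" else "LMM-AR1"
  list(model = model, h2_table = h2,
       votes = c(SpATS = votes_spats, `LMM-AR1` = votes_ar1))
}

#' Spatially correct all flights of one trial
#'
#' Runs both candidate models at every flight, selects one by the
#' heritability vote (unless forced), and returns the corrected NDRE long
#' table of the winning model.
#'
#' @param ndre long NDRE table for one trial (columns \code{plot},
#'   \code{row}, \code{col}, \code{genotype}, \code{flowering_group},
#'   \code{thermal_time}, \code{ndre}).
#' @param model \code{"auto"}, \code{"spats"} or \code{"ar1"}.
#' @return list with the corrected long table, per-flight heritabilities,
#'   chosen model tag and per-flight fits.
#' @export
spatial_correct_trial <- function(ndre, model = c("auto", "spats", "ar1")) {
  model <- match.arg(model)
  ts <- sort(unique(ndre$thermal_time))
  spats <- if (model != "ar1") lapply(ts, function(t) fit_spats_timepoint(ndre, t))
  ar1 <- if (model != "spats") lapply(ts, function(t) fit_lmm_ar1_timepoint(ndre, t))
  tag <- switch(model,
                auto = select_spatial_model(spats, ar1)$model,
                spats = "SpATS", ar1 = "LMM-AR1")
  fits <- if (tag == "SpATS") spats else ar1
  corrected <- do.call(rbind, lapply(seq_along(ts), function(i) {
    d <- ndre[abs(ndre$thermal_time - ts[i]) < 1e-8, , drop = FALSE]
    d$ndre_corrected <- fits[[i]]$corrected
    d
  }))
  h2 <- data.frame(t = ts, h2 = vapply(fits, function(f) f$h2, numeric(1)))
  list(corrected = corrected, h2_table = h2, model = tag, fits = fits,
       selection = if (model == "auto") select_spatial_model(spats, ar1))
}

#' Genotype BLUEs for yield from the AR1 spatial model
#'
#' Fits yield per plot with genotype fixed, random row, column and
#' replicate effects, and a separable AR1 x AR1 residual correlation, and
#' returns the genotype best linear unbiased estimators.
#'
#' @param yield data.frame with columns \code{row}, \code{col},
#'   \code{replicate}, \code{genotype}, \code{yield} (t/ha).
#' @param ar1 fit the separable AR1 residual correlation (default); set
#'   \code{FALSE} for independent residuals.
#' @return data.frame of genotype BLUEs plus the fit (attribute
#'   \code{"fit"}); the fit's generalized heritability is computed from a
#'   companion genotype-random fit.
#' @export
yield_blues <- function(yield, ar1 = TRUE) {
  d <- as.data.frame(yield)
  stopifnot(all(c("row", "col", "genotype", "yield") %in% names(d)))
  if (!"replicate" %in% names(d)) d$replicate <- 1L
  d$genof <- factor(d$genotype)
  X <- stats::model.matrix(~ 0 + genof, d)
  colnames(X) <- levels(d$genof)
  random <- list(rowf = factor(d$row), colf = factor(d$col))
  if (length(unique(d$replicate)) > 1) random$repf <- factor(d$replicate)
  resid <- if (ar1) list(type = "ar1xar1", row = d$row, col = d$col)
  else list(type = "iid")
  # variance parameters from the genotype-random fit (also yields the
  # generalized heritability); BLUEs then come from one GLS solve with
  # genotype fixed at those variance parameters
  rfit <- reml_lmm(d$yield, matrix(1, nrow(d), 1),
                   c(list(genotype = d$genof), random),
                   resid = resid, pev_term = "genotype")
  V0 <- if (ar1) {
    rr <- rfit$rho
    (rr[1]^abs(outer(d$row, d$row, `-`))) * (rr[2]^abs(outer(d$col, d$col, `-`)))
  } else diag(nrow(d))
  for (nm in names(random)) {
    Z <- rfit$Zs[[nm]]
    V0 <- V0 + (rfit$varcomp[nm] / rfit$sigma2) * tcrossprod(Z)
  }
  ch <- chol(V0)
  ViX <- backsolve(ch, forwardsolve(t(ch), X))
  Viy <- backsolve(ch, forwardsolve(t(ch), d$yield))
  beta <- solve(crossprod(X, ViX), crossprod(X, Viy))
  blue <- data.frame(genotype = colnames(X), blue = drop(beta),
                     stringsAsFactors = FALSE)
  attr(blue, "fit") <- rfit
  attr(blue, "h2") <- heritability_generalized(rfit)
  blue
}
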