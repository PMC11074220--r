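#' @export
#' @method print genotype_matrix
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d genotypes x %d markers on %d chromosome(s)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$map$chrom))))
  miss <- sum(is.na(x$dosage))
  if (miss) cat(sprintf("  missing dosages: %d\n", miss))
  invisible(x)
}

#' @export
#' @method print met_fit
print.met_fit <- function(x, ...) {
  cat(sprintf("MET covariance fit [%s]: %d environments, %d genotypes\n",
              x$structure, length(x$env), x$n_genotypes))
  cat(sprintf("  REML logL %.2f  AIC %.1f  (%d free parameters)\n",
              x$loglik, x$AIC, x$n_par))
  if (!is.null(x$Lambda))
    cat(sprintf("  %% variance accounted: %.1f\n",
                attr(variance_accounted(x), "overall")))
  invisible(x)
}

#' @export
#' @method print growth_curve_set
print.growth_curve_set <- function(x, ...) {
  cat(sprintf("growth_curve_set: %d genotypes%s, basis K = %d on [%.0f, %.0f]\n",
              length(x$genotypes),
              if (x$individual) sprintf(" + %d plot curves", ncol(x$coef_indiv))
              else "",
              x$basis$K, x$basis$domain[1], x$basis$domain[2]))
  cat(sprintf("  residual sd %.4g, restricted logL %.2f\n",
              sqrt(x$sigma2), x$loglik))
  invisible(x)
}

#' @export
#' @method print spatial_fit
print.spatial_fit <- function(x, ...) {
  cat(sprintf("spatial fit [%s]%s: %d plots, h2 = %.3f\n", x$model,
              if (!is.null(x$t)) sprintf(" at t = %g", x$t) else "",
              length(x$corrected), x$h2))
  invisible(x)
}
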