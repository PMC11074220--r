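#' @keywords internal
#' @import Matrix
#' @importFrom splines splineDesign
#' @importFrom jsonlite write_json
#' @importFrom yaml read_yaml
#' @importFrom tools md5sum
#' @importFrom utils write.csv read.csv packageVersion
"_PACKAGE"

# Derive a stream-specific seed from a master seed.  Keeps derived seeds
# inside the 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# logistic decline in thermal time: upper -> lower around midpoint t0 with
# scale s (GDD).  Used by the synthetic generator and by closed-form truth.
logistic_decline <- function(t, upper, lower, t0, s) {
  lower + (upper - lower) / (1 + exp((t - t0) / s))
}

# Exact integral of logistic_decline over [a, b].
# Antiderivative of 1/(1+exp((t-t0)/s)) is s*log(1+exp(-(t-t0)/s)) * (-1),
# i.e. integral_a^b = g(a) - g(b) with g(t) = s*log1p(exp(-(t-t0)/s)).
logistic_decline_auc <- function(a, b, upper, lower, t0, s) {
  g <- function(t) s * log1p(exp(-(t - t0) / s))
  lower * (b - a) + (upper - lower) * (g(a) - g(b))
}

# Pearson r^2 between two dosage vectors; NA-safe; 0 if either is constant.
dosage_r2 <- function(x, y) {
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) return(0)
  stats::cor(x, y)^2
}
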