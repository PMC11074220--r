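#' P-spline basis over a thermal-time domain
#'
#' Constructs a B-spline basis of given degree with equally spaced interior
#' knots on a stated domain, together with the difference penalty used for
#' P-spline smoothing.  The default configuration (cubic basis, second-order
#' difference penalty, seven interior knots) is the one used throughout the
#' senescence growth-curve modeling.
#'
#' @param domain numeric length-2, the interval the basis must cover
#'   (typically the observed thermal-time range of a trial, in growing degree
#'   days).
#' @param n_knots number of equally spaced interior knots.
#' @param degree polynomial degree of the B-spline segments.
#' @param penalty_order order of the difference penalty on coefficients.
#' @return an object of class \code{spline_basis} with the full (replicated)
#'   knot vector, basis dimension \code{K}, and penalty matrix \code{P}.
#' @export
spline_basis <- function(domain, n_knots = 7, degree = 3, penalty_order = 2) {
  stopifnot(length(domain) == 2, domain[2] > domain[1],
            n_knots >= 1, degree >= 1, penalty_order >= 1)
  interior <- seq(domain[1], domain[2], length.out = n_knots + 2)[-c(1, n_knots + 2)]
  knots <- c(rep(domain[1], degree + 1), interior, rep(domain[2], degree + 1))
  K <- n_knots + degree + 1
  D <- diff(diag(K), differences = penalty_order)
  structure(list(domain = domain, degree = degree, penalty_order = penalty_order,
                 n_knots = n_knots, knots = knots, K = K, D = D,
                 P = crossprod(D)),
            class = "spline_basis")
}

#' Evaluate a B-spline basis (or a derivative of it)
#'
#' @param basis a \code{spline_basis}.
#' @param t evaluation points; must lie within the basis domain.
#' @param deriv derivative order (0 = the basis itself).
#' @return matrix of dimension \code{length(t)} x \code{basis$K}.
#' @export
basis_eval <- function(basis, t, deriv = 0) {
  if (any(t < basis$domain[1] - 1e-8 | t > basis$domain[2] + 1e-8))
    stopf("evaluation points outside basis domain [%g, %g]",
          basis$domain[1], basis$domain[2])
  t <- pmin(pmax(t, basis$domain[1]), basis$domain[2])
  splines::splineDesign(basis$knots, t, ord = basis$degree + 1,
                        derivs = rep(deriv, length(t)))
}

# Greville abscissae: the points at which a linear function's B-spline
# coefficients equal its values, so low-order polynomials are represented
# exactly in the basis.
greville <- function(basis) {
  k <- basis$degree
  kn <- basis$knots
  vapply(seq_len(basis$K), function(i) mean(kn[(i + 1):(i + k)]), numeric(1))
}

#' Analytic derivative of a spline given by B-spline coefficients
#'
#' Returns the derivative as a spline of one lower degree on the same
#' interior knots, with coefficients obtained by the standard B-spline
#' differentiation formula (no numerical differencing involved).
#'
#' @param basis a \code{spline_basis}.
#' @param coef coefficient vector of length \code{basis$K}.
#' @return list with the derivative basis (\code{spline_basis}-like knot
#'   info) and its coefficient vector, plus an \code{eval(t)} closure.
#' @export
spline_derivative <- function(basis, coef) {
  stopifnot(length(coef) == basis$K)
  k <- basis$degree
  kn <- basis$knots
  # d_i = k * (c_{i+1} - c_i) / (knots[i+k+1] - knots[i+1]), i = 1..K-1
  denom <- kn[seq_len(basis$K - 1) + k + 1] - kn[seq_len(basis$K - 1) + 1]
  dcoef <- k * diff(coef) / denom
  dknots <- kn[-c(1, length(kn))]
  evalf <- function(t) {
    t <- pmin(pmax(t, basis$domain[1]), basis$domain[2])
    drop(splines::splineDesign(dknots, t, ord = k) %*% dcoef)
  }
  list(knots = dknots, degree = k - 1, coef = dcoef, eval = evalf)
}

#' Exact integral of a spline from its B-spline coefficients
#'
#' Integrates the spline on \code{[a, b]} through its piecewise-polynomial
#' antiderivative: the antiderivative of a degree-\code{k} spline is a
#' degree-\code{k+1} spline whose coefficients are cumulative sums of
#' \code{coef * (knot span)/(k+1)}.  No quadrature is involved.
#'
#' @param basis a \code{spline_basis}.
#' @param coef coefficient vector.
#' @param a,b integration limits, inside the basis domain.
#' @return the value of the integral.
#' @export
spline_integral <- function(basis, coef, a, b) {
  stopifnot(length(coef) == basis$K)
  if (b < a) stopf("inverted integration window [%g, %g]", a, b)
  k <- basis$degree
  kn <- basis$knots
  # antiderivative basis: degree k+1 on knot vector with one extra
  # replicate at each boundary
  akn <- c(kn[1], kn, kn[length(kn)])
  spans <- kn[seq_len(basis$K) + k + 1] - kn[seq_len(basis$K)]
  acoef <- c(0, cumsum(coef * spans / (k + 1)))
  Fab <- splines::splineDesign(akn, c(a, b), ord = k + 2)
  drop(Fab %*% acoef)[2] - drop(Fab %*% acoef)[1]
}

# Integral of |f'| over [a, b], computed exactly by locating the sign
# changes of the (piecewise-quadratic, for a cubic spline) derivative and
# summing |f(t_{j+1}) - f(t_j)| over sign-constant pieces.
spline_abs_deriv_integral <- function(basis, coef, a, b) {
  d <- spline_derivative(basis, coef)
  f <- function(t) drop(basis_eval(basis, t) %*% coef)
  brk <- sort(unique(c(a, b, basis$knots[basis$knots > a & basis$knots < b])))
  roots <- c()
  for (j in seq_len(length(brk) - 1)) {
    lo <- brk[j]; hi <- brk[j + 1]
    if (hi - lo < 1e-12) next
    # derivative restricted to [lo, hi] is a single polynomial of degree
    # basis$degree - 1; recover it exactly by interpolation and take roots
    deg <- basis$degree - 1
    ts <- seq(lo, hi, length.out = deg + 1)
    V <- outer(ts - lo, 0:deg, `^`)
    pc <- solve(V, d$eval(ts))            # polynomial coefficients in (t-lo)
    keep <- which(abs(pc) > 1e-11 * max(1, max(abs(pc))))
    if (length(keep) == 0 || max(keep) < 2) next   # (near-)constant derivative
    rts <- polyroot(pc[seq_len(max(keep))])
    rts <- Re(rts[abs(Im(rts)) < 1e-8])
    rts <- rts + lo
    roots <- c(roots, rts[rts > lo + 1e-10 & rts < hi - 1e-10])
  }
  pts <- sort(unique(c(brk, roots)))
  vals <- f(pts)
  sum(abs(diff(vals)))
}
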