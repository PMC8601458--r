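#' Natural cubic spline basis with analytic derivatives
#'
#' Builds the natural cubic regression spline basis (truncated-power
#' construction with the natural constraints imposed, i.e. linear beyond the
#' boundary knots and continuous second derivative throughout) used for the
#' SITAR mean curve.  The basis omits the constant column — the intercept is
#' carried by the size parameters of the growth model — so for `K` knots
#' (2 boundary + `K - 2` interior) the basis has `K - 1` columns.
#'
#' Because the basis is closed-form piecewise cubic, exact first and second
#' derivatives are available; velocity curves are therefore analytic and never
#' obtained by finite-differencing data.
#'
#' @param x numeric vector of evaluation points.
#' @param knots strictly increasing numeric vector of all knots (boundary
#'   knots first/last), length at least 3.
#' @param deriv derivative order: 0 (value), 1 or 2.
#' @return numeric matrix, `length(x)` rows and `length(knots) - 1` columns.
#' @examples
#' b <- ns_basis(seq(7, 19, 0.5), knots = c(7, 10, 12, 14, 19))
#' dim(b)
#' @export
ns_basis <- function(x, knots, deriv = 0L) {
  if (length(knots) < 3L) {
    stop("`knots` must contain at least 2 boundary and 1 interior knot.")
  }
  if (any(diff(knots) <= 0)) stop("`knots` must be strictly increasing.")
  if (!deriv %in% 0:2) stop("`deriv` must be 0, 1 or 2.")
  K <- length(knots)
  kK <- knots[K]
  kK1 <- knots[K - 1L]
  n <- length(x)

  tp <- function(k) {
    # (x - k)_+^3 and its derivatives
    u <- x - k
    u[u < 0] <- 0
    switch(deriv + 1L, u * u * u, 3 * u * u, 6 * u)
  }
  out <- matrix(0, n, K - 1L)
  out[, 1L] <- switch(deriv + 1L, x, rep(1, n), rep(0, n))
  if (K > 2L) {
    tK <- tp(kK)
    dlast <- (tp(kK1) - tK) / (kK - kK1)
    for (j in seq_len(K - 2L)) {
      out[, j + 1L] <- (tp(knots[j]) - tK) / (kK - knots[j]) - dlast
    }
  }
  colnames(out) <- paste0("s", seq_len(K - 1L))
  out
}

#' Knot placement for the SITAR mean curve
#'
#' Boundary knots at the range of the ages, interior knots at equally spaced
#' quantiles.  `df` is the number of basis columns, so `df - 1` interior knots
#' are used.
#'
#' @param age numeric vector of ages (years).
#' @param df spline degrees of freedom (basis columns), 2 or more.
#' @return numeric vector of knots (boundary first/last).
#' @keywords internal
sitar_knots <- function(age, df) {
  if (df < 2L) stop("`df` must be at least 2.")
  n_int <- df - 1L
  probs <- seq_len(n_int) / (n_int + 1L)
  interior <- unname(stats::quantile(age, probs, type = 7))
  knots <- c(min(age), interior, max(age))
  if (any(diff(knots) <= 0)) {
    # quantile knots collide (e.g. many visits at the exact same age):
    # fall back to equally spaced knots over the observed range
    knots <- seq(min(age), max(age), length.out = df + 1L)
  }
  if (any(diff(knots) <= 0)) {
    stop("Degenerate knot placement: too little spread in `age` for df = ", df)
  }
  knots
}
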