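#' Pseudo-elastic (Hertzian) fit of a force curve
#'
#' Parameterizes the traditional Hertzian spherical contact model: the
#' closed-form least-squares slope of the normalized force against `h^{3/2}`
#' (identical computation to [fit_elastic()]) gives a shear-type modulus `G`,
#' converted to a Young's modulus via `E = 2 G (1 + nu)` — consistent with the
#' `8 sqrt(R)/(3(1-nu))` prefactor being the shear form of Hertz contact.
#' The full repulsive segment is used unless `h_max` windows it.
#'
#' @param curve a [force_curve()].
#' @param geom a [contact_geometry()]; defaults to the curve's.
#' @param h_max optional indentation cutoff, m.
#' @return a `hertz_result`: `E` (Young's, Pa), `G` (shear form, Pa),
#'   residual `sse`, and the curve id.
#' @export
fit_hertz <- function(curve, geom = curve$geom, h_max = NULL) {
  stopifnot(inherits(curve, "force_curve"))
  if (!is.null(h_max)) {
    keep <- curve$h <= h_max
    if (sum(keep) < 3L) stop("h_max leaves too few samples")
    curve <- list(t = curve$t[keep], h = curve$h[keep], F = curve$F[keep],
                  geom = curve$geom, provenance = curve$provenance)
    class(curve) <- "force_curve"
  }
  G <- fit_elastic(curve, geom)
  k0 <- lr_prefactor(geom)
  structure(list(E = 2 * G * (1 + geom$nu), G = G,
                 sse = sum((curve$F / k0 - G * curve$h^1.5)^2),
                 curve_id = curve$provenance),
            class = "hertz_result")
}

#' @export
print.hertz_result <- function(x, ...) {
  cat(sprintf("Hertz fit: E = %.4g Pa (G = %.4g Pa), SSE = %.4g\n",
              x$E, x$G, x$sse))
  invisible(x)
}

#' Box-plot summary of a modulus population
#'
#' Median, quartiles, whiskers and outliers, with outliers defined as values
#' more than `1.5 * IQR` beyond the quartiles; whiskers reach the most extreme
#' non-outlying observations. Invariant to input order.
#'
#' @param x numeric vector of moduli, or a list of `hertz_result`.
#' @return list with `n`, `median`, `q1`, `q3`, `iqr`, `whisker_low`,
#'   `whisker_high`, `outliers`.
#' @export
summarize_population <- function(x) {
  if (is.list(x) && all(vapply(x, inherits, TRUE, "hertz_result")))
    x <- vapply(x, `[[`, 0, "E")
  stopifnot(is.numeric(x), length(x) >= 1)
  q <- unname(quantile(x, c(0.25, 0.5, 0.75)))
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  inside <- x >= lo & x <= hi
  list(n = length(x), median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
       whisker_low = min(x[inside]), whisker_high = max(x[inside]),
       outliers = sort(x[!inside]))
}

#' Welch's unpaired two-tailed t-test
#'
#' Direct Welch-Satterthwaite computation: `t = (mA - mB)/sqrt(sA^2/nA +
#' sB^2/nB)` with the Satterthwaite degrees of freedom, two-tailed p from the
#' Student-t distribution, and a significance flag at `alpha`.
#'
#' @param a,b numeric groups, each `n >= 2` with nonzero variance.
#' @param alpha significance level (default 0.05).
#' @return list with `t`, `df`, `p`, `significant`.
#' @export
welch_test <- function(a, b, alpha = 0.05) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) >= 2, length(b) >= 2)
  va <- var(a); vb <- var(b)
  if (va == 0 && vb == 0) stop("degenerate variance: both groups are constant")
  na <- length(a); nb <- length(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(t), df = df)
  list(t = t, df = df, p = p, significant = p < alpha)
}

#' @importFrom stats var
NULL
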