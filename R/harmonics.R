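#' Experiment-implied frequency grid
#'
#' A quasi-static ramp excites mechanical action at every frequency between
#' the inverse experiment length and the sampling rate (each timestep acts as
#' an excitation at `1/t_i`). The grid is log-spaced between exactly those two
#' endpoints.
#'
#' @param x a [force_curve()], or the experiment duration in seconds.
#' @param sampling_rate Hz; taken from the curve when `x` is one.
#' @param points_per_decade grid density (default 50).
#' @return frequency grid, Hz, strictly increasing, endpoints exact.
#' @export
frequency_grid <- function(x, sampling_rate = NULL, points_per_decade = 50) {
  if (inherits(x, "force_curve")) {
    duration <- max(x$t)
    sampling_rate <- sampling_rate %||% x$sampling_rate
  } else duration <- x
  stopifnot(is.numeric(duration), length(duration) == 1L,
            is.numeric(sampling_rate), sampling_rate > 0)
  lo <- 1 / duration
  hi <- sampling_rate
  if (!is.finite(lo) || lo <= 0 || duration <= 1 / sampling_rate)
    stop("degenerate duration: need duration > 1/sampling_rate")
  n <- max(2L, ceiling(log10(hi / lo) * points_per_decade) + 1L)
  f <- 10^seq(log10(lo), log10(hi), length.out = n)
  f[1] <- lo
  f[n] <- hi
  f
}

new_spectrum <- function(f, storage, loss, angle, n = 1L, ci = NULL) {
  structure(list(f = f, storage = storage, loss = loss, angle = angle,
                 n = n, ci = ci),
            class = "harmonic_spectrum")
}

#' Harmonic spectrum of a fitted model
#'
#' Storage modulus, loss modulus and loss angle of a material model on a
#' frequency grid, via the closed-form harmonic expressions of
#' [harmonic_moduli()]. By default frequencies in Hz are converted to angular
#' frequency (`omega = 2 pi f`); set `angular = FALSE` to evaluate at
#' `omega = f`, which shifts spectra horizontally by 2 pi.
#'
#' @param model a [gm_model()] or [gkv_model()].
#' @param f frequency grid, Hz (e.g. [frequency_grid()]).
#' @param angular convert Hz to rad/s before evaluating (default TRUE).
#' @return a `harmonic_spectrum` (single-curve: `n = 1`, no bands).
#' @export
spectrum <- function(model, f, angular = TRUE) {
  stopifnot(is.numeric(f), all(f > 0), !is.unsorted(f, strictly = TRUE))
  hm <- harmonic_moduli(model, if (angular) 2 * pi * f else f)
  new_spectrum(f, hm$storage, hm$loss, loss_angle(hm$storage, hm$loss))
}

#' @export
print.harmonic_spectrum <- function(x, ...) {
  cat(sprintf(paste0("Harmonic spectrum: %d frequencies in [%.3g, %.3g] Hz, ",
                     "n = %d curve(s)%s\n"),
              length(x$f), min(x$f), max(x$f), x$n,
              if (!is.null(x$ci)) ", with bands" else ""))
  invisible(x)
}

#' @export
as.data.frame.harmonic_spectrum <- function(x, ...) {
  d <- data.frame(frequency_hz = x$f, storage_pa = x$storage,
                  loss_pa = x$loss, loss_angle_deg = x$angle)
  if (!is.null(x$ci))
    for (q in names(x$ci)) {
      d[[paste0("ci_low_", q)]] <- x$ci[[q]][, 1]
      d[[paste0("ci_high_", q)]] <- x$ci[[q]][, 2]
    }
  d
}

#' Aggregate harmonic spectra across curves
#'
#' Per-frequency simple mean of storage, loss and loss angle over the input
#' spectra (averaging happens in the frequency domain, after each fitted
#' parameter set has been converted to its predicted spectrum), with Student-t
#' bands at the requested confidence level. `band = "mean"` gives the standard
#' CI of the mean, `mean +/- t * sd/sqrt(n)`; `band = "observation"` gives the
#' observation-range style band `mean +/- t * sd`.
#'
#' @param spectra list of `harmonic_spectrum` on one shared grid.
#' @param level confidence level (default 0.95).
#' @param band `"mean"` or `"observation"`.
#' @return a `harmonic_spectrum` with `n = length(spectra)` and `ci` bands.
#' @export
aggregate_spectra <- function(spectra, level = 0.95,
                              band = c("mean", "observation")) {
  band <- match.arg(band)
  stopifnot(length(spectra) >= 1)
  f <- spectra[[1]]$f
  for (s in spectra)
    if (length(s$f) != length(f) || any(s$f != f))
      stop("mismatched frequency grids")
  n <- length(spectra)
  ci <- list()
  out <- list()
  for (q in c("storage", "loss", "angle")) {
    m <- vapply(spectra, `[[`, f, q)          # length(f) x n
    if (is.null(dim(m))) m <- matrix(m, nrow = length(f))
    mu <- rowMeans(m)
    out[[q]] <- mu
    if (n >= 2) {
      s <- apply(m, 1, sd)
      tq <- qt((1 + level) / 2, df = n - 1)
      half <- if (band == "mean") tq * s / sqrt(n) else tq * s
      ci[[q]] <- cbind(mu - half, mu + half)
    }
  }
  new_spectrum(f, out$storage, out$loss, out$angle, n = n,
               ci = if (length(ci)) ci else NULL)
}

#' Write a spectrum to CSV
#'
#' Columns `frequency_hz,storage_pa,loss_pa,loss_angle_deg` plus
#' `ci_low_*`/`ci_high_*` when bands are present. Fixed number formatting for
#' byte-stable output.
#'
#' @param spec a `harmonic_spectrum`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  d <- as.data.frame(spec)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(d), collapse = ","), con)
  rows <- do.call(sprintf,
                  c(list(paste(rep("%.12e", ncol(d)), collapse = ",")),
                    unname(as.list(d))))
  writeLines(rows, con)
  invisible(path)
}
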