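#' Quasi-static AFM force curve
#'
#' One preprocessed indentation record on a uniform time grid starting at
#' contact: time `t` (s), indentation `h` (m), force `F` (N), plus instrument
#' geometry, cantilever spring constant and sampling rate. `h[1] = F[1] = 0`
#' after preprocessing; on synthetic noisy curves the force may dip slightly
#' below zero near contact (detection noise), which is tolerated.
#'
#' @param t uniform time grid, s, starting at 0, length `>= 16`.
#' @param h indentation, m, non-negative.
#' @param F force, N.
#' @param geom a [contact_geometry()].
#' @param k cantilever spring constant, N/m (NA when unknown).
#' @param sampling_rate Hz; defaults to `1/dt`.
#' @param provenance raw-file path or synthetic ground-truth reference.
#' @param ground_truth optional generating model for recovery tests.
#' @return an object of class `force_curve`.
#' @export
force_curve <- function(t, h, F, geom, k = NA_real_, sampling_rate = NULL,
                        provenance = NULL, ground_truth = NULL) {
  stopifnot(is.numeric(t), is.numeric(h), is.numeric(F),
            length(t) == length(h), length(t) == length(F),
            inherits(geom, "contact_geometry"))
  if (length(t) < 16L) stop("a force curve needs at least 16 samples")
  dt <- check_uniform_grid(t)
  if (any(h < 0)) stop("indentation h must be non-negative")
  if (abs(h[1]) > 0 || abs(F[1]) > max(1e-12 * max(abs(F)), .Machine$double.xmin))
    stop("curve must be re-zeroed: h and F must be 0 at contact (t = 0)")
  structure(list(t = as.double(t), h = as.double(h), F = as.double(F),
                 geom = geom, k = k,
                 sampling_rate = sampling_rate %||% (1 / dt),
                 provenance = provenance, ground_truth = ground_truth),
            class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf(paste0("AFM force curve: %d samples, %.4g s at %.4g kHz, ",
                     "max h = %.4g nm, max F = %.4g nN%s\n"),
              length(x$t), max(x$t), x$sampling_rate / 1e3,
              max(x$h) * 1e9, max(x$F) * 1e9,
              if (!is.null(x$ground_truth)) " [synthetic]" else ""))
  invisible(x)
}

#' @export
length.force_curve <- function(x) length(x$t)

# Uniform-stride decimation preserving the first sample; used before fitting.
decimate_curve <- function(curve, stride) {
  if (stride <= 1L) return(curve)
  idx <- seq(1L, length(curve$t), by = as.integer(stride))
  force_curve(curve$t[idx], curve$h[idx], curve$F[idx], curve$geom,
              k = curve$k, sampling_rate = curve$sampling_rate / stride,
              provenance = curve$provenance, ground_truth = curve$ground_truth)
}
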