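#' Default experiment configuration
#'
#' Calibration constants and preprocessing knobs used by [read_curve()] and
#' [detect_contact_and_trim()]. All internal units are SI (m, s, N, Pa);
#' readers convert from declared units at parse time.
#'
#' @param spring_constant_n_per_m cantilever spring constant, N/m.
#' @param tip_radius_m probe radius, m.
#' @param poisson_ratio sample Poisson ratio.
#' @param sampling_rate_hz acquisition rate, Hz (NULL: inferred from time).
#' @param column_map named list mapping canonical names (`time`, `z`,
#'   `deflection`, `indentation`, `force`) to the file's column names.
#' @param units named list of units per canonical column, e.g.
#'   `list(z = "nm", deflection = "nm")`. Supported: m/mm/um/nm/pm, s/ms/us,
#'   N/mN/uN/nN/pN.
#' @param contact_threshold_sd contact threshold in baseline-residual SDs.
#' @param baseline_fraction fraction of the approach used for the baseline fit.
#' @param confirm_samples forward-confirmation window for the threshold rule.
#' @param refine_contact refine the contact point by a piecewise-Hertz grid
#'   search (recommended; `FALSE` keeps the raw threshold rule).
#' @return a named list (class `vf_config`).
#' @export
vf_config <- function(spring_constant_n_per_m = 0.75, tip_radius_m = 12.5e-6,
                      poisson_ratio = 0.5, sampling_rate_hz = NULL,
                      column_map = NULL, units = NULL,
                      contact_threshold_sd = 3, baseline_fraction = 0.5,
                      confirm_samples = 10L, refine_contact = TRUE) {
  structure(list(spring_constant_n_per_m = spring_constant_n_per_m,
                 tip_radius_m = tip_radius_m, poisson_ratio = poisson_ratio,
                 sampling_rate_hz = sampling_rate_hz, column_map = column_map,
                 units = units, contact_threshold_sd = contact_threshold_sd,
                 baseline_fraction = baseline_fraction,
                 confirm_samples = as.integer(confirm_samples),
                 refine_contact = isTRUE(refine_contact)),
            class = "vf_config")
}

#' Read an experiment configuration from a JSON file
#'
#' @param path JSON file with any subset of the [vf_config()] keys.
#' @return a `vf_config`.
#' @export
read_config <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  base <- vf_config()
  known <- names(base)
  bad <- setdiff(names(doc), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  base[names(doc)] <- doc
  structure(base, class = "vf_config")
}

unit_scale <- function(u) {
  switch(u,
         m = 1, mm = 1e-3, um = 1e-6, "µm" = 1e-6, nm = 1e-9, pm = 1e-12,
         s = 1, ms = 1e-3, us = 1e-6,
         N = 1, mN = 1e-3, uN = 1e-6, nN = 1e-9, pN = 1e-12,
         stop("unsupported unit: ", u))
}

#' Write a preprocessed force curve to CSV
#'
#' Header `time_s,indentation_m,force_n`, '.' decimal, '#' comment lines
#' carrying the instrument constants. Number formatting is fixed so identical
#' curves serialize to identical bytes.
#'
#' @param curve a [force_curve()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "force_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# viscofit force curve (SI units)",
               sprintf("# tip_radius_m: %.12e", curve$geom$R),
               sprintf("# poisson_ratio: %.12e", curve$geom$nu),
               sprintf("# sampling_rate_hz: %.12e", curve$sampling_rate),
               sprintf("# spring_constant_n_per_m: %.12e", curve$k),
               "time_s,indentation_m,force_n"), con)
  writeLines(sprintf("%.12e,%.12e,%.12e", curve$t, curve$h, curve$F), con)
  invisible(path)
}

#' Read a raw or preprocessed AFM force-curve table
#'
#' Accepts a delimited text table whose header names either
#' (`time_s`, `indentation_m`, `force_n`) — preprocessed — or
#' (`time_s`, `z_m`, `deflection_m`) — raw piezo/deflection. Other column names
#' are handled through `config$column_map` with units from `config$units`.
#' Returns a raw record; pass it to [detect_contact_and_trim()] to obtain a
#' [force_curve()].
#'
#' @param path file path (CSV; '#' comments; '.' decimal).
#' @param config a [vf_config()] supplying k, R, nu and units.
#' @return an `afm_raw` record with SI-unit columns.
#' @export
read_curve <- function(path, config = vf_config()) {
  tab <- read.table(path, header = TRUE, sep = ",", comment.char = "#",
                    check.names = FALSE)
  cols <- names(tab)
  cmap <- config$column_map
  pick <- function(canon, builtin) {
    if (!is.null(cmap[[canon]])) {
      if (!cmap[[canon]] %in% cols)
        stop("column_map names a missing column: ", cmap[[canon]])
      return(tab[[cmap[[canon]]]] * unit_scale(config$units[[canon]] %||% "m"))
    }
    if (builtin %in% cols) return(tab[[builtin]])  # builtin headers are SI
    NULL
  }
  time <- if (!is.null(cmap[["time"]]))
    tab[[cmap[["time"]]]] * unit_scale(config$units[["time"]] %||% "s")
  else if ("time_s" %in% cols) tab[["time_s"]] else NULL
  if (is.null(time)) stop("missing column: time")
  if (any(diff(time) <= 0)) stop("non-monotone time column")
  ind <- pick("indentation", "indentation_m")
  force <- if (!is.null(cmap[["force"]]))
    tab[[cmap[["force"]]]] * unit_scale(config$units[["force"]] %||% "N")
  else if ("force_n" %in% cols) tab[["force_n"]] else NULL
  z <- pick("z", "z_m")
  defl <- pick("deflection", "deflection_m")
  kind <- if (!is.null(ind) && !is.null(force)) "processed"
          else if (!is.null(z) && !is.null(defl)) "raw"
          else stop("missing columns: need (time, indentation, force) or (time, z, deflection)")
  if (kind == "raw" && !is.finite(config$spring_constant_n_per_m))
    stop("missing calibration constant: spring_constant_n_per_m")
  structure(list(kind = kind, time = time, indentation = ind, force = force,
                 z = z, deflection = defl,
                 k = config$spring_constant_n_per_m,
                 geom = contact_geometry(config$tip_radius_m,
                                         config$poisson_ratio),
                 sampling_rate = config$sampling_rate_hz,
                 path = path),
            class = "afm_raw")
}

#' Detect the contact point and isolate the repulsive segment
#'
#' Subtracts a linear baseline fitted over the configured pre-contact fraction
#' of the approach, locates contact by a threshold rule (corrected force
#' exceeding `contact_threshold_sd` baseline SDs, confirmed over
#' `confirm_samples` forward samples), optionally refines the contact sample by
#' a piecewise-Hertz grid search (flat baseline before contact, `a (t-tc)^{3/2}`
#' after), then re-zeros time, indentation and force at contact and truncates
#' at the force maximum. Already-preprocessed [force_curve()] inputs are
#' returned unchanged apart from float re-zeroing (idempotence).
#'
#' @param raw an `afm_raw` record from [read_curve()], or a [force_curve()].
#' @param config a [vf_config()].
#' @return a [force_curve()].
#' @export
detect_contact_and_trim <- function(raw, config = vf_config()) {
  if (inherits(raw, "force_curve")) {
    return(force_curve(raw$t - raw$t[1], raw$h - raw$h[1], raw$F - raw$F[1],
                       raw$geom, k = raw$k, sampling_rate = raw$sampling_rate,
                       provenance = raw$provenance,
                       ground_truth = raw$ground_truth))
  }
  stopifnot(inherits(raw, "afm_raw"))
  t <- raw$time
  n <- length(t)
  if (raw$kind == "processed") {
    # already-trimmed record: starts at contact, no baseline to remove
    h0 <- raw$indentation; F0 <- raw$force
    trimmed <- abs(h0[1]) <= 1e-6 * max(abs(h0)) &&
      abs(F0[1]) <= 1e-3 * max(abs(F0)) && all(h0 >= -1e-12) &&
      F0[min(n, 16L)] > 0
    if (trimmed)
      return(force_curve(t - t[1], pmax(h0 - h0[1], 0), F0 - F0[1],
                         geom = raw$geom, k = raw$k,
                         sampling_rate = raw$sampling_rate %||%
                           (1 / mean(diff(t))),
                         provenance = if (is.null(raw$path)) "raw record"
                                      else basename(raw$path)))
  }
  sig <- if (raw$kind == "raw") raw$deflection else raw$force
  nb <- max(8L, floor(config$baseline_fraction * n))
  if (nb >= n - config$confirm_samples) nb <- max(8L, n %/% 2L)
  bl <- lm(sig[seq_len(nb)] ~ t[seq_len(nb)])
  trend <- coef(bl)[1] + coef(bl)[2] * t
  corr <- sig - trend
  sigma <- sd(corr[seq_len(nb)])
  if (!is.finite(sigma) || sigma == 0) sigma <- .Machine$double.eps
  Fcorr <- if (raw$kind == "raw") raw$k * corr else corr
  thr <- config$contact_threshold_sd * (if (raw$kind == "raw") raw$k else 1) * sigma

  m <- config$confirm_samples
  above <- Fcorr > thr
  conf <- which(vapply(seq_len(n - m), function(i) all(above[i:(i + m - 1L)]), TRUE))
  if (!length(conf)) stop("no contact detected")
  coarse <- conf[1]
  contact <- max(1L, coarse - 1L)  # last sample before the confirmed crossing

  if (config$refine_contact) {
    # at realistic noise the 3-sigma crossing sits well after true contact,
    # so the candidate window spans the whole record up to the confirmed
    # crossing; the two-pass grid keeps this cheap
    lo <- 1L
    hi <- min(n - m, coarse + m)
    # indentation coordinate, up to the per-candidate offset: for raw records
    # h(c) = (z - z_c) - (d - d_c); for processed records h is given
    hbase <- if (raw$kind == "raw") raw$z - corr else raw$indentation
    contact <- refine_contact_point(hbase, Fcorr, lo, hi, n)
  }

  idx <- contact:n
  Fout <- Fcorr[idx] - Fcorr[contact]
  peak <- which.max(Fout)
  if (peak < length(idx)) { idx <- idx[seq_len(peak)]; Fout <- Fout[seq_len(peak)] }
  h <- if (raw$kind == "raw") {
    (raw$z[idx] - raw$z[contact]) - (corr[idx] - corr[contact])
  } else {
    raw$indentation[idx] - raw$indentation[contact]
  }
  tolh <- max(1e-12, 0.05 * max(h))
  if (any(h < -tolh)) stop("negative indentation after contact: check calibration")
  h <- pmax(h, 0)
  if (length(idx) < 16L) stop("repulsive segment too short after trimming")
  force_curve(t[idx] - t[contact], h, Fout,
              geom = raw$geom, k = raw$k,
              sampling_rate = raw$sampling_rate %||% (1 / mean(diff(t))),
              provenance = if (is.null(raw$path)) "raw record"
                           else basename(raw$path))
}

# Two-pass grid search for the contact sample: minimizes the SSE of a
# piecewise Hertz model (zero force before contact, a * h^{3/2} after, with h
# re-zeroed at the candidate) over candidates lo:hi.
refine_contact_point <- function(hbase, F, lo, hi, n) {
  score <- function(c) {
    x <- pmax(hbase - hbase[c], 0)^1.5
    Fb <- F - F[c]
    reg <- lo:n
    a <- sum(x[reg] * Fb[reg]) / sum(x[reg]^2)
    sum((Fb[reg] - a * x[reg])^2)
  }
  repeat {
    cand <- unique(round(seq(lo, hi, length.out = min(hi - lo + 1L, 128L))))
    best <- cand[which.min(vapply(cand, score, 0))]
    stride <- max(1L, (hi - lo) %/% 127L)
    if (stride == 1L) return(best)
    lo <- max(lo, best - 2L * stride)
    hi <- min(hi, best + 2L * stride)
  }
}
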