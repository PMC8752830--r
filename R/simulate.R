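#' Constant-velocity indentation ramp protocol
#'
#' Describes how a synthetic quasi-static approach is driven: probe speed,
#' sampling rate, one stop trigger (maximum force or maximum indentation) and
#' optional additive Gaussian force noise. Defaults mirror a typical live-cell
#' experiment with a 25 um-diameter bead: 2 um/s approach, 50 kHz sampling and
#' a 10 nN force trigger (applied forces in the 5-18 nN working range).
#'
#' @param speed probe approach velocity, m/s, `> 0`.
#' @param sampling_rate Hz, `> 0`.
#' @param trigger_force stop at this force, N (set exactly one trigger).
#' @param trigger_indentation stop at this depth, m.
#' @param noise_sd additive Gaussian force noise SD, N, `>= 0`.
#' @param max_duration give up if the trigger is not reached by this time, s.
#' @return an object of class `ramp_protocol`.
#' @export
ramp_protocol <- function(speed = 2e-6, sampling_rate = 5e4,
                          trigger_force = 10e-9, trigger_indentation = NULL,
                          noise_sd = 0, max_duration = 10) {
  stopifnot(speed > 0, sampling_rate > 0, noise_sd >= 0, max_duration > 0)
  if (is.null(trigger_force) == is.null(trigger_indentation))
    stop("set exactly one trigger: trigger_force or trigger_indentation")
  structure(list(speed = speed, sampling_rate = sampling_rate,
                 trigger_force = trigger_force,
                 trigger_indentation = trigger_indentation,
                 noise_sd = noise_sd, max_duration = max_duration),
            class = "ramp_protocol")
}

#' Simulate one synthetic AFM force curve
#'
#' Builds the constant-velocity indentation history `h(t) = speed * t` on the
#' uniform sampling grid, computes the force through the Lee-Radok hereditary
#' integral ([predict_force()]) until the trigger fires, then adds seeded
#' Gaussian force noise. The returned curve is flagged synthetic and embeds the
#' generating model for recovery tests.
#'
#' @param model ground-truth [gm_model()].
#' @param protocol a [ramp_protocol()].
#' @param geom a [contact_geometry()]; default 12.5 um bead radius, nu = 0.5.
#' @param seed integer seed for the noise stream (bit-identical curves for the
#'   same seed).
#' @return a [force_curve()].
#' @export
simulate_curve <- function(model, protocol = ramp_protocol(),
                           geom = contact_geometry(12.5e-6, 0.5), seed = 1L) {
  stopifnot(inherits(model, "generalized_maxwell"),
            inherits(protocol, "ramp_protocol"))
  dt <- 1 / protocol$sampling_rate
  if (n_arms(model) && dt > min(model$tau) / 2)
    warning("sampling interval (", signif(dt, 3), " s) exceeds half the ",
            "fastest relaxation time; the discretized convolution may be ",
            "inaccurate -- raise sampling_rate")
  if (!is.null(protocol$trigger_indentation)) {
    t_end <- protocol$trigger_indentation / protocol$speed
    if (t_end > protocol$max_duration)
      stop("trigger unreachable within max_duration")
    t <- seq(0, t_end, by = dt)
    h <- protocol$speed * t
    F <- predict_force(model, t, h, geom)
    n_keep <- length(t)
  } else {
    # Equilibrium stiffness bounds the force from below on a monotone ramp, so
    # it bounds the trigger time from above.
    k0 <- lr_prefactor(geom)
    t_bound <- (protocol$trigger_force / (k0 * model$Ge))^(2 / 3) / protocol$speed
    t_bound <- min(t_bound * 1.02 + 2 * dt, protocol$max_duration)
    t <- seq(0, t_bound, by = dt)
    h <- protocol$speed * t
    F <- predict_force(model, t, h, geom)
    hit <- which(F >= protocol$trigger_force)
    if (!length(hit)) {
      if (t_bound >= protocol$max_duration)
        stop("trigger unreachable within max_duration")
      hit <- length(t)  # bound guarantees the trigger fires before t_bound
    }
    n_keep <- hit[1]
  }
  if (n_keep < 16L)
    stop("trigger fires within 16 samples; raise the trigger or sampling rate")
  idx <- seq_len(n_keep)
  t <- t[idx]; h <- h[idx]; F <- F[idx]
  if (protocol$noise_sd > 0) {
    noise <- with_local_seed(seed, function()
      rnorm(length(F), sd = protocol$noise_sd))
    noise[1] <- 0  # keep F(0) = 0 at contact
    F <- F + noise
  }
  force_curve(t, h, F, geom, sampling_rate = protocol$sampling_rate,
              provenance = list(type = "synthetic", seed = as.integer(seed)),
              ground_truth = model)
}

#' Default ground-truth parameter distribution
#'
#' Moduli log-uniform in `[1e2, 1e4]` Pa and arm timescales one decade apart
#' starting at 1e-4 s — the regime of the live-cell fits this package targets.
#'
#' @param arms number of viscoelastic arms, `>= 0`.
#' @param tau_seed first-arm timescale, s.
#' @return function(seed) returning a random [gm_model()].
#' @export
default_model_distribution <- function(arms = 2L, tau_seed = 1e-4) {
  stopifnot(arms >= 0, tau_seed > 0)
  function(seed) {
    with_local_seed(seed, function() {
      mag <- 10^runif(arms + 1L, 2, 4)
      if (arms == 0L) return(gm_model(mag[1]))
      gm_model(mag[1], G = mag[-1], tau = tau_seed * 10^(seq_len(arms) - 1L))
    })
  }
}

# Fixed benchmark ground truth used by the method-comparison protocol; chosen
# once inside the default distribution's regime (Ge, Gn in [1e2, 1e4] Pa, tau
# decades from 1e-4 s).
#' Fixed benchmark generalized Maxwell model
#'
#' The deterministic ground truth used by [compare_methods()] and the recovery
#' tests: `Ge = 1000` Pa, arms `(3000 Pa, 1e-4 s)`, `(1500 Pa, 1e-3 s)`,
#' `(800 Pa, 1e-2 s)` truncated to `arms`.
#'
#' @param arms number of arms in `0..3`.
#' @return a [gm_model()].
#' @export
benchmark_model <- function(arms = 3L) {
  stopifnot(arms >= 0, arms <= 3)
  if (arms == 0L) return(gm_model(1000))
  gm_model(1000, G = c(3000, 1500, 800)[seq_len(arms)],
           tau = c(1e-4, 1e-3, 1e-2)[seq_len(arms)])
}

#' Simulate a population of force curves
#'
#' Either replays an explicit list of ground-truth models (recycled over
#' `n_curves`) or draws per-curve models from a distribution spec: a base model
#' plus mean-one log-normal jitter on moduli and timescales, emulating
#' cell-to-cell heterogeneity. Deterministic given `seed`; each curve records
#' its own ground truth.
#'
#' @param models a list of [gm_model()]s, a single model, or a spec
#'   `list(base = model, sd_log_modulus = 0.1, sd_log_tau = 0.05)`.
#' @param n_curves number of curves, `>= 1`.
#' @param protocol a [ramp_protocol()].
#' @param geom a [contact_geometry()].
#' @param seed master seed; per-curve seeds are derived from it.
#' @return list of [force_curve()]s.
#' @export
simulate_population <- function(models, n_curves, protocol = ramp_protocol(),
                                geom = contact_geometry(12.5e-6, 0.5),
                                seed = 1L) {
  stopifnot(n_curves >= 1)
  draw <- population_model_sampler(models)
  lapply(seq_len(n_curves), function(i) {
    m <- draw(i, derive_seed(seed, 1L, i))
    simulate_curve(m, protocol, geom, seed = derive_seed(seed, 2L, i))
  })
}

population_model_sampler <- function(models) {
  if (inherits(models, "generalized_maxwell")) {
    function(i, s) models
  } else if (is.list(models) && !is.null(models$base)) {
    base <- models$base
    if (!inherits(base, "generalized_maxwell"))
      stop("invalid distribution spec: base must be a generalized Maxwell model")
    sdm <- models$sd_log_modulus %||% 0.1
    sdt <- models$sd_log_tau %||% 0.05
    if (sdm < 0 || sdt < 0) stop("invalid distribution spec: negative jitter SD")
    function(i, s) {
      with_local_seed(s, function() {
        # mean-one log-normal multipliers so the population mean is unbiased
        jm <- exp(rnorm(1 + n_arms(base), -sdm^2 / 2, sdm))
        jt <- exp(rnorm(n_arms(base), -sdt^2 / 2, sdt))
        tau <- base$tau * jt
        if (length(tau) > 1L) tau <- sort(tau)
        gm_model(base$Ge * jm[1], G = base$G * jm[-1], tau = tau)
      })
    }
  } else if (is.list(models) && all(vapply(models, inherits, TRUE,
                                           "generalized_maxwell"))) {
    function(i, s) models[[((i - 1L) %% length(models)) + 1L]]
  } else stop("invalid distribution spec")
}
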