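#' Spherical contact geometry
#'
#' @param R probe radius, m, `> 0`.
#' @param nu Poisson ratio, in `[0, 0.5]` (0.5 is the incompressible limit; the
#'   Lee-Radok prefactor uses `1 - nu` and stays finite there).
#' @return an object of class `contact_geometry`.
#' @export
contact_geometry <- function(R, nu = 0.5) {
  stopifnot(is.numeric(R), length(R) == 1L, is.numeric(nu), length(nu) == 1L)
  if (!is.finite(R) || R <= 0) stop("probe radius R must be positive")
  if (!is.finite(nu) || nu < 0 || nu > 0.5) stop("Poisson ratio nu must be in [0, 0.5]")
  structure(list(R = as.double(R), nu = as.double(nu)), class = "contact_geometry")
}

#' @export
print.contact_geometry <- function(x, ...) {
  cat(sprintf("Spherical contact: R = %.4g m, nu = %.3g\n", x$R, x$nu))
  invisible(x)
}

#' Lee-Radok spherical-indentation prefactor
#'
#' The scale `8 sqrt(R) / (3 (1 - nu))` that maps the relaxance convolution of
#' the indentation history `h^{3/2}` to force for a spherical probe. It is the
#' shear-modulus form of the Hertz contact expression; fitted moduli are
#' therefore shear-type magnitudes (see [fit_hertz()] for the Young's
#' conversion).
#'
#' @param geom a [contact_geometry()].
#' @return the scalar prefactor.
#' @export
lr_prefactor <- function(geom) {
  stopifnot(inherits(geom, "contact_geometry"))
  8 * sqrt(geom$R) / (3 * (1 - geom$nu))
}

# Validate a uniform time grid starting at 0; returns dt.
check_uniform_grid <- function(t) {
  stopifnot(is.numeric(t), length(t) >= 2L)
  if (abs(t[1]) > .Machine$double.eps * 100)
    stop("time grid must start at 0")
  d <- diff(t)
  if (any(d <= 0)) stop("time grid must be strictly increasing")
  dt <- d[1]
  if (max(abs(d - dt)) > 1e-6 * dt)
    stop("non-uniform time grid: resample the curve to uniform spacing first")
  dt
}

#' Predict force from an indentation history (Lee-Radok, Maxwell family)
#'
#' Evaluates `F(t) = [8 sqrt(R)/(3(1-nu))] * int_0^t Q(t-z) h(z)^{3/2} dz` on a
#' uniform grid. The relaxance `Q` contains impulsive terms, so the integral is
#' realized through integration by parts (valid for `h(0) = 0`):
#' `F/k0 = G(0) g(t) - sum_n (Gn/taun) int_0^t exp(-(t-z)/taun) g(z) dz` with
#' `g = h^{3/2}`. The exponential integrals use the trapezoid rule; the default
#' `"recursive"` method is the O(n) recursion, `"direct"` is the O(n^2)
#' double-loop evaluation of the identical sum, kept as an independent oracle.
#' For a zero-arm model the result reduces exactly to the Hertz closed form
#' `k0 * Ge * h^{3/2}`.
#'
#' @param model a [gm_model()].
#' @param t uniform time grid, s, starting at 0.
#' @param h indentation, m, `h[1] = 0`, non-negative.
#' @param geom a [contact_geometry()].
#' @param method `"recursive"` (production) or `"direct"` (O(n^2) oracle).
#' @return force, N, on the same grid.
#' @export
predict_force <- function(model, t, h, geom, method = c("recursive", "direct")) {
  stopifnot(inherits(model, "generalized_maxwell"), length(t) == length(h))
  method <- match.arg(method)
  dt <- check_uniform_grid(t)
  if (any(h < 0)) stop("indentation h must be non-negative")
  g <- h^1.5
  lr_prefactor(geom) * gm_convolution(g, dt, model, method)
}

# int_0^t Q(t-z) g(z) dz by parts; shared by predict_force and action_integral.
gm_convolution <- function(g, dt, model, method = "recursive") {
  out <- glassy_modulus(model) * g
  for (i in seq_along(model$G)) {
    I <- if (method == "direct") exp_trapz_direct(g, dt, model$tau[i])
         else exp_trapz_rec(g, dt, model$tau[i])
    out <- out - (model$G[i] / model$tau[i]) * I
  }
  out
}

# int_0^t U(t-z) F(z) dz by parts (retardance side).
gkv_convolution <- function(F, dt, model, method = "recursive") {
  out <- model$Jg * F
  for (i in seq_along(model$J)) {
    I <- if (method == "direct") exp_trapz_direct(F, dt, model$tau[i])
         else exp_trapz_rec(F, dt, model$tau[i])
    out <- out + (model$J[i] / model$tau[i]) * I
  }
  out
}

#' Predict indentation^(3/2) from a force history (Lee-Radok, Kelvin-Voigt)
#'
#' Evaluates `h(t)^{3/2} = [3(1-nu)/(8 sqrt(R))] * int_0^t U(t-z) F(z) dz`,
#' realized by parts as `(1/k0) [Jg F(t) + sum_n (Jn/taun) int exp(-(t-z)/taun)
#' F(z) dz]` for `F(0) = 0`.
#'
#' @param model a [gkv_model()].
#' @param t uniform time grid, s, starting at 0.
#' @param F force, N, `F[1] = 0`, non-negative.
#' @param geom a [contact_geometry()].
#' @param method `"recursive"` or `"direct"` (see [predict_force()]).
#' @return `h^{3/2}`, m^(3/2), on the same grid.
#' @export
predict_indentation <- function(model, t, F, geom, method = c("recursive", "direct")) {
  stopifnot(inherits(model, "generalized_kelvin_voigt"), length(t) == length(F))
  method <- match.arg(method)
  dt <- check_uniform_grid(t)
  if (any(F < 0)) stop("force F must be non-negative")
  gkv_convolution(F, dt, model, method) / lr_prefactor(geom)
}

#' Action-integral pair: normalized observable vs model convolution
#'
#' The two series whose pointwise squared difference is the fitting cost.
#' For the Maxwell family the pair is `( [3(1-nu)/(8 sqrt R)] F(t),
#' int_0^t Q(t-z) h(z)^{3/2} dz )`; for the Kelvin-Voigt family it is
#' `( h(t)^{3/2}, [3(1-nu)/(8 sqrt R)] int_0^t U(t-z) F(z) dz )`.
#'
#' @param model a [gm_model()] or [gkv_model()].
#' @param curve a [force_curve()].
#' @param geom a [contact_geometry()]; defaults to the curve's own geometry.
#' @return list with `observable` and `convolution` numeric series.
#' @export
action_integral <- function(model, curve, geom = curve$geom) {
  stopifnot(inherits(curve, "force_curve"))
  dt <- check_uniform_grid(curve$t)
  k0 <- lr_prefactor(geom)
  if (inherits(model, "generalized_maxwell")) {
    list(observable = curve$F / k0,
         convolution = gm_convolution(curve$h^1.5, dt, model))
  } else if (inherits(model, "generalized_kelvin_voigt")) {
    list(observable = curve$h^1.5,
         convolution = gkv_convolution(curve$F, dt, model) / k0)
  } else stop("not a material model")
}
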