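#' Generalized Maxwell material model
#'
#' A discrete spring-dashpot network: an equilibrium spring `Ge` in parallel
#' with `N` Maxwell arms `(Gn, taun)`. Its relaxation modulus is the Prony
#' series `G(t) = Ge + sum Gn * exp(-t/taun)`; the relaxance (the stiffness-side
#' response operator convolved with the indentation history in the Lee-Radok
#' framework) is represented implicitly by this parameter set and never
#' materialized as a time-domain distribution, since it contains impulsive
#' terms.
#'
#' @param Ge equilibrium (long-time) modulus, Pa. Must be positive.
#' @param G numeric vector of arm moduli, Pa (may be empty).
#' @param tau numeric vector of arm relaxation times, s; strictly increasing,
#'   same length as `G`. Arm 1 is the fastest timescale.
#' @return an object of class `generalized_maxwell`.
#' @examples
#' m <- gm_model(100, G = 300, tau = 1e-3)
#' relaxation_modulus(m, c(0, 1e-3))
#' @export
gm_model <- function(Ge, G = numeric(0), tau = numeric(0)) {
  stopifnot(is.numeric(Ge), length(Ge) == 1L, is.finite(Ge),
            is.numeric(G), is.numeric(tau), length(G) == length(tau))
  if (Ge <= 0) stop("Ge must be positive")
  if (length(G)) {
    if (any(!is.finite(G)) || any(G <= 0)) stop("all arm moduli G must be positive")
    if (any(!is.finite(tau)) || any(tau <= 0)) stop("all arm times tau must be positive")
    if (length(tau) > 1L && any(diff(tau) <= 0))
      stop("arm timescales tau must be strictly increasing")
  }
  structure(list(Ge = as.double(Ge), G = as.double(G), tau = as.double(tau)),
            class = "generalized_maxwell")
}

#' Generalized Kelvin-Voigt material model
#'
#' The compliance-side counterpart of [gm_model()]: a glassy spring of
#' compliance `Jg` in series with `N` Kelvin-Voigt arms `(Jn, taun)`. Its creep
#' compliance is `J(t) = Jg + sum Jn * (1 - exp(-t/taun))`; the retardance is
#' represented implicitly by the parameter set.
#'
#' @param Jg glassy (instantaneous) compliance, 1/Pa. Positive.
#' @param J numeric vector of arm compliances, 1/Pa (may be empty).
#' @param tau numeric vector of retardation times, s; strictly increasing.
#' @return an object of class `generalized_kelvin_voigt`.
#' @export
gkv_model <- function(Jg, J = numeric(0), tau = numeric(0)) {
  stopifnot(is.numeric(Jg), length(Jg) == 1L, is.finite(Jg),
            is.numeric(J), is.numeric(tau), length(J) == length(tau))
  if (Jg <= 0) stop("Jg must be positive")
  if (length(J)) {
    if (any(!is.finite(J)) || any(J <= 0)) stop("all arm compliances J must be positive")
    if (any(!is.finite(tau)) || any(tau <= 0)) stop("all arm times tau must be positive")
    if (length(tau) > 1L && any(diff(tau) <= 0))
      stop("arm timescales tau must be strictly increasing")
  }
  structure(list(Jg = as.double(Jg), J = as.double(J), tau = as.double(tau)),
            class = "generalized_kelvin_voigt")
}

n_arms <- function(model) length(model$tau)

#' @export
print.generalized_maxwell <- function(x, ...) {
  cat(sprintf("Generalized Maxwell model: Ge = %.4g Pa, %d arm(s)\n",
              x$Ge, n_arms(x)))
  if (n_arms(x))
    for (i in seq_along(x$G))
      cat(sprintf("  arm %d: G = %.4g Pa, tau = %.4g s\n", i, x$G[i], x$tau[i]))
  invisible(x)
}

#' @export
print.generalized_kelvin_voigt <- function(x, ...) {
  cat(sprintf("Generalized Kelvin-Voigt model: Jg = %.4g 1/Pa, %d arm(s)\n",
              x$Jg, n_arms(x)))
  if (n_arms(x))
    for (i in seq_along(x$J))
      cat(sprintf("  arm %d: J = %.4g 1/Pa, tau = %.4g s\n", i, x$J[i], x$tau[i]))
  invisible(x)
}

#' Relaxation modulus G(t) of a generalized Maxwell model
#'
#' `G(t) = Ge + sum Gn * exp(-t/taun)`: the stress response to a unit step
#' strain. Monotone non-increasing, `G(0)` is the glassy modulus and
#' `G(Inf) = Ge`.
#'
#' @param model a [gm_model()].
#' @param t numeric vector of times, s, all `>= 0`.
#' @return modulus in Pa, same length as `t`.
#' @export
relaxation_modulus <- function(model, t) {
  stopifnot(inherits(model, "generalized_maxwell"), is.numeric(t))
  if (any(t < 0)) stop("t must be non-negative")
  out <- rep(model$Ge, length(t))
  for (i in seq_along(model$G))
    out <- out + model$G[i] * exp(-t / model$tau[i])
  out
}

#' Creep compliance J(t) of a generalized Kelvin-Voigt model
#'
#' `J(t) = Jg + sum Jn * (1 - exp(-t/taun))`: the strain response to a unit
#' step stress. Monotone non-decreasing from `J(0) = Jg` to
#' `J(Inf) = Jg + sum Jn`.
#'
#' @param model a [gkv_model()].
#' @param t numeric vector of times, s, all `>= 0`.
#' @return compliance in 1/Pa, same length as `t`.
#' @export
creep_compliance <- function(model, t) {
  stopifnot(inherits(model, "generalized_kelvin_voigt"), is.numeric(t))
  if (any(t < 0)) stop("t must be non-negative")
  out <- rep(model$Jg, length(t))
  for (i in seq_along(model$J))
    out <- out + model$J[i] * (1 - exp(-t / model$tau[i]))
  out
}

glassy_modulus <- function(model) model$Ge + sum(model$G)

#' Storage and loss moduli at angular frequency omega
#'
#' For the Maxwell family: `storage = Ge + sum Gn w^2 tau^2/(1 + w^2 tau^2)`,
#' `loss = sum Gn w tau/(1 + w^2 tau^2)`. For the Kelvin-Voigt family the
#' complex compliance `J' - i J''` is formed first and inverted:
#' `storage = J'/(J'^2 + J''^2)`, `loss = J''/(J'^2 + J''^2)`.
#'
#' @param model a [gm_model()] or [gkv_model()].
#' @param omega angular frequency, rad/s, all `> 0`.
#' @return list with numeric vectors `storage` and `loss`, Pa.
#' @export
harmonic_moduli <- function(model, omega) UseMethod("harmonic_moduli")

#' @export
harmonic_moduli.generalized_maxwell <- function(model, omega) {
  stopifnot(is.numeric(omega))
  if (any(omega <= 0)) stop("omega must be positive")
  storage <- rep(model$Ge, length(omega))
  loss <- numeric(length(omega))
  for (i in seq_along(model$G)) {
    wt <- omega * model$tau[i]
    d <- 1 + wt^2
    storage <- storage + model$G[i] * wt^2 / d
    loss <- loss + model$G[i] * wt / d
  }
  list(storage = storage, loss = loss)
}

#' @export
harmonic_moduli.generalized_kelvin_voigt <- function(model, omega) {
  stopifnot(is.numeric(omega))
  if (any(omega <= 0)) stop("omega must be positive")
  Jp <- rep(model$Jg, length(omega))
  Jpp <- numeric(length(omega))
  for (i in seq_along(model$J)) {
    wt <- omega * model$tau[i]
    d <- 1 + wt^2
    Jp <- Jp + model$J[i] / d
    Jpp <- Jpp + model$J[i] * wt / d
  }
  m2 <- Jp^2 + Jpp^2
  list(storage = Jp / m2, loss = Jpp / m2)
}

#' Loss angle from storage and loss moduli
#'
#' The inverse tangent of the ratio of loss modulus to storage modulus, in
#' degrees: 0 for a purely elastic response, approaching 90 for a purely
#' viscous one.
#'
#' @param storage storage modulus, Pa, `> 0`.
#' @param loss loss modulus, Pa, `>= 0`.
#' @return angle in degrees, in `[0, 90)`.
#' @export
loss_angle <- function(storage, loss) {
  stopifnot(is.numeric(storage), is.numeric(loss))
  if (any(storage <= 0)) stop("storage modulus must be positive")
  if (any(loss < 0)) stop("loss modulus must be non-negative")
  atan2(loss, storage) * 180 / pi
}

#' Interconvert a single-arm model between Maxwell and Kelvin-Voigt form
#'
#' The standard linear solid has closed-form equivalent representations in both
#' families: `Jg = 1/(Ge + G1)`, `Jg + J1 = 1/Ge`, and the retardation time is
#' `tau * (Ge + G1)/Ge`. The two representations have identical complex moduli
#' at every frequency. Multi-arm interconversion is not closed-form and is not
#' supported.
#'
#' @param model a single-arm [gm_model()] (or single-arm [gkv_model()], which
#'   converts back to Maxwell form).
#' @return the equivalent model of the other family.
#' @export
sls_interconvert <- function(model) UseMethod("sls_interconvert")

#' @export
sls_interconvert.generalized_maxwell <- function(model) {
  if (n_arms(model) != 1L)
    stop("unsupported conversion: closed-form interconversion requires exactly 1 arm")
  G0 <- model$Ge + model$G[1]
  Jg <- 1 / G0
  J1 <- 1 / model$Ge - Jg
  if (J1 <= 0) stop("degenerate arm: interconversion requires G1 > 0")
  gkv_model(Jg, J = J1, tau = model$tau[1] * G0 / model$Ge)
}

#' @export
sls_interconvert.generalized_kelvin_voigt <- function(model) {
  if (n_arms(model) != 1L)
    stop("unsupported conversion: closed-form interconversion requires exactly 1 arm")
  Ge <- 1 / (model$Jg + model$J[1])
  G0 <- 1 / model$Jg
  gm_model(Ge, G = G0 - Ge, tau = model$tau[1] * Ge / G0)
}

#' Serialize a material model to JSON
#'
#' Format: `{"family": "maxwell"|"kelvinvoigt", "equilibrium_or_glassy": x,
#' "arms": [[magnitude, tau], ...], "units": "Pa"|"1/Pa"}`.
#'
#' @param model a material model.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to `path`.
#' @export
model_to_json <- function(model, path = NULL) {
  if (inherits(model, "generalized_maxwell")) {
    doc <- list(family = "maxwell", equilibrium_or_glassy = model$Ge,
                arms = unname(Map(c, model$G, model$tau)), units = "Pa")
  } else if (inherits(model, "generalized_kelvin_voigt")) {
    doc <- list(family = "kelvinvoigt", equilibrium_or_glassy = model$Jg,
                arms = unname(Map(c, model$J, model$tau)), units = "1/Pa")
  } else stop("not a material model")
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(txt))
  writeLines(as.character(txt), path)
  invisible(as.character(txt))
}

#' Deserialize a material model from JSON
#'
#' @param x a JSON string or a path to a JSON file written by [model_to_json()].
#' @return a [gm_model()] or [gkv_model()].
#' @export
model_from_json <- function(x) {
  doc <- jsonlite::fromJSON(x, simplifyMatrix = TRUE)
  arms <- doc$arms
  if (is.null(arms) || length(arms) == 0) {
    mag <- numeric(0); tau <- numeric(0)
  } else if (is.matrix(arms)) {
    mag <- arms[, 1]; tau <- arms[, 2]
  } else {  # list of pairs
    mag <- vapply(arms, `[`, 0, 1); tau <- vapply(arms, `[`, 0, 2)
  }
  switch(doc$family,
         maxwell = gm_model(doc$equilibrium_or_glassy, G = mag, tau = tau),
         kelvinvoigt = gkv_model(doc$equilibrium_or_glassy, J = mag, tau = tau),
         stop("unknown model family: ", doc$family))
}
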