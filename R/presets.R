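# calibrated synthetic presets -------------------------------------------
#
# The presets emulate the four neuronal-membrane lipids studied in
# Langmuir films. They are calibrated ONLY to the printed characteristic
# points of such films (lift-off areas 91/78 A^2 for brain/egg
# sphingomyelin, collapse pressures 69/50/46 mN/m, compression-modulus
# maxima 150/300/830/160 mN/m); every other parameter is an illustrative
# free choice. Lift-off anchors are placed so that the pressure passes
# the 0.1 mN/m detection threshold at exactly the printed area.

preset_names <- function() c("SM-brain", "SM-egg", "POPC", "Chol", "7KC")

#' Calibrated pure-film presets
#'
#' Returns the forward model and simulation defaults for one of the
#' shipped synthetic lipid films:
#' \describe{
#'   \item{`"SM-brain"`}{liquid-expanded film with a transition plateau
#'     at 5 mN/m, lift-off 91 \eqn{\AA^2}, condensed branch reaching
#'     \eqn{C_s^{-1}} = 150 mN/m, collapse plateau at 69 mN/m.}
#'   \item{`"SM-egg"`}{as above but lift-off 78 \eqn{\AA^2} and a solid
#'     condensed branch (\eqn{C_s^{-1}} = 300 mN/m).}
#'   \item{`"POPC"`}{expanded film without any transition, collapse at
#'     50 mN/m.}
#'   \item{`"Chol"`}{highly condensed linear film,
#'     \eqn{C_s^{-1}} up to 830 mN/m, collapse at 46 mN/m.}
#'   \item{`"7KC"`}{liquid-condensed film, \eqn{C_s^{-1}} up to
#'     160 mN/m, collapse at 46 mN/m.}
#' }
#'
#' @param name preset name.
#' @param collapse_pi optional collapse-pressure override (e.g. 43 or 47
#'   mN/m for the temperature dependence of oxysterol films).
#' @return list with `name`, `model` ([eos_model()]), `temperature`,
#'   `n_points`, `area_range`, `component` and `expected` (the
#'   calibration targets the descriptors should recover).
#' @export
#' @examples
#' eos_preset("Chol")$expected
eos_preset <- function(name = preset_names(), collapse_pi = NULL) {
  name <- match.arg(name)
  kT <- kT_film(20)
  spec <- switch(name,
    "SM-brain" = {
      pi_coh <- kT / (91 - 40) - 0.1
      list(model = eos_model("piecewise_LE_plateau_LC", omega = 40,
                             pi_coh = pi_coh, slope = 150 / 55,
                             plateau_pi = 5, plateau_area_end = 55,
                             collapse_pi = collapse_pi %||% 69),
           area_range = c(110, 26),
           component = new_component("SM-brain", "sphingolipid"),
           expected = list(lift_off = 91, collapse = 69, cs_max = 150,
                           state = "LC", transition = 5))
    },
    "SM-egg" = {
      pi_coh <- kT / (78 - 40) - 0.1
      list(model = eos_model("piecewise_LE_plateau_LC", omega = 40,
                             pi_coh = pi_coh, slope = 300 / 55,
                             plateau_pi = 5, plateau_area_end = 55,
                             collapse_pi = collapse_pi %||% 69),
           area_range = c(95, 38),
           component = new_component("SM-egg", "sphingolipid"),
           expected = list(lift_off = 78, collapse = 69, cs_max = 300,
                           state = "S", transition = 5))
    },
    "POPC" = list(
      model = eos_model("linear_condensed", omega = 100, slope = 0.9,
                        collapse_pi = collapse_pi %||% 50),
      area_range = c(115, 40),
      component = new_component("POPC", "phospholipid"),
      expected = list(lift_off = 100, collapse = 50, cs_max = 90,
                      state = "LC", transition = NULL)),
    "Chol" = list(
      model = eos_model("linear_condensed", omega = 40.5,
                        slope = 830 / 40.5,
                        collapse_pi = collapse_pi %||% 46),
      area_range = c(46, 36),
      component = new_component("Chol", "sterol"),
      expected = list(lift_off = 40.5, collapse = 46, cs_max = 830,
                      state = "S", transition = NULL)),
    "7KC" = list(
      model = eos_model("linear_condensed", omega = 48, slope = 160 / 48,
                        collapse_pi = collapse_pi %||% 46),
      area_range = c(65, 30),
      component = new_component("7KC", "sterol"),
      expected = list(lift_off = 48, collapse = 46, cs_max = 160,
                      state = "LC", transition = NULL)))
  c(list(name = name, temperature = 20, n_points = 500L), spec)
}

#' Simulate a shipped pure-film preset
#'
#' @param name preset name (see [eos_preset()]).
#' @param noise `c(sigma_pi, sigma_area)`, default noise-free.
#' @param seed integer seed.
#' @param collapse_pi optional collapse override.
#' @param n_points optional point-count override.
#' @return an [isotherm].
#' @export
simulate_preset <- function(name, noise = c(0, 0), seed = NULL,
                            collapse_pi = NULL, n_points = NULL) {
  ps <- eos_preset(name, collapse_pi = collapse_pi)
  simulate_pure_isotherm(ps$model, ps$temperature,
                         n_points %||% ps$n_points, ps$area_range,
                         noise = noise, seed = seed,
                         component = ps$component,
                         provenance = list(preset = ps$name))
}

mixture_preset_names <- function() {
  c("Chol-POPC", "7KC-POPC", "Chol-SM", "7KC-SM",
    "Chol-POPC:SM", "7KC-POPC:SM")
}

#' Calibrated mixture presets
#'
#' Binary (and pseudo-binary ternary) mixing scenarios built from the
#' pure-film presets with Margules-type excess models. Endpoint 2 is
#' always the sterol; `x2` is the sterol mole fraction. Calibration
#' anchors: the cholesterol/POPC excess amplitude is twice the
#' 7-ketocholesterol/POPC one (interaction-strength ratio 2); the
#' sphingomyelin/sterol model has its continuous minimum at
#' \eqn{X \approx 0.27} and changes sign at \eqn{X = 0.7}; the ternary
#' pseudo-binary models change sign at \eqn{X = 0.8}.
#'
#' @param name mixture preset name.
#' @return list with `name`, `endpoint_1`, `endpoint_2` (forward
#'   models), `components`, `excess` ([excess_model()]), `temperature`
#'   and default `x2` grid.
#' @export
mixture_preset <- function(name = mixture_preset_names()) {
  name <- match.arg(name)
  popc <- eos_preset("POPC")
  chol <- eos_preset("Chol")
  kc <- eos_preset("7KC")
  sm <- eos_preset("SM-brain")
  x_default <- seq(0, 1, by = 0.1)
  spec <- switch(name,
    "Chol-POPC" = list(endpoint_1 = popc, endpoint_2 = chol,
                       excess = excess_model(alpha0 = -8)),
    "7KC-POPC" = list(endpoint_1 = popc, endpoint_2 = kc,
                      excess = excess_model(alpha0 = -4)),
    "Chol-SM" = list(endpoint_1 = sm, endpoint_2 = chol,
                     excess = excess_model(alpha0 = -5, alpha1 = -12.5)),
    "7KC-SM" = list(endpoint_1 = sm, endpoint_2 = kc,
                    excess = excess_model(alpha0 = -5.5,
                                          alpha1 = -13.75)),
    "Chol-POPC:SM" = list(
      endpoint_1 = list(blend = eos_blend(list(popc$model, sm$model),
                                          c(0.5, 0.5)),
                        component = new_component("POPC:SM(1:1)",
                                                  "pseudo")),
      endpoint_2 = chol,
      excess = excess_model(alpha0 = -4, alpha1 = -4 / 0.6)),
    "7KC-POPC:SM" = list(
      endpoint_1 = list(blend = eos_blend(list(popc$model, sm$model),
                                          c(0.5, 0.5)),
                        component = new_component("POPC:SM(1:1)",
                                                  "pseudo")),
      endpoint_2 = kc,
      excess = excess_model(alpha0 = -8, alpha1 = -8 / 0.6)))
  e1 <- spec$endpoint_1
  model_1 <- if (!is.null(e1$blend)) e1$blend else e1$model
  comp_1 <- e1$component
  list(name = name,
       endpoint_1 = model_1, endpoint_2 = spec$endpoint_2$model,
       components = list(comp_1, spec$endpoint_2$component),
       excess = spec$excess, temperature = 20, x2 = x_default)
}

#' Simulate a shipped mixture preset
#'
#' @param name mixture preset name (see [mixture_preset()]).
#' @param x2 composition grid override.
#' @param noise `c(sigma_pi, sigma_area)`.
#' @param seed master seed.
#' @param n_points points per member.
#' @return a [mixture_series].
#' @export
#' @examples
#' ser <- simulate_mixture_preset("Chol-POPC", x2 = c(0, 0.5, 1))
#' gibbs_composition_scan(ser, pi_target = 30)$min_value
simulate_mixture_preset <- function(name, x2 = NULL, noise = c(0, 0),
                                    seed = NULL, n_points = 400L) {
  ps <- mixture_preset(name)
  simulate_mixture_series(ps$endpoint_1, ps$endpoint_2,
                          x2 %||% ps$x2, excess = ps$excess,
                          temperature = ps$temperature,
                          n_points = n_points, noise = noise,
                          seed = seed, components = ps$components)
}
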