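# parametric excess-area model with closed-form excess Gibbs energy ------
#
# Margules-type form: A^exc(pi, X) = X(1-X) [alpha0 + alpha1 (1 - 2X)] g(pi)
# with X the mole fraction of endpoint 2 (the sterol convention).
# g is either constant 1 or the linear decay 1 - pi/pi_ref, so the
# pressure integral has a closed form and the generated mixtures carry
# analytic ground truth.

#' Construct a parametric excess-area mixing model
#'
#' @param alpha0 symmetric interaction amplitude, \eqn{\AA^2} (negative =
#'   attractive / condensing).
#' @param alpha1 asymmetry amplitude, \eqn{\AA^2}.
#' @param pressure_profile `"constant"` (`g(pi) = 1`) or
#'   `"linear_decay"` (`g(pi) = 1 - pi/pi_ref`).
#' @param pi_ref reference pressure of the linear decay, mN/m.
#' @return an object of class `excess_model`.
#' @export
#' @examples
#' ex <- excess_model(alpha0 = -8)
#' excess_area_model(ex, pi = 30, x2 = 0.5)  # -2
excess_model <- function(alpha0, alpha1 = 0,
                         pressure_profile = c("constant", "linear_decay"),
                         pi_ref = NULL) {
  pressure_profile <- match.arg(pressure_profile)
  if (!is.numeric(alpha0) || !is.numeric(alpha1)) {
    mf_error("alpha0 and alpha1 must be numeric", "mf_argument_error")
  }
  if (pressure_profile == "linear_decay" &&
      (is.null(pi_ref) || pi_ref <= 0)) {
    mf_error("linear_decay needs pi_ref > 0", "mf_argument_error")
  }
  structure(list(alpha0 = alpha0, alpha1 = alpha1,
                 pressure_profile = pressure_profile, pi_ref = pi_ref),
            class = "excess_model")
}

excess_g <- function(model, pi) {
  switch(model$pressure_profile,
         constant = rep(1, length(pi)),
         linear_decay = 1 - pi / model$pi_ref)
}

excess_g_integral <- function(model, pi_target) {
  switch(model$pressure_profile,
         constant = pi_target,
         linear_decay = pi_target - pi_target^2 / (2 * model$pi_ref))
}

#' Evaluate the parametric excess area
#'
#' @param model an [excess_model()] (or `NULL`, meaning ideal mixing).
#' @param pi surface pressures, mN/m.
#' @param x2 mole fraction of endpoint 2.
#' @return excess areas, \eqn{\AA^2}/molecule; identically 0 at
#'   `x2 = 0` and `x2 = 1`.
#' @export
excess_area_model <- function(model, pi, x2) {
  if (is.null(model)) return(rep(0, max(length(pi), length(x2))))
  stopifnot(inherits(model, "excess_model"))
  x2 * (1 - x2) * (model$alpha0 + model$alpha1 * (1 - 2 * x2)) *
    excess_g(model, pi)
}

#' Closed-form excess Gibbs energy of the parametric model
#'
#' Ground-truth oracle for the mixing analysis:
#' \eqn{\Delta G^{exc} = N_A X(1-X)[\alpha_0 + \alpha_1(1-2X)]
#' \int_0^{\pi^*} g\,d\pi} with the 6.02214076 J/mol per
#' \eqn{\AA^2\cdot}mN/m unit bridge.
#'
#' @param model an [excess_model()] (or `NULL` for ideal mixing).
#' @param x2 mole fraction(s) of endpoint 2.
#' @param pi_target upper integration limit, mN/m, >= 0.
#' @return J/mol (vectorized over `x2`).
#' @export
#' @examples
#' analytic_excess_gibbs(excess_model(-8), 0.5, 30)  # -361.33 J/mol
analytic_excess_gibbs <- function(model, x2, pi_target) {
  if (any(pi_target < 0)) {
    mf_error("pi_target must be non-negative", "mf_argument_error")
  }
  if (is.null(model)) return(rep(0, length(x2)))
  stopifnot(inherits(model, "excess_model"))
  .GIBBS_BRIDGE * x2 * (1 - x2) *
    (model$alpha0 + model$alpha1 * (1 - 2 * x2)) *
    excess_g_integral(model, pi_target)
}
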