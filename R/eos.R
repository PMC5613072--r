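# two-dimensional equations of state for synthetic pure films ------------
#
# Supported kinds:
#   volmer:            pi = kT/(A - omega) - pi_coh   (clipped at 0)
#   linear_condensed:  pi = slope * (omega - A)       (clipped at 0)
#   piecewise_LE_plateau_LC:
#       Volmer LE branch up to plateau_pi, a first-order transition
#       plateau down to plateau_area_end, then a linear condensed branch
#       pi = plateau_pi + slope * (plateau_area_end - A).
# A collapse overlay caps the curve at collapse_pi, rendered either as a
# hard plateau or as a 10% pressure drop over 2 A^2 followed by a flat.

#' Construct a two-dimensional equation-of-state model
#'
#' Forward model for a synthetic pure-film isotherm. All branches are
#' analytic so that every descriptor has a closed-form oracle.
#'
#' @param kind `"volmer"`, `"linear_condensed"` or
#'   `"piecewise_LE_plateau_LC"`.
#' @param omega co-area (\eqn{\AA^2}): Volmer excluded area, or the
#'   zero-pressure intercept of a linear condensed film.
#' @param pi_coh Volmer cohesion pressure, mN/m (lift-off at
#'   `omega + kT/pi_coh`).
#' @param slope condensed-branch slope, mN/m per \eqn{\AA^2}.
#' @param plateau_pi transition plateau pressure, mN/m (piecewise kind).
#' @param plateau_area_end area at which the plateau ends and the
#'   condensed branch begins, \eqn{\AA^2}.
#' @param collapse_pi optional collapse pressure, mN/m (must exceed
#'   `plateau_pi` when both are set).
#' @param collapse_mode `"plateau"` (hard plateau at `collapse_pi`) or
#'   `"drop"` (10% pressure fall over 2 \eqn{\AA^2}, then flat).
#' @return an object of class `eos_model`.
#' @export
#' @examples
#' m <- eos_model("volmer", omega = 38, pi_coh = 8, collapse_pi = 50)
#' pi_of_area(m, 58, temperature = 20)
eos_model <- function(kind = c("volmer", "linear_condensed",
                               "piecewise_LE_plateau_LC"),
                      omega, pi_coh = 0, slope = NULL,
                      plateau_pi = NULL, plateau_area_end = NULL,
                      collapse_pi = NULL,
                      collapse_mode = c("plateau", "drop")) {
  kind <- match.arg(kind)
  collapse_mode <- match.arg(collapse_mode)
  if (!is.numeric(omega) || length(omega) != 1L || omega <= 0) {
    mf_error("omega must be a positive scalar", "mf_argument_error")
  }
  if (kind == "volmer" && pi_coh <= 0) {
    mf_error("volmer films need pi_coh > 0 (finite lift-off)",
             "mf_argument_error")
  }
  if (kind %in% c("linear_condensed", "piecewise_LE_plateau_LC")) {
    if (is.null(slope) || slope <= 0) {
      mf_error("condensed branches need slope > 0", "mf_argument_error")
    }
  }
  if (kind == "piecewise_LE_plateau_LC") {
    if (is.null(plateau_pi) || plateau_pi <= 0 ||
        is.null(plateau_area_end) || plateau_area_end <= omega) {
      mf_error(paste("piecewise films need plateau_pi > 0 and",
                     "plateau_area_end > omega"), "mf_argument_error")
    }
    if (pi_coh <= 0) {
      mf_error("piecewise films need pi_coh > 0 on the LE branch",
               "mf_argument_error")
    }
  }
  if (!is.null(collapse_pi)) {
    if (collapse_pi <= 0 ||
        (!is.null(plateau_pi) && collapse_pi <= plateau_pi)) {
      mf_error("collapse_pi must be positive and exceed plateau_pi",
               "mf_argument_error")
    }
  }
  structure(list(kind = kind, omega = omega, pi_coh = pi_coh,
                 slope = slope, plateau_pi = plateau_pi,
                 plateau_area_end = plateau_area_end,
                 collapse_pi = collapse_pi,
                 collapse_mode = collapse_mode),
            class = "eos_model")
}

#' @export
print.eos_model <- function(x, ...) {
  cat(sprintf("<eos_model> %s, omega = %g A^2", x$kind, x$omega))
  if (!is.null(x$collapse_pi)) {
    cat(sprintf(", collapse %g mN/m (%s)", x$collapse_pi, x$collapse_mode))
  }
  cat("\n")
  invisible(x)
}

# pre-collapse pressure of the raw EOS (no collapse overlay)
eos_pi_raw <- function(model, area, kT) {
  switch(model$kind,
    volmer = pmax(0, kT / (area - model$omega) - model$pi_coh),
    linear_condensed = pmax(0, model$slope * (model$omega - area)),
    piecewise_LE_plateau_LC = {
      a_hi <- model$omega + kT / (model$plateau_pi + model$pi_coh)
      a_lo <- model$plateau_area_end
      p <- numeric(length(area))
      le <- area >= a_hi
      pl <- area < a_hi & area >= a_lo
      lc <- area < a_lo
      p[le] <- pmax(0, kT / (area[le] - model$omega) - model$pi_coh)
      p[pl] <- model$plateau_pi
      p[lc] <- model$plateau_pi + model$slope * (a_lo - area[lc])
      p
    })
}

# area at which the raw EOS reaches pressure `pi` (single-valued inverse;
# at exactly plateau_pi the expanded-side area is returned)
eos_area_raw <- function(model, pi, kT) {
  switch(model$kind,
    volmer = model$omega + kT / (pi + model$pi_coh),
    linear_condensed = model$omega - pi / model$slope,
    piecewise_LE_plateau_LC = {
      a <- numeric(length(pi))
      le <- pi <= model$plateau_pi
      lc <- !le
      a[le] <- model$omega + kT / (pi[le] + model$pi_coh)
      a[lc] <- model$plateau_area_end -
        (pi[lc] - model$plateau_pi) / model$slope
      a
    })
}

eos_collapse_area <- function(model, kT) {
  if (is.null(model$collapse_pi)) return(NA_real_)
  eos_area_raw(model, model$collapse_pi, kT)
}

#' Surface pressure of an EOS model at given areas
#'
#' Evaluates the model (with its collapse overlay, if any) at molecular
#' areas `area`. For Volmer films areas at or below the co-area are a
#' domain error.
#'
#' @param model an [eos_model()].
#' @param area molecular areas, \eqn{\AA^2} (vectorized).
#' @param temperature subphase temperature, degrees C (enters via
#'   \eqn{k_B T}).
#' @return surface pressures, mN/m.
#' @export
pi_of_area <- function(model, area, temperature = 20) {
  stopifnot(inherits(model, "eos_model"))
  kT <- kT_film(temperature)
  if (model$kind == "volmer" && any(area <= model$omega)) {
    mf_error(sprintf(
      "volmer EOS undefined for A <= omega (= %g A^2)", model$omega),
      "mf_domain_error")
  }
  p <- eos_pi_raw(model, area, kT)
  if (!is.null(model$collapse_pi)) {
    a_coll <- eos_collapse_area(model, kT)
    past <- area < a_coll
    if (model$collapse_mode == "plateau") {
      p[past] <- model$collapse_pi
    } else {
      depth <- 0.1 * model$collapse_pi
      p[past] <- model$collapse_pi -
        depth * pmin(1, (a_coll - area[past]) / 2)
    }
    p[!past] <- pmin(p[!past], model$collapse_pi)
  }
  p
}

#' Molecular area of an EOS model at given pressures
#'
#' Closed-form inverse of the pre-collapse branch. Pressures above the
#' collapse pressure are a range error unless `beyond_collapse = TRUE`
#' (used when blending endpoint equations of state into mixed films).
#'
#' @param model an [eos_model()].
#' @param pressure surface pressures, mN/m, >= 0 (vectorized).
#' @param temperature subphase temperature, degrees C.
#' @param beyond_collapse evaluate the raw EOS past its collapse.
#' @return molecular areas, \eqn{\AA^2}.
#' @export
area_of_pressure <- function(model, pressure, temperature = 20,
                             beyond_collapse = FALSE) {
  stopifnot(inherits(model, "eos_model"))
  if (any(pressure < 0)) {
    mf_error("pressure must be non-negative", "mf_argument_error")
  }
  if (!beyond_collapse && !is.null(model$collapse_pi) &&
      any(pressure > model$collapse_pi + 1e-9)) {
    mf_error(sprintf("pressure exceeds the collapse pressure %g mN/m",
                     model$collapse_pi), "mf_range_error")
  }
  kT <- kT_film(temperature)
  eos_area_raw(model, pressure, kT)
}

#' Blend of endpoint equations of state (pseudo-component forward model)
#'
#' Represents a fixed-ratio ideal blend of EOS models as a single
#' endpoint for pseudo-binary ternary simulations: its area at pressure
#' is the weight-averaged area of the constituents.
#'
#' @param models list of [eos_model()] objects.
#' @param weights mole-fraction weights, summing to 1.
#' @param collapse_pi collapse pressure of the blended film; default the
#'   weight-averaged constituent collapse pressures.
#' @return an object of class `eos_blend`.
#' @export
eos_blend <- function(models, weights, collapse_pi = NULL) {
  if (!is.list(models) || !all(vapply(models, inherits, TRUE, "eos_model"))) {
    mf_error("models must be a list of eos_model objects",
             "mf_argument_error")
  }
  if (length(weights) != length(models) || abs(sum(weights) - 1) > 1e-9) {
    mf_error("weights must match models and sum to 1",
             "mf_argument_error")
  }
  if (is.null(collapse_pi)) {
    cps <- vapply(models, function(m) m$collapse_pi %||% NA_real_, 0)
    if (all(is.finite(cps))) collapse_pi <- sum(weights * cps)
  }
  structure(list(models = models, weights = weights,
                 collapse_pi = collapse_pi),
            class = "eos_blend")
}

blend_area_of_pressure <- function(end, pressure, temperature) {
  if (inherits(end, "eos_model")) {
    return(area_of_pressure(end, pressure, temperature,
                            beyond_collapse = TRUE))
  }
  stopifnot(inherits(end, "eos_blend"))
  Reduce(`+`, Map(function(m, w) {
    w * area_of_pressure(m, pressure, temperature, beyond_collapse = TRUE)
  }, end$models, end$weights))
}

endpoint_collapse_pi <- function(end) {
  cp <- end$collapse_pi
  if (is.null(cp) || !is.finite(cp)) {
    mf_error("mixture endpoints need a collapse pressure",
             "mf_argument_error")
  }
  cp
}
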