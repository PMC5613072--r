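# isotherm data model: one compression run of a Langmuir film ---------------

#' Film component descriptor
#'
#' A lipid (or pseudo-component standing for a fixed-ratio blend) with an
#' optional molecular geometry used by [packing_parameter()].
#'
#' @param component_id character, e.g. `"POPC"`, `"Chol"`.
#' @param role one of `"phospholipid"`, `"sphingolipid"`, `"sterol"`,
#'   `"pseudo"`, `"other"`.
#' @param geometry optional named list with strictly positive entries `V`
#'   (chain volume, \eqn{\AA^3}), `a` (head-group area, \eqn{\AA^2}) and
#'   `l_c` (critical chain length, \eqn{\AA}).
#' @return an object of class `component`.
#' @export
#' @examples
#' new_component("Chol", role = "sterol",
#'               geometry = list(V = 400, a = 19, l_c = 17.5))
new_component <- function(component_id,
                          role = c("other", "phospholipid", "sphingolipid",
                                   "sterol", "pseudo"),
                          geometry = NULL) {
  if (!is.character(component_id) || length(component_id) != 1L ||
      !nzchar(component_id)) {
    mf_error("component_id must be a non-empty string", "mf_argument_error")
  }
  role <- match.arg(role)
  if (!is.null(geometry)) {
    need <- c("V", "a", "l_c")
    if (!all(need %in% names(geometry))) {
      mf_error("geometry must supply V, a and l_c", "mf_argument_error")
    }
    vals <- unlist(geometry[need])
    if (!all(is.finite(vals)) || any(vals <= 0)) {
      mf_error("geometry values V, a, l_c must be strictly positive",
               "mf_argument_error")
    }
    geometry <- as.list(vals)
  }
  structure(list(component_id = component_id, role = role,
                 geometry = geometry),
            class = "component")
}

#' @export
print.component <- function(x, ...) {
  cat("<component>", x$component_id, sprintf("(%s)", x$role), "\n")
  if (!is.null(x$geometry)) {
    cat(sprintf("  V = %g A^3, a = %g A^2, l_c = %g A\n",
                x$geometry$V, x$geometry$a, x$geometry$l_c))
  }
  invisible(x)
}

normalize_components <- function(components) {
  if (is.numeric(components) && !is.null(names(components))) {
    components <- data.frame(component_id = names(components),
                             mole_fraction = as.numeric(components),
                             stringsAsFactors = FALSE)
  }
  if (!is.data.frame(components) ||
      !all(c("component_id", "mole_fraction") %in% names(components))) {
    mf_error(paste("components must be a named numeric vector or a",
                   "data.frame with columns component_id, mole_fraction"),
             "mf_validation_error")
  }
  x <- components$mole_fraction
  if (any(!is.finite(x)) || any(x < -1e-12) || any(x > 1 + 1e-12)) {
    mf_error("mole fractions must lie in [0, 1]", "mf_validation_error")
  }
  if (abs(sum(x) - 1) > 1e-9) {
    mf_error(sprintf(
      "mole fractions of components (%s) sum to %.10g, not 1",
      paste(components$component_id, collapse = ", "), sum(x)),
      "mf_validation_error")
  }
  components[, c("component_id", "mole_fraction")]
}

#' Construct a validated pi-A isotherm
#'
#' Builds the canonical internal representation of one compression run:
#' points ordered by strictly decreasing molecular area (the compression
#' direction). Input point order is auto-detected; exact duplicate areas
#' are averaged (barrier jitter) and noted in the validation report
#' attached as attribute `"validation"`.
#'
#' @param area molecular areas, \eqn{\AA^2}/molecule, all > 0.
#' @param pressure surface pressures, mN/m. Values below -0.5 mN/m (beyond
#'   sensor drift) are rejected.
#' @param temperature subphase temperature, degrees Celsius.
#' @param components named numeric vector of mole fractions (summing to 1
#'   within 1e-9) or a data.frame with columns `component_id`,
#'   `mole_fraction`.
#' @param provenance free-form named list of metadata (compression rate,
#'   subphase, ...).
#' @return an object of class `isotherm` with fields `area`, `pressure`,
#'   `temperature`, `components`, `provenance`.
#' @export
#' @examples
#' a <- seq(100, 40, length.out = 200)
#' iso <- isotherm(a, pmax(0, 2 * (60 - a)), 20, c(POPC = 1))
#' iso
isotherm <- function(area, pressure, temperature, components,
                     provenance = list()) {
  if (!is.numeric(area) || !is.numeric(pressure)) {
    mf_error("area and pressure must be numeric", "mf_validation_error")
  }
  if (length(area) != length(pressure)) {
    mf_error("area and pressure must have equal length",
             "mf_validation_error")
  }
  if (any(!is.finite(area)) || any(!is.finite(pressure))) {
    mf_error("area and pressure must be finite", "mf_validation_error")
  }
  if (any(area <= 0)) {
    mf_error("all areas must be strictly positive", "mf_validation_error")
  }
  if (any(pressure < -0.5)) {
    mf_error(paste("pressures below -0.5 mN/m exceed sensor drift and are",
                   "rejected"), "mf_validation_error")
  }
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature)) {
    mf_error("temperature must be a finite scalar (degrees C)",
             "mf_validation_error")
  }
  components <- normalize_components(components)

  notes <- character()
  # canonical order: area strictly decreasing (compression direction)
  o <- order(area, decreasing = TRUE)
  if (is.unsorted(rev(o))) notes <- c(notes, "points reordered to compression order")
  area <- area[o]
  pressure <- pressure[o]
  dup <- duplicated(area)
  if (any(dup)) {
    notes <- c(notes, sprintf("%d duplicate areas averaged", sum(dup)))
    ua <- unique(area)
    idx <- match(area, ua)
    pressure <- as.numeric(rowsum(pressure, idx) / tabulate(idx))
    area <- ua
  }
  if (length(area) < 10L) {
    mf_error("an isotherm needs at least 10 distinct points",
             "mf_validation_error")
  }
  structure(
    list(area = area, pressure = pressure,
         temperature = temperature, components = components,
         provenance = provenance),
    class = "isotherm", validation = notes)
}

n_points <- function(iso) length(iso$area)

#' @export
print.isotherm <- function(x, ...) {
  comp <- paste(sprintf("%s(%.3g)", x$components$component_id,
                        x$components$mole_fraction), collapse = " + ")
  cat(sprintf(
    "<isotherm> %d points, A %.4g-%.4g A^2/molecule, pi %.3g-%.4g mN/m\n",
    n_points(x), min(x$area), max(x$area), min(x$pressure), max(x$pressure)))
  cat(sprintf("  %s at %g C\n", comp, x$temperature))
  invisible(x)
}

#' @export
as.data.frame.isotherm <- function(x, ...) {
  data.frame(area_A2 = x$area, pressure_mN_m = x$pressure)
}

#' @export
format.isotherm <- function(x, ...) {
  sprintf("<isotherm: %d points at %g C>", n_points(x), x$temperature)
}
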