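# mixture series: isotherms of one (pseudo-)binary pair across mole
# fractions at a single temperature --------------------------------------

as_component <- function(x) {
  if (inherits(x, "component")) return(x)
  if (is.character(x) && length(x) == 1L) return(new_component(x))
  mf_error("endpoint must be a component object or a component id string",
           "mf_argument_error")
}

#' Assemble a mixture series
#'
#' Collects isotherms of the same binary (or pseudo-binary) pair recorded
#' at one temperature across mole fractions of endpoint 2 (the sterol, by
#' the package's convention). The pure endpoints `x2 = 0` and `x2 = 1`
#' are required; members are sorted by composition.
#'
#' @param members list of [isotherm] objects.
#' @param x2 mole fraction of endpoint 2 for each member (unique,
#'   including 0 and 1).
#' @param endpoint_1,endpoint_2 [new_component()] objects (or id strings).
#' @return an object of class `mixture_series`.
#' @export
mixture_series <- function(members, x2, endpoint_1, endpoint_2) {
  if (!is.list(members) || !all(vapply(members, inherits, TRUE, "isotherm"))) {
    mf_error("members must be a list of isotherm objects",
             "mf_argument_error")
  }
  if (length(members) != length(x2)) {
    mf_error("members and x2 must have equal length", "mf_argument_error")
  }
  if (any(!is.finite(x2)) || any(x2 < 0) || any(x2 > 1)) {
    mf_error("x2 values must lie in [0, 1]", "mf_argument_error")
  }
  if (anyDuplicated(round(x2, 9))) {
    mf_error("x2 values must be unique", "mf_argument_error")
  }
  if (min(x2) > 1e-9 || max(x2) < 1 - 1e-9) {
    mf_error("series must include the pure endpoints x2 = 0 and x2 = 1",
             "mf_argument_error")
  }
  temps <- vapply(members, `[[`, 0, "temperature")
  if (diff(range(temps)) > 1e-6) {
    mf_error(sprintf(
      "members span temperatures %.6g-%.6g C; a series is isothermal",
      min(temps), max(temps)), "mf_validation_error")
  }
  o <- order(x2)
  structure(list(
    endpoint_1 = as_component(endpoint_1),
    endpoint_2 = as_component(endpoint_2),
    x2 = x2[o],
    members = members[o],
    temperature = temps[1L]),
    class = "mixture_series")
}

#' @export
print.mixture_series <- function(x, ...) {
  cat(sprintf("<mixture_series> %s / %s at %g C\n",
              x$endpoint_1$component_id, x$endpoint_2$component_id,
              x$temperature))
  cat("  x2:", paste(signif(x$x2, 4), collapse = ", "), "\n")
  invisible(x)
}

series_member <- function(series, x2, tol = 1e-9) {
  i <- which(abs(series$x2 - x2) <= tol)
  if (!length(i)) {
    mf_error(sprintf("x2 = %g is not a member composition of the series",
                     x2), "mf_argument_error")
  }
  series$members[[i[1L]]]
}

#' Wrap a fixed-ratio mixed film as a pseudo-component
#'
#' Pseudo-binary treatment of ternary data: an isotherm of a fixed-ratio
#' mixture (e.g. POPC:SM 1:1) becomes a single endpoint component, so the
#' ternary system reduces to a binary scan over the sterol mole fraction.
#'
#' @param iso an [isotherm] with at least two components.
#' @param label optional pseudo-component id; default
#'   `"id1:id2(r1:r2)"` built from the composition.
#' @return list with elements `component` (role `"pseudo"`) and
#'   `isotherm` (the input relabelled as the pure pseudo-component).
#' @export
#' @examples
#' a <- seq(100, 40, length.out = 120)
#' mix <- isotherm(a, pmax(0, 1.2 * (80 - a)), 20,
#'                 c(POPC = 0.5, SM = 0.5))
#' as_pseudo_component(mix)$component
as_pseudo_component <- function(iso, label = NULL) {
  stopifnot(inherits(iso, "isotherm"))
  comps <- iso$components
  if (nrow(comps) < 2L) {
    mf_error("a pseudo-component requires a mixed film (>= 2 components)",
             "mf_argument_error")
  }
  ratio <- comps$mole_fraction / min(comps$mole_fraction)
  if (is.null(label)) {
    label <- sprintf("%s(%s)",
                     paste(comps$component_id, collapse = ":"),
                     paste(signif(ratio, 3), collapse = ":"))
  }
  comp <- new_component(label, role = "pseudo")
  out <- iso
  out$components <- data.frame(component_id = label, mole_fraction = 1,
                               stringsAsFactors = FALSE)
  out$provenance <- c(iso$provenance, list(
    pseudo_constituents = paste(sprintf("%s=%.6g", comps$component_id,
                                        comps$mole_fraction),
                                collapse = ";")))
  attr(out, "validation") <- attr(iso, "validation")
  list(component = comp, isotherm = out)
}
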