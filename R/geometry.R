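# critical packing parameter and molecular shape classification ----------

#' Critical packing parameter
#'
#' \eqn{s = V / (a \cdot l_c)} for hydrocarbon chain volume `V`
#' (\eqn{\AA^3}), head-group area `a` (\eqn{\AA^2}) and critical chain
#' length `l_c` (\eqn{\AA}). Dimensionless; maps onto molecular shapes
#' via [shape_class()].
#'
#' @param V,a,l_c strictly positive numerics (vectorized).
#' @return numeric packing parameter.
#' @export
#' @examples
#' packing_parameter(300, 30, 20)  # 0.5
packing_parameter <- function(V, a, l_c) {
  vals <- c(V, a, l_c)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    mf_error("V, a and l_c must be strictly positive", "mf_argument_error")
  }
  V / (a * l_c)
}

shape_band_table <- function() {
  data.frame(
    shape = c("cone", "truncated_cone", "cylinder",
              "inverted_truncated_cone", "inverted_cone"),
    s_min = c(0, 1 / 3, 0.95, 1.05, 3),
    s_max = c(1 / 3, 0.95, 1.05, 3, Inf))
}

#' Molecular shape from the packing parameter
#'
#' Deterministic band lookup (Israelachvili-style partition of
#' \eqn{(0, \infty)}): cone for \eqn{s \le 1/3}, truncated cone for
#' \eqn{1/3 < s < 0.95}, cylinder for \eqn{s = 1 \pm 0.05}, inverted
#' truncated cone for \eqn{1.05 < s \le 3}, inverted cone above 3.
#' Boundary values are assigned to the lower band. The mapping of the
#' qualitative shape words onto numeric bands is a convention; films mixing
#' favourably tend to pair complementary shapes.
#'
#' @param s packing parameter, > 0 (vectorized).
#' @return character vector of shape labels.
#' @export
#' @examples
#' shape_class(c(0.3, 0.7, 1, 1.3, 4))
shape_class <- function(s) {
  if (any(!is.finite(s)) || any(s <= 0)) {
    mf_error("s must be strictly positive", "mf_argument_error")
  }
  bands <- shape_band_table()
  idx <- findInterval(s, bands$s_min, left.open = TRUE)
  idx[idx < 1L] <- 1L
  bands$shape[idx]
}

#' Shape assessment of a component
#'
#' Computes the packing parameter from a component's geometry (or from
#' explicit `V`, `a`, `l_c`) and classifies its mean molecular shape.
#'
#' @param x a [new_component()] object with geometry, or the chain
#'   volume `V` (\eqn{\AA^3}).
#' @param a,l_c head-group area and critical length when `x` is numeric.
#' @return list of class `shape_assessment` with `s` and `shape`.
#' @export
shape_assessment <- function(x, a = NULL, l_c = NULL) {
  if (inherits(x, "component")) {
    if (is.null(x$geometry)) {
      mf_error(sprintf("component '%s' carries no geometry",
                       x$component_id), "mf_argument_error")
    }
    s <- packing_parameter(x$geometry$V, x$geometry$a, x$geometry$l_c)
  } else {
    s <- packing_parameter(x, a, l_c)
  }
  structure(list(s = s, shape = shape_class(s)),
            class = "shape_assessment")
}

#' @export
print.shape_assessment <- function(x, ...) {
  cat(sprintf("<shape_assessment> s = %.4g -> %s\n", x$s, x$shape))
  invisible(x)
}

#' JSON round-trip of component geometry and shape assessment
#'
#' @param component a [new_component()] object.
#' @param path optional output path.
#' @return JSON string (invisibly when written).
#' @export
component_to_json <- function(component, path = NULL) {
  stopifnot(inherits(component, "component"))
  obj <- unclass(component)
  if (!is.null(component$geometry)) {
    sa <- shape_assessment(component)
    obj$shape_assessment <- list(s = sa$s, shape = sa$shape)
  }
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                         null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname component_to_json
#' @param json JSON string or file path produced by [component_to_json()].
#' @export
component_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  new_component(obj$component_id, role = obj$role,
                geometry = obj$geometry)
}
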