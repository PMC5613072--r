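# pre-collapse branch extraction and shape-preserving regridding ----------

# Pre-collapse branch: points up to and including the FIRST occurrence of
# the global pressure maximum (a collapse plateau repeats the maximum;
# its onset terminates the branch). Post-collapse points are retained in
# the isotherm but excluded from interpolation/integration.
precollapse_branch <- function(iso) {
  i_max <- which.max(iso$pressure)
  idx <- seq_len(i_max)
  list(area = iso$area[idx], pressure = iso$pressure[idx], idx = idx)
}

# Maximal monotone pre-collapse branch: negative pressures (sensor drift)
# clipped to 0 for integration; an initial zero-pressure foot is collapsed
# onto its last point (the area closest to lift-off, so A(pi ~ 0) is the
# lift-off-side area); then a strictly-increasing record filter handles
# residual noise.
monotone_branch <- function(iso) {
  br <- precollapse_branch(iso)
  p <- pmax(br$pressure, 0)
  a <- br$area
  start <- 1L
  at_zero <- which(br$pressure <= 0)
  if (length(at_zero)) {
    # last contiguous-from-anywhere zero point before the rise
    start <- max(at_zero)
  }
  keep <- logical(length(p))
  last <- -Inf
  for (i in start:length(p)) {
    if (p[i] > last) {
      keep[i] <- TRUE
      last <- p[i]
    }
  }
  list(area = a[keep], pressure = p[keep])
}

#' Evaluate molecular area at given surface pressures
#'
#' Monotone (shape-preserving, piecewise-cubic Hermite) interpolation of A
#' as a function of \eqn{\pi} on the maximal monotone pre-collapse branch
#' of the isotherm. The returned areas are non-increasing in \eqn{\pi}.
#' Negative pressures within sensor drift are clipped to 0 before
#' interpolation.
#'
#' @param iso an [isotherm].
#' @param grid surface pressures (mN/m) at which to evaluate A.
#' @param extend_low pressures below the lowest branch pressure but not
#'   more than `extend_low` mN/m below it are answered with the area at
#'   the lowest branch pressure (flat extension below the lift-off noise
#'   floor). Default 0: out-of-range pressures are an error.
#' @return data.frame with columns `pressure` and `area`.
#' @export
#' @examples
#' a <- seq(70, 30, length.out = 100)
#' iso <- isotherm(a, 2 * (60 - a), 20, c(X = 1))
#' area_at_pressure(iso, 10)$area  # 55 exactly
area_at_pressure <- function(iso, grid, extend_low = 0) {
  stopifnot(inherits(iso, "isotherm"))
  if (!is.numeric(grid) || !length(grid) || any(!is.finite(grid))) {
    mf_error("grid must be finite numeric pressures", "mf_argument_error")
  }
  br <- monotone_branch(iso)
  if (length(br$pressure) < 2L) {
    mf_error("fewer than 2 points on the monotone pre-collapse branch",
             "mf_insufficient_data")
  }
  pmin_br <- br$pressure[1L]
  pmax_br <- br$pressure[length(br$pressure)]
  too_high <- grid > pmax_br + 1e-9
  too_low <- grid < pmin_br - extend_low - 1e-9
  if (any(too_high) || any(too_low)) {
    bad <- c(grid[too_high], grid[too_low])
    mf_error(sprintf(
      "pressure(s) %s outside the covered range [%.6g, %.6g] mN/m",
      paste(format(bad[seq_len(min(3L, length(bad)))]), collapse = ", "),
      pmin_br, pmax_br), "mf_range_error")
  }
  q <- pmin(pmax(grid, pmin_br), pmax_br)
  area <- pracma::pchip(br$pressure, br$area, q)
  data.frame(pressure = grid, area = area)
}
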