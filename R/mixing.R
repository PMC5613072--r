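# excess-area / excess Gibbs energy mixing thermodynamics ----------------
#
# A^exc = A12 - (A1*X1 + A2*X2)          (deviation from ideal mixing)
# dG^exc = N_A * integral_0^pi A^exc dpi  (J/mol)
#
# The unit bridge: 1 A^2 * mN/m per molecule = 6.02214076 J/mol.

#' Excess area per molecule of a mixed film
#'
#' \eqn{A^{exc} = A_{12} - (A_1 X_1 + A_2 X_2)} with
#' \eqn{X_2 = 1 - X_1}. Zero for ideal (additive) mixing; negative values
#' indicate condensation (attractive interactions).
#'
#' @param a12 mean molecular area of the mixed film, \eqn{\AA^2}.
#' @param a1,a2 areas of the pure component films at the same pressure.
#' @param x1 mole fraction of component 1.
#' @return numeric, \eqn{\AA^2}/molecule (vectorized).
#' @export
#' @examples
#' excess_area(45, 40, 60, 0.5)  # -5
excess_area <- function(a12, a1, a2, x1) {
  if (any(!is.finite(c(a12, a1, a2))) || any(c(a12, a1, a2) <= 0)) {
    mf_error("areas must be strictly positive", "mf_argument_error")
  }
  if (any(!is.finite(x1)) || any(x1 < 0) || any(x1 > 1)) {
    mf_error("x1 must lie in [0, 1]", "mf_argument_error")
  }
  a12 - (a1 * x1 + a2 * (1 - x1))
}

check_coverage <- function(series, pi_needed, what = "pressure grid") {
  tops <- vapply(series$members, function(m) {
    br <- monotone_branch(m)
    br$pressure[length(br$pressure)]
  }, 0)
  short <- tops + 1e-9 < pi_needed
  if (any(short)) {
    mf_error(sprintf(
      "member(s) x2 = %s do not cover the %s: pre-collapse branch tops out at %s mN/m",
      paste(signif(series$x2[short], 4), collapse = ", "), what,
      paste(signif(tops[short], 5), collapse = ", ")), "mf_range_error")
  }
  invisible(tops)
}

regrid_series <- function(series, grid, smooth = NULL) {
  vapply(series$members, function(m) {
    m <- resolve_smooth(m, smooth)
    area_at_pressure(m, grid, extend_low = 0.5)$area
  }, numeric(length(grid)))
}

#' Excess-area surface over a (pressure, composition) grid
#'
#' Regrids every member isotherm onto common pressures (monotone
#' interpolation on the pre-collapse branch) and evaluates the excess
#' area against the mole-fraction-weighted endpoint areas. Endpoint
#' columns are identically zero by construction.
#'
#' @param series a [mixture_series].
#' @param pressures evaluation pressures, mN/m.
#' @param smooth optional smoothing config applied before regridding.
#' @param sign_tol magnitude (\eqn{\AA^2}) below which an entry is
#'   reported as `"zero"` in the sign matrix.
#' @return an object of class `excess_table` with fields `pressures`,
#'   `compositions`, `a_exc` (matrix pressures x compositions) and
#'   `signs`.
#' @export
excess_area_surface <- function(series, pressures = seq(5, 35, by = 5),
                                smooth = NULL, sign_tol = 0.05) {
  stopifnot(inherits(series, "mixture_series"))
  if (any(pressures < 0)) {
    mf_error("pressures must be non-negative", "mf_argument_error")
  }
  check_coverage(series, max(pressures))
  A <- regrid_series(series, pressures, smooth)
  x <- series$x2
  i1 <- which(abs(x) <= 1e-9)[1L]
  i2 <- which(abs(x - 1) <= 1e-9)[1L]
  ideal <- outer(A[, i1], 1 - x) + outer(A[, i2], x)
  a_exc <- A - ideal
  signs <- matrix("zero", nrow(a_exc), ncol(a_exc))
  signs[a_exc > sign_tol] <- "positive"
  signs[a_exc < -sign_tol] <- "negative"
  structure(list(pressures = pressures, compositions = x,
                 a_exc = a_exc, signs = signs,
                 pi_target = NULL, dg_exc = NULL,
                 endpoint_1 = series$endpoint_1$component_id,
                 endpoint_2 = series$endpoint_2$component_id),
            class = "excess_table")
}

uniform_pi_grid <- function(pi_target, step) {
  g <- seq(0, pi_target, by = step)
  if (g[length(g)] < pi_target - 1e-12) g <- c(g, pi_target)
  g
}

#' Excess Gibbs energy of mixing at one composition
#'
#' Trapezoidal integration of the excess area over surface pressure from
#' 0 to `pi_target`, times the Avogadro-number unit bridge:
#' \eqn{\Delta G^{exc} = N_A \int_0^{\pi^*} A^{exc} d\pi} in J/mol.
#' Negative values indicate attractive, film-stabilizing interactions.
#'
#' @param series a [mixture_series].
#' @param x2 a member composition (mole fraction of endpoint 2).
#' @param pi_target upper integration limit, mN/m (default 30, the
#'   monolayer-bilayer correspondence pressure).
#' @param step uniform pressure grid step, mN/m.
#' @param smooth optional smoothing config applied before regridding.
#' @return numeric, J/mol.
#' @export
excess_gibbs_energy <- function(series, x2, pi_target = 30, step = 0.1,
                                smooth = NULL) {
  stopifnot(inherits(series, "mixture_series"))
  if (!is.numeric(pi_target) || length(pi_target) != 1L || pi_target < 0) {
    mf_error("pi_target must be a non-negative scalar", "mf_argument_error")
  }
  if (pi_target == 0) return(0)
  m12 <- series_member(series, x2)
  m1 <- series_member(series, 0)
  m2 <- series_member(series, 1)
  tops <- vapply(list(m1 = m1, m2 = m2, m12 = m12), function(m) {
    br <- monotone_branch(m)
    br$pressure[length(br$pressure)]
  }, 0)
  if (any(tops + 1e-9 < pi_target)) {
    mf_error(sprintf(
      "pi_target = %g mN/m exceeds the pre-collapse coverage (%s mN/m) of the %s isotherm(s) needed at x2 = %g",
      pi_target, paste(signif(tops[tops + 1e-9 < pi_target], 5),
                       collapse = ", "),
      paste(names(tops)[tops + 1e-9 < pi_target], collapse = ", "), x2),
      "mf_range_error")
  }
  grid <- uniform_pi_grid(pi_target, step)
  ar <- function(m) {
    area_at_pressure(resolve_smooth(m, smooth), grid,
                     extend_low = 0.5)$area
  }
  a_exc <- ar(m12) - ((1 - x2) * ar(m1) + x2 * ar(m2))
  .GIBBS_BRIDGE * pracma::trapz(grid, a_exc)
}

#' Composition scan of the excess Gibbs energy
#'
#' Evaluates \eqn{\Delta G^{exc}} at every member composition of the
#' series at one target pressure. The minimum is reported at measured
#' compositions; an optional parabolic refinement through the minimum and
#' its neighbours is available but off by default.
#'
#' @param series a [mixture_series].
#' @param pi_target target pressure, mN/m.
#' @param step integration grid step, mN/m.
#' @param smooth optional smoothing config.
#' @param refine if `TRUE`, also report the vertex of a parabola through
#'   the discrete minimum and its two neighbours (`argmin_refined`).
#' @return an object of class `gibbs_scan`: list with `curve`
#'   (data.frame `x2`, `dg_exc`), `argmin_x`, `min_value`, `pi_target`.
#' @export
gibbs_composition_scan <- function(series, pi_target = 30, step = 0.1,
                                   smooth = NULL, refine = FALSE) {
  stopifnot(inherits(series, "mixture_series"))
  if (length(series$x2) < 3L) {
    mf_error("a composition scan needs at least 3 compositions",
             "mf_insufficient_data")
  }
  errs <- character()
  dg <- vapply(series$x2, function(x) {
    tryCatch(excess_gibbs_energy(series, x, pi_target, step, smooth),
             mf_range_error = function(e) {
               errs <<- c(errs, sprintf("x2 = %g: %s", x,
                                        conditionMessage(e)))
               NA_real_
             })
  }, 0)
  if (length(errs)) {
    mf_error(paste0("composition scan failed for member(s):\n  ",
                    paste(errs, collapse = "\n  ")), "mf_range_error")
  }
  i_min <- which.min(dg)
  out <- list(curve = data.frame(x2 = series$x2, dg_exc = dg),
              argmin_x = series$x2[i_min], min_value = dg[i_min],
              pi_target = pi_target)
  if (refine && i_min > 1L && i_min < length(dg)) {
    x3 <- series$x2[(i_min - 1L):(i_min + 1L)]
    y3 <- dg[(i_min - 1L):(i_min + 1L)]
    cf <- stats::coef(stats::lm(y3 ~ x3 + I(x3^2)))
    if (is.finite(cf[3L]) && cf[3L] > 0) {
      out$argmin_refined <- as.numeric(-cf[2L] / (2 * cf[3L]))
    }
  }
  structure(out, class = "gibbs_scan")
}

#' @export
print.gibbs_scan <- function(x, ...) {
  cat(sprintf("<gibbs_scan> pi_target = %g mN/m\n", x$pi_target))
  print(x$curve, row.names = FALSE)
  cat(sprintf("  minimum %.4g J/mol at x2 = %g\n", x$min_value,
              x$argmin_x))
  invisible(x)
}

#' Full excess table: area surface plus Gibbs scan
#'
#' Convenience wrapper combining [excess_area_surface()] and
#' [gibbs_composition_scan()] in one object, mirroring the standard
#' bubble-plot + scan presentation of mixing data.
#'
#' @inheritParams excess_area_surface
#' @inheritParams gibbs_composition_scan
#' @return an `excess_table` with the `dg_exc` vector and `pi_target`
#'   filled in.
#' @export
excess_table <- function(series, pressures = seq(5, 35, by = 5),
                         pi_target = 30, step = 0.1, smooth = NULL,
                         sign_tol = 0.05) {
  tab <- excess_area_surface(series, pressures, smooth, sign_tol)
  scan <- gibbs_composition_scan(series, pi_target, step, smooth)
  tab$pi_target <- pi_target
  tab$dg_exc <- scan$curve$dg_exc
  tab$argmin_x <- scan$argmin_x
  tab$min_value <- scan$min_value
  tab
}

#' @export
print.excess_table <- function(x, ...) {
  cat(sprintf("<excess_table> %s / %s, %d pressures x %d compositions\n",
              x$endpoint_1, x$endpoint_2, length(x$pressures),
              length(x$compositions)))
  if (!is.null(x$dg_exc)) {
    cat(sprintf("  dG_exc at %g mN/m: min %.4g J/mol at x2 = %g\n",
                x$pi_target, x$min_value, x$argmin_x))
  }
  invisible(x)
}

#' Long-form export of an excess table
#'
#' One row per (pressure, composition) cell with bubble-plot-ready
#' columns: `radius` proportional to `|A^exc|` and `polarity` for the
#' bright/dark (positive/negative) convention.
#'
#' @param x an `excess_table`.
#' @param ... unused.
#' @return data.frame with columns `pi`, `x`, `a_exc`, `sign`, `radius`,
#'   `polarity`.
#' @export
as.data.frame.excess_table <- function(x, ...) {
  grid <- expand.grid(pi = x$pressures, x = x$compositions,
                      KEEP.OUT.ATTRS = FALSE)
  data.frame(grid,
             a_exc = as.vector(x$a_exc),
             sign = as.vector(x$signs),
             radius = abs(as.vector(x$a_exc)),
             polarity = ifelse(as.vector(x$a_exc) >= 0, "bright", "dark"))
}

#' Miscibility assessment from collapse pressures
#'
#' Applies the collapse-pressure criterion: in a miscible film the
#' collapse pressure varies continuously with composition, whereas
#' components that demix collapse at the pressure of one of the pure
#' films regardless of composition.
#'
#' @param series a [mixture_series].
#' @param band significance band, mN/m (default 0.6, three times the
#'   collapse-detection uncertainty).
#' @return list with `table` (data.frame `x2`, `collapse_pressure`,
#'   `mode`), `verdict` (one of `"miscible"`,
#'   `"immiscible-indication"`, `"inconclusive"`), `range` and `band`.
#' @export
miscibility_from_collapse <- function(series, band = 0.6) {
  stopifnot(inherits(series, "mixture_series"))
  rows <- lapply(seq_along(series$x2), function(i) {
    col <- tryCatch(collapse_pressure(series$members[[i]]),
                    mf_no_collapse = function(e)
                      list(pressure = NA_real_, mode = "absent"))
    data.frame(x2 = series$x2[i], collapse_pressure = col$pressure,
               mode = col$mode, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ok <- is.finite(tab$collapse_pressure)
  if (sum(ok) < 3L) {
    mf_error(sprintf(
      "collapse detected for only %d composition(s); need >= 3", sum(ok)),
      "mf_insufficient_data")
  }
  pc <- tab$collapse_pressure
  rng <- diff(range(pc[ok]))
  interior <- ok & series$x2 > 1e-9 & series$x2 < 1 - 1e-9
  pc1 <- pc[ok & series$x2 <= 1e-9][1]
  pc2 <- pc[ok & series$x2 >= 1 - 1e-9][1]
  verdict <- "inconclusive"
  coincide <- function(ref) {
    is.finite(ref) && any(interior) &&
      all(abs(pc[interior] - ref) <= band)
  }
  if (coincide(pc1) || coincide(pc2)) {
    verdict <- "immiscible-indication"
  } else if (rng > band) {
    verdict <- "miscible"
  }
  list(table = tab, verdict = verdict, range = rng, band = band)
}
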