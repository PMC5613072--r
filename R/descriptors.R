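# per-isotherm film descriptors -------------------------------------------

#' Compression modulus curve
#'
#' Computes the in-plane compression modulus
#' \eqn{C_s^{-1} = -A\,d\pi/dA} (mN/m) by centered finite differences on
#' the pre-collapse branch of the (optionally smoothed) isotherm.
#' Negative values arising from residual noise are floored at 0; the
#' number of floored points is recorded in attribute `"n_floored"`.
#'
#' @param iso an [isotherm].
#' @param smooth `NULL` (no smoothing), `TRUE`, or a list with entries
#'   `window`, `polyorder` passed to [smooth_pressure()].
#' @return data.frame with columns `area`, `pressure`, `cs` (the modulus,
#'   mN/m), covering the interior points of the branch.
#' @export
#' @examples
#' a <- seq(70, 30, length.out = 200)
#' iso <- isotherm(a, 2 * (60 - a), 20, c(X = 1))
#' cs <- compression_modulus_curve(iso)
#' head(cs)  # cs = 2 * A on a linear isotherm
compression_modulus_curve <- function(iso, smooth = NULL) {
  stopifnot(inherits(iso, "isotherm"))
  iso <- resolve_smooth(iso, smooth)
  br <- precollapse_branch(iso)
  m <- length(br$area)
  if (m < 3L) {
    mf_error("fewer than 3 points on the pre-collapse branch",
             "mf_insufficient_data")
  }
  i <- 2:(m - 1L)
  dpda <- (br$pressure[i + 1L] - br$pressure[i - 1L]) /
    (br$area[i + 1L] - br$area[i - 1L])
  cs <- -br$area[i] * dpda
  n_floored <- sum(cs < 0)
  cs[cs < 0] <- 0
  structure(
    data.frame(area = br$area[i], pressure = br$pressure[i], cs = cs),
    n_floored = n_floored)
}

#' Physical-state bands for the maximum compression modulus
#'
#' The paper-standard (Davies-Rideal convention) bands used by
#' [classify_state()]: gaseous/very expanded below 12.5 mN/m,
#' liquid-expanded 12.5-50, an intermediate LE/LC band 50-100 (reported as
#' LC with `borderline = TRUE`), liquid-condensed 100-250, solid above
#' 250 mN/m. Boundary values belong to the lower band.
#'
#' @return data.frame with columns `state`, `cs_min`, `cs_max`,
#'   `borderline`.
#' @export
state_bands <- function() {
  data.frame(
    state = c("G", "LE", "LC", "LC", "S"),
    cs_min = c(0, 12.5, 50, 100, 250),
    cs_max = c(12.5, 50, 100, 250, Inf),
    borderline = c(FALSE, FALSE, TRUE, FALSE, FALSE))
}

#' Classify the physical state of a monolayer from its modulus maximum
#'
#' Maps the maximum compression modulus to the film state label G
#' (gaseous), LE (liquid-expanded), LC (liquid-condensed) or S (solid)
#' using [state_bands()]. Values in the intermediate 50-100 mN/m band are
#' reported as LC with attribute `borderline` set.
#'
#' @param cs_max maximum compression modulus, mN/m, > 0 (vectorized).
#' @return character vector of state labels with logical attribute
#'   `borderline`.
#' @export
#' @examples
#' classify_state(c(150, 300, 160, 830))  # LC, S, LC, S
classify_state <- function(cs_max) {
  if (!is.numeric(cs_max) || !length(cs_max) || any(!is.finite(cs_max)) ||
      any(cs_max <= 0)) {
    mf_error("cs_max must be strictly positive and finite",
             "mf_argument_error")
  }
  bands <- state_bands()
  # boundary values assigned to the lower band
  idx <- findInterval(cs_max, bands$cs_min, left.open = TRUE,
                      rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L
  structure(bands$state[idx], borderline = bands$borderline[idx])
}

#' Lift-off area of an isotherm
#'
#' The largest molecular area at which the surface pressure rises
#' measurably above zero: the first crossing (in compression order) of
#' `max(3 * noise_sigma, 0.1)` mN/m that is sustained for `k` consecutive
#' points, refined by linear interpolation between the bracketing points.
#'
#' @param iso an [isotherm].
#' @param noise_sigma pressure noise standard deviation, mN/m (sensor
#'   resolution scale; default 0.01).
#' @param k number of consecutive above-threshold points required
#'   (robustness against noise spikes).
#' @param threshold optional explicit threshold overriding the noise rule.
#' @return numeric area (\eqn{\AA^2}) with attribute `threshold`.
#' @export
lift_off_area <- function(iso, noise_sigma = 0.01, k = 5L,
                          threshold = NULL) {
  stopifnot(inherits(iso, "isotherm"))
  thr <- threshold %||% max(3 * noise_sigma, 0.1)
  br <- precollapse_branch(iso)
  p <- br$pressure
  a <- br$area
  n <- length(p)
  k <- min(as.integer(k), n)
  ok <- p >= thr
  # first index starting a run of >= k above-threshold points
  run <- stats::filter(as.numeric(ok), rep(1, k), sides = 1)
  i <- which(run == k)
  if (!length(i)) {
    mf_error(sprintf(
      "pressure never sustains the lift-off threshold %.4g mN/m", thr),
      "mf_no_lift_off")
  }
  i <- i[1L] - k + 1L
  if (i == 1L || p[i - 1L] >= thr) {
    res <- a[i]
  } else {
    res <- a[i - 1L] + (thr - p[i - 1L]) *
      (a[i] - a[i - 1L]) / (p[i] - p[i - 1L])
  }
  structure(res, threshold = thr)
}

#' Limiting area by extrapolation of the last rectilinear segment
#'
#' Finds the longest sliding window on the pre-collapse branch (at least
#' `min_frac` of its length) over which the isotherm is linear
#' (\eqn{R^2 \ge} `r2_min`, negative slope, pressure span >= 1 mN/m);
#' among equally long qualifying windows the most condensed (last) one is
#' taken. The ordinary least-squares line \eqn{\pi = c_0 + c_1 A} over
#' that segment is extrapolated to \eqn{\pi = 0}, giving the limiting
#' area \eqn{-c_0/c_1}.
#'
#' @param iso an [isotherm].
#' @param r2_min minimum squared correlation for a window to qualify.
#' @param min_frac minimum window length as a fraction of the branch.
#' @param smooth optional smoothing config (see
#'   [compression_modulus_curve()]).
#' @return numeric area (\eqn{\AA^2}) with attributes `segment_area`
#'   (range), `segment_pressure` (range), `r2` and `slope`.
#' @export
limiting_area <- function(iso, r2_min = 0.999, min_frac = 0.15,
                          smooth = NULL) {
  stopifnot(inherits(iso, "isotherm"))
  iso <- resolve_smooth(iso, smooth)
  br <- precollapse_branch(iso)
  # the rectilinear segment lives on the rising part of the isotherm;
  # the zero-pressure foot (noise floor) is excluded from the search
  lifted <- br$pressure > 0.1
  a <- br$area[lifted]
  p <- br$pressure[lifted]
  n <- length(a)
  wmin <- max(10L, ceiling(min_frac * n))
  if (n < wmin) {
    mf_error("pre-collapse branch too short for segment search",
             "mf_insufficient_data")
  }
  ca <- c(0, cumsum(a)); cp <- c(0, cumsum(p))
  caa <- c(0, cumsum(a * a)); cpp <- c(0, cumsum(p * p))
  cap <- c(0, cumsum(a * p))
  for (L in seq(n, wmin)) {
    s <- seq_len(n - L + 1L)
    e <- s + L - 1L
    sx <- ca[e + 1L] - ca[s]
    sy <- cp[e + 1L] - cp[s]
    sxx <- caa[e + 1L] - caa[s]
    syy <- cpp[e + 1L] - cpp[s]
    sxy <- cap[e + 1L] - cap[s]
    varx <- sxx - sx * sx / L
    vary <- syy - sy * sy / L
    covxy <- sxy - sx * sy / L
    span <- abs(p[e] - p[s])
    r2 <- ifelse(varx > 0 & vary > 0, covxy^2 / (varx * vary), 0)
    slope <- ifelse(varx > 0, covxy / varx, 0)
    ok <- r2 >= r2_min & slope < 0 & span >= 1
    if (any(ok)) {
      j <- max(which(ok))  # most condensed qualifying window
      slope_j <- slope[j]
      meanx <- sx[j] / L
      meany <- sy[j] / L
      a0 <- meanx - meany / slope_j  # area at pi = 0
      return(structure(
        a0,
        segment_area = range(a[s[j]:e[j]]),
        segment_pressure = range(p[s[j]:e[j]]),
        r2 = r2[j], slope = slope_j, n_segment = L))
    }
  }
  mf_error(sprintf(
    "no rectilinear segment with R^2 >= %g over >= %d points", r2_min,
    wmin), "mf_no_linear_segment")
}

#' Collapse pressure of a monolayer
#'
#' Detects the onset of film failure on a fully compressed isotherm by,
#' in order of precedence at the same onset pressure: a pressure drop
#' after the global maximum (`mode = "drop"`), a sustained near-zero
#' slope plateau at the pressure maximum after the modulus maximum
#' (`mode = "plateau"`), or, as a fallback, a sharp slope-ratio break
#' (`mode = "kink"`). If both drop and plateau signatures fire, the lower
#' onset pressure is reported.
#'
#' @param iso an [isotherm].
#' @param k sustain count for the plateau/kink tests (points).
#' @param slope_eps plateau slope tolerance, mN/m per \eqn{\AA^2}.
#' @param drop_tol pressure fall (mN/m) regarded as a genuine drop, and
#'   the band below the maximum within which a plateau may sit.
#' @param kink_ratio slope-magnitude ratio (after/before) below which a
#'   breakpoint counts as a kink.
#' @return list with `pressure` (mN/m), `area` (\eqn{\AA^2}) and `mode`
#'   (one of `"drop"`, `"plateau"`, `"kink"`).
#' @export
collapse_pressure <- function(iso, k = 5L, slope_eps = 0.05,
                              drop_tol = 0.3, kink_ratio = 0.25) {
  stopifnot(inherits(iso, "isotherm"))
  a <- iso$area
  p <- iso$pressure
  n <- length(p)
  i_max <- which.max(p)
  p_max <- p[i_max]
  cand <- list()

  if (i_max < n && any(p[(i_max + 1L):n] < p_max - drop_tol)) {
    cand$drop <- list(pressure = p_max, area = a[i_max], mode = "drop")
  }

  # plateau: sustained |dpi/dA| <= slope_eps at the pressure maximum,
  # searched after the modulus maximum (so LE/LC transition plateaus at
  # lower pressure never qualify)
  cs <- tryCatch(compression_modulus_curve(iso), error = function(e) NULL)
  if (!is.null(cs) && n >= 3L) {
    m_idx <- which.max(cs$cs) + 1L  # index in full record
    s_all <- diff(p) / diff(a)
    k2 <- as.integer(k)
    if (n - 1L >= m_idx + k2 - 1L) {
      for (i in m_idx:(n - k2)) {
        if (all(abs(s_all[i:(i + k2 - 1L)]) <= slope_eps) &&
            p[i] >= p_max - drop_tol) {
          cand$plateau <- list(pressure = p[i], area = a[i],
                               mode = "plateau")
          break
        }
      }
    }
    if (is.null(cand$drop) && is.null(cand$plateau) &&
        n - 1L >= 2L * k2 + m_idx) {
      for (i in (m_idx + k2):(n - k2)) {
        before <- stats::median(abs(s_all[(i - k2):(i - 1L)]))
        after <- stats::median(abs(s_all[i:(i + k2 - 1L)]))
        if (before > 5 * slope_eps && after <= kink_ratio * before &&
            p[i] >= 0.6 * p_max) {
          cand$kink <- list(pressure = p[i], area = a[i], mode = "kink")
          break
        }
      }
    }
  }
  if (!length(cand)) {
    mf_error("no collapse signature (drop, plateau or kink) detected",
             "mf_no_collapse")
  }
  # tie-break: lowest onset pressure
  cand[[which.min(vapply(cand, `[[`, 0, "pressure"))]]
}

#' Phase-transition pressures from a compression modulus curve
#'
#' Locates liquid-type (LE to LC) transitions as local modulus minima that
#' fall below `threshold` between two above-threshold maxima. Runs
#' touching either end of the branch (the gaseous foot, the collapse) are
#' not transitions. An empty result is valid (e.g. a pure LE film).
#'
#' @param cs_curve data.frame from [compression_modulus_curve()].
#' @param threshold modulus value (mN/m) below which the film is
#'   plateau-like; default 12.5 (the gaseous band edge).
#' @return numeric vector of transition pressures (mN/m), possibly empty.
#' @export
transition_pressures <- function(cs_curve, threshold = 12.5) {
  stopifnot(is.data.frame(cs_curve), all(c("pressure", "cs") %in%
                                           names(cs_curve)))
  cs <- cs_curve$cs
  pi_ <- cs_curve$pressure
  n <- length(cs)
  if (n < 3L) return(numeric())
  below <- cs < threshold
  if (!any(below)) return(numeric())
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- numeric()
  for (j in seq_along(r$values)) {
    if (!r$values[j]) next
    s <- starts[j]; e <- ends[j]
    if (s == 1L || e == n) next  # touches branch end: foot or collapse
    if (max(cs[1:(s - 1L)]) >= threshold && max(cs[(e + 1L):n]) >= threshold) {
      i_min <- s - 1L + which.min(cs[s:e])
      out <- c(out, pi_[i_min])
    }
  }
  sort(out)
}

#' Full descriptor set for one isotherm
#'
#' Runs every per-film descriptor and assembles the result: lift-off and
#' limiting areas, collapse pressure and mode, compression-modulus
#' maximum and the pressure where it occurs, physical state, and
#' transition pressures. Descriptors whose signature is absent (no
#' collapse recorded, no lift-off) are reported as `NA` rather than
#' failing the whole set.
#'
#' @param iso an [isotherm].
#' @param noise_sigma pressure noise scale for the lift-off threshold.
#' @param smooth optional smoothing config applied to modulus, limiting
#'   area and collapse detection.
#' @param ... further arguments passed to [limiting_area()].
#' @return an object of class `descriptor_set` (a list).
#' @export
describe_isotherm <- function(iso, noise_sigma = 0.01, smooth = NULL, ...) {
  stopifnot(inherits(iso, "isotherm"))
  iso_s <- resolve_smooth(iso, smooth)
  cs <- compression_modulus_curve(iso_s)
  i_best <- which.max(cs$cs)
  cs_max <- cs$cs[i_best]
  lift <- tryCatch(lift_off_area(iso, noise_sigma = noise_sigma),
                   mf_no_lift_off = function(e) NA_real_)
  lim <- tryCatch(limiting_area(iso_s, ...),
                  mf_no_linear_segment = function(e) NA_real_,
                  mf_insufficient_data = function(e) NA_real_)
  col <- tryCatch(collapse_pressure(iso_s),
                  mf_no_collapse = function(e)
                    list(pressure = NA_real_, area = NA_real_,
                         mode = "absent"))
  state <- classify_state(cs_max)
  structure(list(
    lift_off_area = as.numeric(lift),
    limiting_area = as.numeric(lim),
    collapse_pressure = col$pressure,
    collapse_area = col$area,
    collapse_mode = col$mode,
    cs_max = cs_max,
    cs_max_pressure = cs$pressure[i_best],
    state = as.character(state),
    state_borderline = isTRUE(attr(state, "borderline")),
    transitions = transition_pressures(cs),
    temperature = iso$temperature,
    components = iso$components),
    class = "descriptor_set")
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat("<descriptor_set>\n")
  cat(sprintf("  lift-off area    : %s A^2\n", format(x$lift_off_area)))
  cat(sprintf("  limiting area    : %s A^2\n", format(x$limiting_area)))
  cat(sprintf("  collapse         : %s mN/m (%s)\n",
              format(x$collapse_pressure), x$collapse_mode))
  cat(sprintf("  Cs^-1 max        : %.4g mN/m at %.4g mN/m\n",
              x$cs_max, x$cs_max_pressure))
  cat(sprintf("  state            : %s%s\n", x$state,
              if (x$state_borderline) " (LE/LC borderline)" else ""))
  cat(sprintf("  transitions      : %s\n",
              if (length(x$transitions)) paste(signif(x$transitions, 4),
                                               collapse = ", ")
              else "none"))
  invisible(x)
}

#' JSON descriptor report
#'
#' @param desc a `descriptor_set` from [describe_isotherm()].
#' @param path optional output path.
#' @return JSON string (invisibly when written to file).
#' @export
descriptor_report_json <- function(desc, path = NULL) {
  stopifnot(inherits(desc, "descriptor_set"))
  js <- jsonlite::toJSON(unclass(desc), auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
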