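# synthetic isotherm generators: pure functions of (parameters, seed) ----

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate one pure-film isotherm from an EOS model
#'
#' Samples the model on a uniform descending area grid and applies the
#' instrument noise model: i.i.d. Gaussian pressure noise of standard
#' deviation `noise[1]` per point (Wilhelmy sensor), and a single
#' Gaussian area offset of standard deviation `noise[2]` applied to the
#' whole record (per-replicate spreading/calibration error, reflecting
#' the +/- 2 A^2/molecule replicate reproducibility of film balance
#' work). Deterministic given `seed`; exactly the closed-form EOS when
#' both sigmas are 0.
#'
#' @param model an [eos_model()].
#' @param temperature subphase temperature, degrees C.
#' @param n_points number of points (>= 50).
#' @param area_range length-2 numeric, \eqn{\AA^2} (order free).
#' @param noise length-2 numeric `c(sigma_pi, sigma_area)` in
#'   (mN/m, \eqn{\AA^2}).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @param component a [new_component()] for the metadata (default a
#'   generic `"compound"`).
#' @param provenance extra metadata list.
#' @return an [isotherm].
#' @export
#' @examples
#' m <- eos_model("volmer", omega = 38, pi_coh = 8, collapse_pi = 50)
#' iso <- simulate_pure_isotherm(m, 20, 200, c(90, 45))
simulate_pure_isotherm <- function(model, temperature = 20,
                                   n_points = 500L,
                                   area_range, noise = c(0, 0),
                                   seed = NULL, component = NULL,
                                   provenance = list()) {
  stopifnot(inherits(model, "eos_model"))
  if (n_points < 50L) {
    mf_error("n_points must be at least 50", "mf_argument_error")
  }
  if (length(area_range) != 2L || any(area_range <= 0)) {
    mf_error("area_range must be two positive areas", "mf_argument_error")
  }
  if (model$kind == "volmer" && min(area_range) <= model$omega) {
    mf_error(sprintf(
      "area range intersects A <= omega (= %g A^2) where the volmer EOS is undefined",
      model$omega), "mf_domain_error")
  }
  areas <- seq(max(area_range), min(area_range), length.out = n_points)
  p <- pi_of_area(model, areas, temperature)
  component <- component %||% new_component("compound")
  with_seed(seed, {
    if (noise[1] > 0) p <- p + stats::rnorm(n_points, 0, noise[1])
    if (noise[2] > 0) areas <- areas + stats::rnorm(1L, 0, noise[2])
    isotherm(areas, p, temperature,
             data.frame(component_id = component$component_id,
                        mole_fraction = 1, stringsAsFactors = FALSE),
             provenance = c(provenance,
                            list(generator = model$kind,
                                 seed = seed %||% "stream",
                                 sigma_pi = noise[1],
                                 sigma_area = noise[2])))
  })
}

mixture_collapse_profile <- function(end1, end2, x2) {
  c1 <- endpoint_collapse_pi(end1)
  c2 <- endpoint_collapse_pi(end2)
  (1 - x2) * c1 + x2 * c2
}

#' Simulate a binary (or pseudo-binary) mixture series
#'
#' Mixture areas follow additive blending of the endpoint equations of
#' state plus the parametric excess model:
#' \eqn{A_{12}(\pi) = X_1 A_1(\pi) + X_2 A_2(\pi) + A^{exc}(\pi, X_2)}.
#' The collapse pressure of each member interpolates linearly between the
#' endpoint collapse pressures (miscible-film behaviour) and is rendered
#' as a plateau (or drop, when both endpoints collapse by drop).
#'
#' Noise model: i.i.d. Gaussian pressure noise per point and per member;
#' the area calibration offset (`noise[2]`) is drawn once per series and
#' shared by all members, modelling the common-mode spreading/calibration
#' error of one measurement session -- excess areas are exactly invariant
#' to common-mode area shifts, which is why excess quantities are robust
#' observables.
#'
#' @param endpoint_1,endpoint_2 [eos_model()] (or [eos_blend()]) forward
#'   models; both need a collapse pressure.
#' @param x2 mole fractions of endpoint 2, including 0 and 1.
#' @param excess an [excess_model()] or `NULL` (ideal mixing).
#' @param temperature degrees C.
#' @param n_points points per member on the pre-collapse branch.
#' @param noise `c(sigma_pi, sigma_area)`.
#' @param seed master seed; member noise is drawn sequentially from it.
#' @param components optional list of two [new_component()] endpoints.
#' @return a [mixture_series]; the generating truth (excess model and
#'   programmed collapse pressures) is attached as attribute
#'   `"ground_truth"`.
#' @export
simulate_mixture_series <- function(endpoint_1, endpoint_2, x2,
                                    excess = NULL, temperature = 20,
                                    n_points = 400L, noise = c(0, 0),
                                    seed = NULL, components = NULL) {
  if (any(!is.finite(x2)) || any(x2 < 0) || any(x2 > 1)) {
    mf_error("x2 values must lie in [0, 1]", "mf_argument_error")
  }
  x2 <- sort(unique(x2))
  if (min(x2) > 1e-9 || max(x2) < 1 - 1e-9) {
    mf_error("x2 must include the pure endpoints 0 and 1",
             "mf_argument_error")
  }
  if (!is.null(excess)) stopifnot(inherits(excess, "excess_model"))
  comps <- components %||% list(new_component("component_1"),
                                new_component("component_2"))
  pc <- mixture_collapse_profile(endpoint_1, endpoint_2, x2)
  mode1 <- if (inherits(endpoint_1, "eos_model")) endpoint_1$collapse_mode else "plateau"
  mode2 <- if (inherits(endpoint_2, "eos_model")) endpoint_2$collapse_mode else "plateau"
  tail_mode <- if (mode1 == "drop" && mode2 == "drop") "drop" else "plateau"

  members <- with_seed(seed, {
    offset <- if (noise[2] > 0) stats::rnorm(1L, 0, noise[2]) else 0
    lapply(seq_along(x2), function(i) {
      x <- x2[i]
      grid <- seq(0, pc[i], length.out = n_points)
      a <- (1 - x) * blend_area_of_pressure(endpoint_1, grid, temperature) +
        x * blend_area_of_pressure(endpoint_2, grid, temperature) +
        excess_area_model(excess, grid, x)
      # render the collapse as a tail beyond the branch end
      n_tail <- max(5L, round(0.08 * n_points))
      da <- abs(stats::median(diff(a)))
      a_tail <- a[n_points] - cumsum(rep(da, n_tail))
      p_tail <- if (tail_mode == "plateau") {
        rep(pc[i], n_tail)
      } else {
        pc[i] - 0.1 * pc[i] * pmin(1, (a[n_points] - a_tail) / 2)
      }
      area <- c(a, a_tail)
      pres <- c(grid, p_tail)
      if (noise[1] > 0) pres <- pres + stats::rnorm(length(pres), 0,
                                                    noise[1])
      area <- area + offset
      cdf <- if (x <= 0) {
        data.frame(component_id = comps[[1]]$component_id,
                   mole_fraction = 1, stringsAsFactors = FALSE)
      } else if (x >= 1) {
        data.frame(component_id = comps[[2]]$component_id,
                   mole_fraction = 1, stringsAsFactors = FALSE)
      } else {
        data.frame(component_id = c(comps[[1]]$component_id,
                                    comps[[2]]$component_id),
                   mole_fraction = c(1 - x, x), stringsAsFactors = FALSE)
      }
      isotherm(area, pres, temperature, cdf,
               provenance = list(generator = "mixture_blend",
                                 x2 = x, collapse_pi = pc[i]))
    })
  })
  series <- mixture_series(members, x2, comps[[1]], comps[[2]])
  attr(series, "ground_truth") <- list(excess = excess,
                                       collapse_pi = pc,
                                       temperature = temperature)
  series
}
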