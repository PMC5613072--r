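test_that("excess area identities and argument checks", {
  expect_equal(excess_area(50, 40, 60, 0.5), 0)
  expect_equal(excess_area(45, 40, 60, 0.5), -5)
  expect_equal(excess_area(47, 40, 60, 1), 7)    # a12 - a1 at x1 = 1
  expect_error(excess_area(-1, 40, 60, 0.5), class = "mf_argument_error")
  expect_error(excess_area(45, 40, 60, 1.2), class = "mf_argument_error")
})

test_that("excess surface: ideal series is null, endpoints exactly zero", {
  ep <- std_endpoints()
  ser <- simulate_mixture_series(ep$e1, ep$e2, seq(0, 1, 0.25))
  tab <- excess_area_surface(ser, pressures = seq(5, 35, by = 5))
  expect_lt(max(abs(tab$a_exc)), 0.05)
  expect_true(all(tab$a_exc[, 1] == 0))
  expect_true(all(tab$a_exc[, ncol(tab$a_exc)] == 0))
  expect_true(all(tab$signs %in% c("zero", "positive", "negative")))
})

test_that("excess surface matches the Margules closed form", {
  ep <- std_endpoints()
  ex <- excess_model(alpha0 = -8)
  ser <- simulate_mixture_series(ep$e1, ep$e2, seq(0, 1, 0.25),
                                 excess = ex)
  tab <- excess_area_surface(ser, pressures = c(5, 15, 30))
  truth <- outer(rep(1, 3), -8 * ser$x2 * (1 - ser$x2))
  interior <- truth != 0
  expect_lt(max(abs(tab$a_exc[interior] - truth[interior]) /
                  abs(truth[interior])), 0.005)
  # attractive sterol/phospholipid pattern: negative across compositions
  expect_true(all(tab$signs[, 2:4] == "negative"))
})

test_that("unit bridge: constant 1 A^2 over 1 mN/m gives 6.022 J/mol", {
  ser <- linear_excess_series(function(p) rep(1, length(p)))
  expect_equal(excess_gibbs_energy(ser, 0.5, pi_target = 1),
               6.02214076, tolerance = 1e-6)
})

test_that("trapezoid matches closed forms for linear-in-pressure excess", {
  b <- -0.1
  ser <- linear_excess_series(function(p) b * p)
  for (pt in c(5, 15, 30)) {
    truth <- 6.02214076 * b * pt^2 / 2
    expect_equal(excess_gibbs_energy(ser, 0.5, pt), truth,
                 tolerance = abs(truth) * 0.005)
  }
})

test_that("endpoint and zero-pressure nullity are exact", {
  ep <- std_endpoints()
  ser <- simulate_mixture_series(ep$e1, ep$e2, c(0, 0.3, 1),
                                 excess = excess_model(-8))
  expect_identical(excess_gibbs_energy(ser, 0, 30), 0)
  expect_identical(excess_gibbs_energy(ser, 1, 30), 0)
  expect_identical(excess_gibbs_energy(ser, 0.3, 0), 0)
})

test_that("Gibbs energy is additive over pressure intervals", {
  ep <- std_endpoints()
  ser <- simulate_mixture_series(ep$e1, ep$e2, c(0, 0.5, 1),
                                 excess = excess_model(-8, 4))
  g15 <- excess_gibbs_energy(ser, 0.5, 15)
  g30 <- excess_gibbs_energy(ser, 0.5, 30)
  # independent evaluation of the 15 -> 30 segment on the same grid rule
  grid <- seq(15, 30, by = 0.1)
  ar <- function(x) area_at_pressure(monofilm:::series_member(ser, x),
                                     grid)$area
  seg <- 6.02214076 * pracma::trapz(grid, ar(0.5) -
                                      0.5 * ar(0) - 0.5 * ar(1))
  expect_lt(abs(g30 - (g15 + seg)), 0.1)
})

test_that("composition scans locate the programmed minima", {
  ep <- std_endpoints()
  sym <- simulate_mixture_series(ep$e1, ep$e2, seq(0, 1, 0.1),
                                 excess = excess_model(-8))
  scan <- gibbs_composition_scan(sym, 30)
  expect_equal(scan$argmin_x, 0.5)
  expect_equal(scan$curve$dg_exc[c(1, 11)], c(0, 0))

  rep_ <- simulate_mixture_series(ep$e1, ep$e2, seq(0, 1, 0.25),
                                  excess = excess_model(+6))
  scan_r <- gibbs_composition_scan(rep_, 30)
  inner <- scan_r$curve$dg_exc[2:4]
  expect_true(all(inner > 0))
  expect_true(scan_r$argmin_x %in% c(0, 1))
  expect_equal(scan_r$min_value, 0)

  asym <- simulate_mixture_series(ep$e1, ep$e2, seq(0, 1, 0.1),
                                  excess = excess_model(-5, -12.5))
  scan_a <- gibbs_composition_scan(asym, 30, refine = TRUE)
  expect_equal(scan_a$argmin_x, 0.3)  # grid point nearest 1/3
  expect_gt(scan_a$argmin_refined, 0.25)
  expect_lt(scan_a$argmin_refined, 0.31)
})

test_that("sign coherence: dg sign equals the sign of the area integral", {
  ep <- std_endpoints()
  for (a0 in c(-8, 6)) {
    ser <- simulate_mixture_series(ep$e1, ep$e2, c(0, 0.5, 1),
                                   excess = excess_model(a0))
    tab <- excess_table(ser, pressures = seq(5, 30, 5), pi_target = 30)
    integ <- 6.02214076 * pracma::trapz(tab$pressures, tab$a_exc[, 2]) *
      30 / 25  # proportionality only: compare signs
    expect_identical(sign(tab$dg_exc[2]), sign(integ))
  }
})

test_that("coverage violations raise range errors naming the members", {
  ep <- std_endpoints()
  ser <- simulate_mixture_series(ep$e1, ep$e2, c(0, 0.5, 1))
  err <- expect_error(excess_gibbs_energy(ser, 0.5, 55),
                      class = "mf_range_error")
  expect_match(conditionMessage(err), "55")
  expect_error(gibbs_composition_scan(ser, 55), class = "mf_range_error")
  expect_error(excess_area_surface(ser, pressures = c(10, 60)),
               class = "mf_range_error")
})

test_that("pseudo-component wrapping enables the ternary scan", {
  a <- seq(100, 40, length.out = 150)
  mixed <- isotherm(a, pmax(0, 1.2 * (80 - a)), 20,
                    c(POPC = 0.5, SM = 0.5))
  ps <- as_pseudo_component(mixed)
  expect_identical(ps$component$role, "pseudo")
  expect_match(ps$component$component_id, "POPC:SM")
  expect_identical(ps$isotherm$components$mole_fraction, 1)

  pure <- isotherm(a, pmax(0, 1.2 * (80 - a)), 20, c(POPC = 1))
  expect_error(as_pseudo_component(pure), class = "mf_argument_error")

  # ideal pseudo-binary ternary: scan of zeros
  ps3 <- mixture_preset("Chol-POPC:SM")
  ser <- simulate_mixture_series(ps3$endpoint_1, ps3$endpoint_2,
                                 c(0, 0.5, 1), excess = NULL,
                                 components = ps3$components)
  scan <- gibbs_composition_scan(ser, 30)
  expect_lt(max(abs(scan$curve$dg_exc)), 1)
})

test_that("miscibility verdicts follow the collapse-pressure criterion", {
  # programmed linear collapse variation across composition -> miscible
  ser <- simulate_mixture_preset("Chol-SM", x2 = seq(0, 1, 0.25))
  m <- miscibility_from_collapse(ser)
  expect_identical(m$verdict, "miscible")
  expect_gt(m$range, 0.6)
  expect_equal(m$table$collapse_pressure[1], 69, tolerance = 0.3)
  expect_equal(m$table$collapse_pressure[5], 46, tolerance = 0.3)

  # interior collapses pinned at endpoint 1 -> immiscible indication
  mk <- function(pc) simulate_pure_isotherm(
    eos_model("linear_condensed", omega = 60, slope = 2,
              collapse_pi = pc), 20, 300, c(70, 25))
  ser_i <- mixture_series(list(mk(50), mk(50.1), mk(49.9), mk(46)),
                          c(0, 0.3, 0.7, 1), "A", "B")
  expect_identical(miscibility_from_collapse(ser_i)$verdict,
                   "immiscible-indication")

  # fewer than 3 detected collapses -> insufficient data
  ser_2 <- mixture_series(list(mk(50), mk(46)), c(0, 1), "A", "B")
  expect_error(miscibility_from_collapse(ser_2),
               class = "mf_insufficient_data")
})

test_that("long-form export carries bubble-plot columns", {
  ep <- std_endpoints()
  ser <- simulate_mixture_series(ep$e1, ep$e2, c(0, 0.5, 1),
                                 excess = excess_model(-8))
  tab <- excess_table(ser, pressures = c(10, 30), pi_target = 30)
  df <- as.data.frame(tab)
  expect_setequal(names(df),
                  c("pi", "x", "a_exc", "sign", "radius", "polarity"))
  expect_equal(nrow(df), 6L)
  expect_true(all(df$radius >= 0))
  expect_true(all(df$polarity[df$a_exc < 0] == "dark"))
})
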