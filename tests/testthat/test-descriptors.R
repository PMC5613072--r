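test_that("compression modulus matches analytic derivatives", {
  # linear film: Cs^-1 = slope * A at every interior point
  iso <- linear_iso(slope = 3, a0 = 70, range = c(68, 40), n = 300)
  cs <- compression_modulus_curve(iso)
  keep <- cs$pressure > 0.5
  expect_lt(max(abs(cs$cs[keep] - 3 * cs$area[keep]) /
                  (3 * cs$area[keep])), 0.005)

  # Volmer film: Cs^-1 = A*kT/(A-omega)^2; at A = 58 this is ~58.7 mN/m
  vol <- volmer_iso(omega = 38, pi_coh = 8, n = 600, range = c(85, 45))
  csv <- compression_modulus_curve(vol)
  truth <- csv$area * kT20 / (csv$area - 38)^2
  keep <- csv$pressure > 0.5
  expect_lt(max(abs(csv$cs[keep] - truth[keep]) / truth[keep]), 0.01)
  i58 <- which.min(abs(csv$area - 58))
  expect_equal(csv$cs[i58], 58 * kT20 / 400, tolerance = 0.01)
  expect_equal(58 * kT20 / 400, 58.7, tolerance = 0.002)

  # a perfect plateau has zero modulus
  a <- seq(80, 40, length.out = 200)
  p <- ifelse(a > 60, 5, ifelse(a > 50, 5, 5 + 2 * (50 - a)))
  pl <- isotherm(a, p, 20, c(X = 1))
  cspl <- compression_modulus_curve(pl)
  expect_true(all(cspl$cs[cspl$area > 52 & cspl$area < 78] == 0))
})

test_that("state classification reproduces the reference film labels", {
  expect_identical(as.character(classify_state(150)), "LC")  # brain SM
  expect_identical(as.character(classify_state(300)), "S")   # egg SM
  expect_identical(as.character(classify_state(160)), "LC")  # 7-KC
  expect_identical(as.character(classify_state(830)), "S")   # cholesterol
  # intermediate band flagged, boundaries to the lower band
  b <- classify_state(75)
  expect_identical(as.character(b), "LC")
  expect_true(attr(b, "borderline"))
  expect_identical(as.character(classify_state(12.5)), "G")
  expect_identical(as.character(classify_state(50)), "LE")
  expect_error(classify_state(0), class = "mf_argument_error")
  expect_error(classify_state(-5), class = "mf_argument_error")
})

test_that("state bands partition (0, Inf) and are condensation-ordered", {
  order_map <- c(G = 1, LE = 2, LC = 3, S = 4)
  grid <- c(seq(0.5, 300, by = 0.5), 500, 1000, 5000)
  labels <- as.character(classify_state(grid))
  expect_true(all(labels %in% names(order_map)))
  expect_true(all(diff(order_map[labels]) >= 0))
})

test_that("lift-off detection: analytic crossing, absence, preset calibration", {
  # pi_coh chosen so pi = 0.1 mN/m at exactly A = 70
  iso <- volmer_iso(omega = 38, pi_coh = kT20 / 32 - 0.1, n = 500,
                    range = c(90, 45))
  expect_equal(as.numeric(lift_off_area(iso)), 70, tolerance = 0.2)

  flat <- isotherm(seq(80, 40, length.out = 100), rep(0, 100), 20,
                   c(X = 1))
  expect_error(lift_off_area(flat), class = "mf_no_lift_off")

  expect_equal(as.numeric(lift_off_area(simulate_preset("SM-brain"))),
               91, tolerance = 1)
  expect_equal(as.numeric(lift_off_area(simulate_preset("SM-egg"))),
               78, tolerance = 1)
})

test_that("limiting area: exact line, noisy line, curved film", {
  exact <- linear_iso(slope = 4, a0 = 42, range = c(60, 30), n = 300)
  expect_equal(as.numeric(limiting_area(exact)), 42, tolerance = 1e-6)

  meds <- sapply(1:100, function(s) {
    noisy <- linear_iso(slope = 4, a0 = 42, range = c(60, 30), n = 300,
                        sigma_pi = 0.05, seed = 3000 + s)
    as.numeric(limiting_area(noisy))
  })
  expect_lt(abs(median(meds) - 42), 0.1)

  # pure Volmer: no window of >= 30% of the branch reaches R^2 = 0.999.
  # Brute-force oracle over every window of exactly that length:
  vol <- volmer_iso(omega = 38, pi_coh = 8, n = 200, range = c(80, 45))
  br <- monofilm:::precollapse_branch(vol)
  keep <- br$pressure > 0.1
  a <- br$area[keep]; p <- br$pressure[keep]
  L <- ceiling(0.3 * length(a))
  r2 <- sapply(seq_len(length(a) - L + 1), function(s)
    stats::cor(a[s:(s + L - 1)], p[s:(s + L - 1)])^2)
  expect_lt(max(r2), 0.999)
  expect_error(limiting_area(vol, r2_min = 0.999, min_frac = 0.3),
               class = "mf_no_linear_segment")
})

test_that("collapse detection: plateau, drop, absence, programmed pressures", {
  m <- eos_model("linear_condensed", omega = 60, slope = 2,
                 collapse_pi = 46)
  iso <- simulate_pure_isotherm(m, 20, 400, c(70, 30))
  col <- collapse_pressure(iso)
  expect_equal(col$pressure, 46, tolerance = 0.2)
  expect_identical(col$mode, "plateau")

  md <- eos_model("linear_condensed", omega = 60, slope = 2,
                  collapse_pi = 46, collapse_mode = "drop")
  isod <- simulate_pure_isotherm(md, 20, 400, c(70, 30))
  cold <- collapse_pressure(isod)
  expect_equal(cold$pressure, 46, tolerance = 0.2)
  expect_identical(cold$mode, "drop")

  expect_error(collapse_pressure(volmer_iso(n = 300, range = c(80, 45))),
               class = "mf_no_collapse")

  # temperature ordering of oxysterol collapse: 43 mN/m at 30 C, 47 at 10 C
  for (pc in c(43, 47)) {
    iso_t <- simulate_preset("7KC", collapse_pi = pc)
    expect_equal(collapse_pressure(iso_t)$pressure, pc, tolerance = 0.2)
  }
})

test_that("transition detection: plateau found, pure-LE and monotone empty", {
  sm <- simulate_preset("SM-brain")
  tr <- transition_pressures(compression_modulus_curve(sm))
  expect_length(tr, 1L)
  expect_equal(tr, 5, tolerance = 0.3)

  popc <- simulate_preset("POPC")
  expect_length(transition_pressures(compression_modulus_curve(popc)), 0L)

  mono <- data.frame(pressure = 1:50, cs = seq(20, 300, length.out = 50))
  expect_length(transition_pressures(mono), 0L)
})

test_that("pressure scaling: modulus and collapse scale, areas do not", {
  base <- simulate_preset("SM-egg")
  for (c_scale in c(0.5, 2)) {
    scaled <- isotherm(base$area, base$pressure * c_scale,
                       base$temperature, base$components)
    cs0 <- compression_modulus_curve(base)
    cs1 <- compression_modulus_curve(scaled)
    expect_equal(max(cs1$cs), c_scale * max(cs0$cs), tolerance = 1e-8)
    expect_equal(collapse_pressure(scaled, slope_eps = 0.05 * c_scale,
                                   drop_tol = 0.3 * c_scale)$pressure,
                 c_scale * collapse_pressure(base)$pressure,
                 tolerance = 1e-8)
    expect_equal(as.numeric(lift_off_area(scaled,
                                          threshold = 0.1 * c_scale)),
                 as.numeric(lift_off_area(base)), tolerance = 1e-8)
    expect_equal(as.numeric(limiting_area(scaled)),
                 as.numeric(limiting_area(base)), tolerance = 1e-8)
  }
})

test_that("descriptor sets are complete and internally consistent on presets", {
  for (nm in c("SM-brain", "SM-egg", "POPC", "Chol", "7KC")) {
    d <- describe_isotherm(simulate_preset(nm))
    expect_s3_class(d, "descriptor_set")
    expect_true(is.finite(d$cs_max) && d$cs_max > 0)
    expect_true(is.finite(d$collapse_pressure) && d$collapse_pressure > 0)
    # lift-off >= limiting, up to the 0.1 mN/m threshold-crossing bias
    # (a perfectly linear film has both at the same intercept)
    expect_gte(d$lift_off_area, d$limiting_area - 0.15)
    expect_identical(d$state,
                     as.character(classify_state(d$cs_max)))
  }
  expect_error(
    compression_modulus_curve(
      structure(list(area = c(3, 2, 1), pressure = c(2, 1, 0),
                     temperature = 20), class = "isotherm")),
    class = "mf_insufficient_data")
})

test_that("descriptor JSON report round-trips its fields", {
  d <- describe_isotherm(simulate_preset("Chol"))
  js <- jsonlite::fromJSON(descriptor_report_json(d))
  expect_equal(js$cs_max, d$cs_max)
  expect_identical(js$state, d$state)
  expect_identical(js$collapse_mode, "plateau")
})
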