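test_that("noise-free generator equals the closed-form EOS", {
  m <- eos_model("volmer", omega = 38, pi_coh = 8)
  iso <- simulate_pure_isotherm(m, 20, 200, c(90, 45))
  truth <- pmax(0, kT20 / (iso$area - 38) - 8)
  expect_lt(max(abs(iso$pressure - truth)), 1e-9)
  expect_error(simulate_pure_isotherm(m, 20, 200, c(90, 30)),
               class = "mf_domain_error")
  expect_error(simulate_pure_isotherm(m, 20, 10, c(90, 45)),
               class = "mf_argument_error")
})

test_that("generators are pure functions of (parameters, seed)", {
  a <- simulate_preset("SM-brain", noise = c(0.05, 1), seed = 7)
  b <- simulate_preset("SM-brain", noise = c(0.05, 1), seed = 7)
  expect_identical(a$area, b$area)
  expect_identical(a$pressure, b$pressure)
  c_ <- simulate_preset("SM-brain", noise = c(0.05, 1), seed = 8)
  expect_false(identical(a$pressure, c_$pressure))

  s1 <- simulate_mixture_preset("Chol-POPC", x2 = c(0, 0.5, 1),
                                noise = c(0.05, 1), seed = 11)
  s2 <- simulate_mixture_preset("Chol-POPC", x2 = c(0, 0.5, 1),
                                noise = c(0.05, 1), seed = 11)
  expect_identical(lapply(s1$members, `[[`, "pressure"),
                   lapply(s2$members, `[[`, "pressure"))
})

test_that("mixture members are exact ideal blends when excess is null", {
  ep <- std_endpoints()
  ser <- simulate_mixture_series(ep$e1, ep$e2, c(0, 0.4, 1))
  m <- monofilm:::series_member(ser, 0.4)
  grid <- m$pressure[m$pressure <= 45 & m$pressure > 0]
  blend <- 0.6 * area_of_pressure(ep$e1, grid, 20) +
    0.4 * area_of_pressure(ep$e2, grid, 20)
  got <- area_at_pressure(m, grid)$area
  expect_lt(max(abs(got - blend)), 1e-8)
})

test_that("pipeline recovers the analytic excess Gibbs energy", {
  ps <- mixture_preset("Chol-SM")
  ser <- simulate_mixture_preset("Chol-SM", x2 = seq(0, 1, 0.25))
  for (x in c(0.25, 0.5, 0.75)) {
    truth <- analytic_excess_gibbs(ps$excess, x, 30)
    expect_equal(excess_gibbs_energy(ser, x, 30), truth,
                 tolerance = abs(truth) * 0.005)
  }
})

test_that("analytic excess Gibbs: endpoints, algebra, quadrature oracle", {
  ex <- excess_model(alpha0 = -8)
  expect_equal(analytic_excess_gibbs(ex, c(0, 1), 30), c(0, 0))
  expect_equal(analytic_excess_gibbs(ex, 0.5, 30),
               6.02214076 * (-8) * 0.25 * 30)

  exd <- excess_model(alpha0 = -6, alpha1 = 2,
                      pressure_profile = "linear_decay", pi_ref = 80)
  for (x in c(0.3, 0.6)) {
    g <- seq(0, 30, by = 0.01)
    quad <- 6.02214076 * pracma::trapz(g, excess_area_model(exd, g, x))
    truth <- analytic_excess_gibbs(exd, x, 30)
    expect_equal(truth, quad, tolerance = abs(quad) * 0.001)
  }
})

test_that("interaction-strength calibration: Chol/POPC is twice 7KC/POPC", {
  s_chol <- simulate_mixture_preset("Chol-POPC", x2 = seq(0, 1, 0.1))
  s_kc <- simulate_mixture_preset("7KC-POPC", x2 = seq(0, 1, 0.1))
  m_chol <- gibbs_composition_scan(s_chol, 30)$min_value
  m_kc <- gibbs_composition_scan(s_kc, 30)$min_value
  expect_equal(m_chol / m_kc, 2, tolerance = 0.1)
})

test_that("replicate noise keeps limiting areas within the +/-2 A^2 envelope", {
  ps <- eos_preset("POPC")
  inside <- sapply(1:200, function(s) {
    iso <- simulate_pure_isotherm(ps$model, 20, 300, ps$area_range,
                                  noise = c(0.05, 1), seed = 5000 + s)
    abs(as.numeric(limiting_area(iso)) - 100) <= 2
  })
  # 95% of replicates expected inside; allow binomial fluctuation at n=200
  expect_gte(mean(inside), 0.93)
})

test_that("every preset passes the full descriptor pipeline", {
  for (nm in c("SM-brain", "SM-egg", "POPC", "Chol", "7KC")) {
    ps <- eos_preset(nm)
    d <- describe_isotherm(simulate_preset(nm))
    expect_equal(d$collapse_pressure, ps$expected$collapse,
                 tolerance = 0.3)
    expect_equal(d$cs_max, ps$expected$cs_max,
                 tolerance = 0.01 * ps$expected$cs_max)
    expect_identical(d$state, ps$expected$state)
    if (is.null(ps$expected$transition)) {
      expect_length(d$transitions, 0L)
    } else {
      expect_equal(d$transitions, ps$expected$transition,
                   tolerance = 0.3)
    }
  }
})
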