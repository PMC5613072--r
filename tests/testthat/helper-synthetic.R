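# shared synthetic fixtures, built in code at test time

kT20 <- kT_film(20)

# noise-free Volmer film: pi = kT/(A - omega) - pi_coh
volmer_iso <- function(omega = 38, pi_coh = 8, n = 500,
                       range = c(85, 45), collapse = NULL) {
  m <- eos_model("volmer", omega = omega, pi_coh = pi_coh,
                 collapse_pi = collapse)
  simulate_pure_isotherm(m, 20, n, range)
}

# exact linear isotherm pi = slope * (a0 - A), clipped at 0
linear_iso <- function(slope = 4, a0 = 42, n = 300, range = c(60, 30),
                       sigma_pi = 0, seed = NULL) {
  a <- seq(max(range), min(range), length.out = n)
  p <- pmax(0, slope * (a0 - a))
  if (sigma_pi > 0) {
    p <- monofilm:::with_seed(seed, p + stats::rnorm(n, 0, sigma_pi))
    p <- pmax(p, -0.45)
  }
  isotherm(a, p, 20, c(X = 1))
}

# three exactly-linear members with a prescribed excess area function,
# all sharing one pressure grid (interpolation is exact on lines)
linear_excess_series <- function(aexc_fun, pi_max = 50, n = 300) {
  g <- seq(0, pi_max, length.out = n)
  a1 <- 70 - 0.3 * g
  a2 <- 50 - 0.2 * g
  mk <- function(a, comp) isotherm(a, g, 20, comp)
  mixture_series(
    list(mk(a1, c(A = 1)),
         mk(0.5 * a1 + 0.5 * a2 + aexc_fun(g), c(A = 0.5, B = 0.5)),
         mk(a2, c(B = 1))),
    c(0, 0.5, 1), "A", "B")
}

std_endpoints <- function() {
  list(e1 = eos_model("volmer", omega = 38, pi_coh = 8, collapse_pi = 50),
       e2 = eos_model("linear_condensed", omega = 40.5, slope = 20.49,
                      collapse_pi = 46))
}
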