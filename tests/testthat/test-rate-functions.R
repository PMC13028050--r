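# Rate functions: printed constants, removable singularities, steady
# states, time constants and the steady-state derivative identity.

gates <- canonical_gates()

test_that("canonical rate values reproduce the printed constants", {
  expect_equal(rate_value(gates$n, "beta", 0), 0.0555)
  expect_equal(rate_value(gates$m, "beta", 0), 0.108)
  # frozen high-precision evaluations of the closed forms
  expect_equal(rate_value(gates$m, "alpha", -65), 0.2235637246, tolerance = 1e-9)
  expect_equal(rate_value(gates$h, "alpha", -65), 0.0027 * exp(65 / 20))
  expect_equal(rate_value(gates$n, "beta", -65), 0.0555 * exp(65 / 80))
})

test_that("removable singularities return the analytic limit", {
  # oracle: both one-sided evaluations converge to the same limit
  f <- function(E) 0.1 * (E + 40) / (1 - exp(-(E + 40) / 10))
  expect_lt(abs(f(-40 + 1e-6) - f(-40 - 1e-6)), 1e-6)
  expect_equal(rate_value(gates$m, "alpha", -40), 1.0)
  expect_equal(rate_value(gates$n, "alpha", -55), 0.1)
  # continuity just outside the singular window
  expect_equal(rate_value(gates$m, "alpha", -40 + 1e-6), 1.0, tolerance = 1e-6)
})

test_that("invalid voltages and malformed specs are rejected", {
  expect_error(rate_value(gates$m, "alpha", NaN), "finite")
  expect_error(rate_value(gates$m, "alpha", Inf), "finite")
  expect_error(rate_value(gates$n, "beta", -1e6), "overflow")
  expect_error(gate_spec("bad", "pure_exp", c(1, 0, 0), "pure_exp", c(1, 0, 1)),
               "nonzero")
  expect_error(gate_spec("bad", "nope", c(1, 0, 1), "pure_exp", c(1, 0, 1)))
})

test_that("all six canonical rates are strictly positive on [-120, 60] mV", {
  E <- seq(-120, 60, by = 0.5)
  for (g in gates) {
    expect_true(all(rate_value(g, "alpha", E) > 0), info = g$name)
    expect_true(all(rate_value(g, "beta", E) > 0), info = g$name)
  }
})

test_that("steady states and time constants behave as defined", {
  expect_equal(steady_state(flat_gate(2, 2), -30), 0.5)
  expect_equal(time_constant(flat_gate(1, 1), 0), 0.5)
  # frozen ratio oracle: alpha_n(-65)/(alpha_n + beta_n)
  expect_equal(steady_state(gates$n, -65), 0.3175535300, tolerance = 1e-9)
  expect_equal(time_constant(gates$m, -65), 0.2369479687, tolerance = 1e-9)
  E <- seq(-100, 40, by = 1)
  for (g in gates) {
    xi <- steady_state(g, E); tau <- time_constant(g, E)
    expect_true(all(xi >= 0 & xi <= 1))
    expect_true(all(tau > 0 & is.finite(tau)))
    # tau * (alpha + beta) = 1 identically
    expect_close(tau * (rate_value(g, "alpha", E) + rate_value(g, "beta", E)),
                 1, 1e-12)
  }
  # sodium activation approaches 1 monotonically with depolarisation
  minf <- steady_state(gates$m, seq(-20, 60, by = 5))
  expect_true(all(diff(minf) > 0))
  expect_gt(minf[length(minf)], 0.999)
  expect_error(steady_state(flat_gate(0, 0), 0), "degenerate")
})

test_that("log-ratio derivative matches closed forms and the steady-state identity", {
  # alpha = e^{E/25}, beta = e^{-E/50}: slope is exactly 1/25 + 1/50
  expect_equal(log_ratio_derivative(biexp_gate(25, 50), -10), 1 / 25 + 1 / 50,
               tolerance = 1e-9)
  # symbolic-derivative oracle for the sodium inactivation gate at -80 mV:
  # d/dE ln(alpha_h/beta_h) = -1/20 - (1/10)(1 - beta_h(E))
  bh <- rate_value(gates$h, "beta", -80)
  expect_equal(log_ratio_derivative(gates$h, -80), -1 / 20 - (1 - bh) / 10,
               tolerance = 1e-8)
  # d xi_inf/dE = xi_inf (1 - xi_inf) d/dE ln(alpha/beta) on the 141-point
  # grid -120..20 mV
  E <- seq(-120, 20, by = 1)
  h <- 1e-3
  for (g in gates) {
    lhs <- (steady_state(g, E + h) - steady_state(g, E - h)) / (2 * h)
    xi <- steady_state(g, E)
    rhs <- xi * (1 - xi) * log_ratio_derivative(g, E, h = h)
    expect_close(lhs, rhs, 1e-6)
  }
  expect_error(log_ratio_derivative(flat_gate(0, 1), 0), "positive")
})

test_that("pure-exponential rates have exactly linear log plots with the classical scales", {
  E <- seq(-100, 40, by = 1)
  cases <- list(list(gates$m, "beta", 18), list(gates$h, "alpha", 20),
                list(gates$n, "beta", 80))
  for (cs in cases) {
    y <- log(rate_value(cs[[1]], cs[[2]], E))
    fit <- stats::lm(y ~ E)
    r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
    expect_gt(r2, 1 - 1e-12)
    expect_equal(-1 / unname(stats::coef(fit)[2]), cs[[3]], tolerance = 1e-8)
  }
})

test_that("rate_table exposes the tabulated voltage dependence", {
  tab <- rate_table(gates$n, -80, 0, 10)
  expect_named(tab, c("E_mV", "alpha_ms1", "beta_ms1", "xinf", "tau_ms"))
  expect_equal(nrow(tab), 9L)
  expect_equal(tab$xinf, tab$alpha_ms1 / (tab$alpha_ms1 + tab$beta_ms1))
})
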