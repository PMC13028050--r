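# Lie machinery: brackets (symbolic vs numeric), the commutation table,
# structure constants, thermal voltage, Q10 scaling and the angle-gate map.

cs <- c("theta", "g", "t")
pt <- c(theta = 1, g = 2, t = 0.5)

test_that("brackets of the bare generators vanish", {
  gen <- bare_generators()
  expect_equal(unname(lie_bracket(gen$Xc, gen$Xg, point = pt,
                                  method = "numeric")), c(0, 0, 0))
  expect_equal(unname(lie_bracket(gen$Xc, gen$Xg, point = pt,
                                  method = "symbolic")), c(0, 0, 0))
  # [X, X] = 0 for any field
  Y <- vector_field(theta = g * t, g = exp(theta), t = 1, coords = cs)
  expect_close(lie_bracket(Y, Y, point = pt, method = "numeric"), 0, 1e-8)
})

test_that("a non-homogeneous scaling bracket is recovered: [d/dg, g d/dg] = d/dg", {
  X <- vector_field(g = 1, coords = cs)
  Y <- vector_field(g = g, coords = cs)
  expect_equal(unname(lie_bracket(X, Y, point = pt, method = "symbolic")),
               c(0, 1, 0))
  expect_close(lie_bracket(X, Y, point = pt, method = "numeric") - c(0, 1, 0),
               0, 1e-8)
})

test_that("numeric brackets agree with the symbolic oracle on random polynomial fields", {
  set.seed(11)
  for (i in 1:5) {
    X <- random_poly_field(); Y <- random_poly_field()
    p <- c(theta = stats::runif(1, -1, 1), g = stats::runif(1, 0.5, 2),
           t = stats::runif(1, -1, 1))
    num <- lie_bracket(X, Y, point = p, method = "numeric")
    sym <- lie_bracket(X, Y, point = p, method = "symbolic")
    expect_close(num - sym, 0, 1e-5)
    # antisymmetry of the numeric route
    expect_close(num + lie_bracket(Y, X, point = p, method = "numeric"),
                 0, 1e-8)
  }
})

test_that("the Jacobi identity holds on random polynomial fields", {
  set.seed(5)
  for (i in 1:4) {
    X <- random_poly_field(); Y <- random_poly_field(); Z <- random_poly_field()
    s <- lie_bracket(X, lie_bracket(Y, Z, method = "symbolic"), method = "symbolic")
    p1 <- lie_bracket(Y, lie_bracket(Z, X, method = "symbolic"), method = "symbolic")
    p2 <- lie_bracket(Z, lie_bracket(X, Y, method = "symbolic"), method = "symbolic")
    p <- c(theta = 0.3, g = 1.7, t = -0.4)
    resid <- eval_vector_field(s, p) + eval_vector_field(p1, p) +
      eval_vector_field(p2, p)
    expect_close(resid, 0, 1e-5)
  }
})

test_that("the commutation table distinguishes bare, coupled and broken realizations", {
  # bare fields with zero structure constants: all three relations pass
  tab0 <- verify_commutation_table(0, 0)
  expect_true(all(tab0$status == "pass"))
  expect_equal(tab0$residual, rep(0, 3))
  # bare fields cannot realise nonzero couplings: reported, not failed
  tabu <- verify_commutation_table(0.04, 0.04)
  expect_equal(tabu$status, c("pass", "unrealized", "unrealized"))
  # the coupled realization satisfies the full table
  tabc <- verify_commutation_table(0.04, 0.03,
                                   realization = coupled_realization(0.04, 0.03))
  expect_true(all(tabc$status == "pass"))
  expect_lt(max(tabc$residual), 1e-6)
  # a wrong structure constant fails against a genuine realization
  tabw <- verify_commutation_table(0.04, 0.1,
                                   realization = coupled_realization(0.04, 0.03))
  expect_equal(tabw$status[3], "fail")
})

test_that("structure constants aggregate the canonical e-fold scales", {
  rep <- estimate_structure_constants()
  expect_true(all(c(18, 80) %in% rep$per_gate_scales))
  expect_equal(unname(sort(rep$per_gate_scales)),
               c(10, 10, 10, 18, 20, 80))
  expect_equal(rep$E0_aggregate, mean(c(10, 18, 20, 10, 10, 80)))
  expect_equal(rep$gamma2, 1 / rep$E0_aggregate)
  expect_gt(rep$gamma2, 0.03); expect_lt(rep$gamma2, 0.05)
  expect_true(rep$gamma1_approximate)
  # synthetic gate alpha = e^{E/25}, beta constant: scale 25, gamma2 = 0.04,
  # the constant component excluded with a notice
  syn <- list(x = gate_spec("syn", "pure_exp", c(1, 0, -25),
                            "constant", c(0.5, 0, 1)))
  r2 <- estimate_structure_constants(syn)
  expect_equal(unname(r2$per_gate_scales), 25)
  expect_equal(r2$gamma2, 0.04)
  expect_match(r2$excluded, "no exponential component")
})

test_that("thermal voltage follows kB T / e", {
  expect_equal(thermal_voltage(310), 26.7, tolerance = 0.001)
  expect_equal(thermal_voltage(0), 0)
  expect_equal(thermal_voltage(293), 25.248786, tolerance = 1e-5)
  # linear in T
  T <- c(100, 200, 400)
  expect_equal(thermal_voltage(T) / T, rep(thermal_voltage(1), 3))
  expect_error(thermal_voltage(-1), "nonnegative")
})

test_that("Q10 scaling of gamma2 behaves multiplicatively", {
  expect_equal(q10_scale(0.04, 20, 20, 3), 0.04)
  expect_equal(q10_scale(0.04, 30, 20, 3), 0.12)
  expect_equal(q10_scale(0.04, 10, 20, 3), 0.04 / 3)
  expect_error(q10_scale(0.04, 20, 20, 0), "positive")
})

test_that("the angle-gate projection maps the circle onto [0,1]", {
  expect_equal(gate_from_angle(0), 1)
  expect_equal(gate_from_angle(pi), 0)
  expect_equal(gate_from_angle(pi / 2), 0.5)
  th <- seq(0, pi, length.out = 25)
  expect_close(angle_from_gate(gate_from_angle(th)) - th, 0, 1e-8)
  expect_true(all(gate_from_angle(seq(-10, 10, 0.1)) >= 0 &
                    gate_from_angle(seq(-10, 10, 0.1)) <= 1))
  expect_error(angle_from_gate(1.2), "boundedness")
})

test_that("sodium conductance sensitivity decomposes gate-wise", {
  s <- conductance_sensitivity(-65)
  expect_equal(s$total, s$activation + s$inactivation)
  expect_equal(s$total, s$total_check, tolerance = 1e-6)
  expect_gt(s$activation, 0)   # m_inf increases with E
  expect_lt(s$inactivation, 0) # h_inf decreases with E
  # voltage-independent gates have zero sensitivity
  flat <- list(m = flat_gate(0.3, 0.7), h = flat_gate(0.2, 0.8),
               n = flat_gate(1, 1))
  s0 <- conductance_sensitivity(-65, gates = flat)
  expect_equal(s0$total, 0)
  # near-saturated steady states are rejected
  expect_error(conductance_sensitivity(59.99,
    gates = list(m = flat_gate(1, 1e-15), h = flat_gate(1, 1),
                 n = flat_gate(1, 1))), "log-sensitivity undefined")
})
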