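# Shared fixtures: built in code, nothing stored on disk.

squid_params <- function() membrane_params()

# a gate with equal constant opening/closing rates (steady state 0.5)
flat_gate <- function(a = 1, b = 1) {
  gate_spec("flat", "constant", c(a, 0, 1), "constant", c(b, 0, 1))
}

# gate with alpha = e^{E/a}, beta = e^{-E/b}: pure exponentials with known
# log-ratio slope 1/a + 1/b
biexp_gate <- function(a = 25, b = 50) {
  gate_spec("biexp", "pure_exp", c(1, 0, -a), "pure_exp", c(1, 0, b))
}

# random polynomial vector field on (theta, g, t), degree <= 2, coeffs in
# [-1, 1]; deterministic given the RNG state at the call
random_poly_field <- function(coords = c("theta", "g", "t")) {
  comp <- lapply(coords, function(nm) {
    co <- round(stats::runif(6, -1, 1), 3)
    bquote(.(co[1]) + .(co[2]) * theta + .(co[3]) * g + .(co[4]) * t +
             .(co[5]) * theta * g + .(co[6]) * g * t)
  })
  names(comp) <- coords
  hhsym:::.vf(comp, coords)
}

expect_close <- function(x, y, tol) expect_lt(max(abs(x - y)), tol)
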