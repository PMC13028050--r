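# Gating rate functions: voltage-dependent opening (alpha) and closing (beta)
# transition rates of the three classical squid-axon gates, in absolute
# membrane potential (mV, resting ~ -65 mV). All rates are in ms^-1.

#' Construct a gating-variable specification
#'
#' A `gate_spec` bundles one gating variable's opening (`alpha`) and closing
#' (`beta`) rate-function parameterisations. Three functional families are
#' supported, each described by three constants `c(prefactor, offset, scale)`:
#'
#' * `"linoverexp"`: `a * (E + V0) / (1 - exp(-(E + V0)/s))` — the classical
#'   linear-over-exponential activation form; prefactor `a` in ms^-1 mV^-1,
#'   offset `V0` and e-fold scale `s` in mV. The removable singularity at
#'   `E = -V0` evaluates to the analytic limit `a * s`.
#' * `"pure_exp"`: `a * exp(-(E + V0)/s)` — a pure exponential; `a` in ms^-1.
#'   A negative `s` gives a rate growing with depolarisation.
#' * `"logistic"`: `a / (1 + exp(-(E + V0)/s))` — a saturating sigmoid.
#' * `"constant"`: the voltage-independent rate `a` (offset and scale are
#'   ignored; pass e.g. `c(a, 0, 1)`).
#'
#' @param name gate label, e.g. `"activation-Na"`.
#' @param alpha_form,beta_form one of `"linoverexp"`, `"pure_exp"`,
#'   `"logistic"`, `"constant"`.
#' @param alpha_constants,beta_constants numeric length-3 vectors
#'   `c(prefactor, offset, scale)`; the scale must be nonzero.
#' @return An object of class `gate_spec`.
#' @seealso [canonical_gates()] for the three classical specifications.
#' @export
gate_spec <- function(name, alpha_form, alpha_constants,
                      beta_form, beta_constants) {
  forms <- c("linoverexp", "pure_exp", "logistic", "constant")
  alpha_form <- match.arg(alpha_form, forms)
  beta_form <- match.arg(beta_form, forms)
  for (k in list(alpha_constants, beta_constants)) {
    if (!is.numeric(k) || length(k) != 3L || !all(is.finite(k)))
      stop("rate constants must be a finite numeric vector c(prefactor, offset, scale)")
    if (k[3L] == 0)
      stop("e-fold scale constant must be nonzero")
  }
  structure(
    list(name = as.character(name),
         alpha_form = alpha_form,
         alpha_constants = as.numeric(alpha_constants),
         beta_form = beta_form,
         beta_constants = as.numeric(beta_constants)),
    class = "gate_spec")
}

#' @export
print.gate_spec <- function(x, ...) {
  cat("<gate_spec>", x$name, "\n")
  cat("  alpha:", x$alpha_form, "(",
      paste(signif(x$alpha_constants, 6), collapse = ", "), ")\n")
  cat("  beta: ", x$beta_form, "(",
      paste(signif(x$beta_constants, 6), collapse = ", "), ")\n")
  invisible(x)
}

#' The three canonical squid-axon gate specifications
#'
#' Returns the activation and inactivation gates of the sodium conductance
#' (`m`, `h`) and the activation gate of the potassium conductance (`n`)
#' with their classical rate constants expressed in absolute membrane
#' potential (the -65 mV resting shift absorbed into the prefactors):
#' \deqn{\alpha_m = 0.1(E+40)/(1 - e^{-(E+40)/10}),\quad
#'       \beta_m = 0.108\,e^{-E/18}}
#' \deqn{\alpha_h = 0.0027\,e^{-E/20},\quad
#'       \beta_h = 1/(1 + e^{-(E+35)/10})}
#' \deqn{\alpha_n = 0.01(E+55)/(1 - e^{-(E+55)/10}),\quad
#'       \beta_n = 0.0555\,e^{-E/80}}
#'
#' @return A named list of three [gate_spec()] objects `m`, `h`, `n`.
#' @examples
#' g <- canonical_gates()
#' rate_value(g$n, "beta", 0)   # 0.0555 ms^-1
#' steady_state(g$n, -65)       # resting potassium activation
#' @export
canonical_gates <- function() {
  list(
    m = gate_spec("activation-Na",
                  "linoverexp", c(0.1, 40, 10),
                  "pure_exp", c(0.108, 0, 18)),
    h = gate_spec("inactivation-Na",
                  "pure_exp", c(0.0027, 0, 20),
                  "logistic", c(1, 35, 10)),
    n = gate_spec("activation-K",
                  "linoverexp", c(0.01, 55, 10),
                  "pure_exp", c(0.0555, 0, 80))
  )
}

# Largest |argument| passed to exp(); beyond this the rate is rejected
# rather than silently saturating to Inf or 0.
.EXP_GUARD <- 700

# Width of the window around a removable singularity inside which the
# analytic series limit is returned (mV).
.SINGULARITY_TOL <- 1e-7

.eval_rate_form <- function(form, k, E) {
  a <- k[1L]; V0 <- k[2L]; s <- k[3L]
  x <- E + V0
  arg <- x / s
  if (any(abs(arg) > .EXP_GUARD))
    stop("exponential overflow guard: |(E + ", V0, ")/", s, "| exceeds ",
         .EXP_GUARD, " at E = ", E[which.max(abs(arg))], " mV")
  switch(form,
    linoverexp = {
      # a*x/(1 - exp(-x/s)); expm1 keeps the ratio accurate near x = 0 and
      # the series limit a*s is substituted inside the singular window.
      out <- ifelse(abs(x) < .SINGULARITY_TOL, a * s, a * x / (-expm1(-arg)))
      out
    },
    pure_exp = a * exp(-arg),
    logistic = a / (1 + exp(-arg)),
    constant = a + 0 * E)
}

#' Evaluate a gating rate function
#'
#' @param gate a [gate_spec()].
#' @param which `"alpha"` (opening) or `"beta"` (closing).
#' @param E membrane potential in mV (vectorised).
#' @return Rate(s) in ms^-1; always finite and nonnegative for the canonical
#'   gates on the physiological range. Removable singularities of the
#'   linear-over-exponential form return the analytic limit.
#' @export
rate_value <- function(gate, which = c("alpha", "beta"), E) {
  stopifnot(inherits(gate, "gate_spec"))
  which <- match.arg(which)
  if (!is.numeric(E) || !all(is.finite(E)))
    stop("membrane potential E must be finite numeric (mV)")
  if (which == "alpha")
    .eval_rate_form(gate$alpha_form, gate$alpha_constants, E)
  else
    .eval_rate_form(gate$beta_form, gate$beta_constants, E)
}

#' Steady-state gate value
#'
#' The equilibrium of the first-order gate kinetics at fixed voltage,
#' `alpha / (alpha + beta)`, a dimensionless value in \[0, 1\].
#'
#' @inheritParams rate_value
#' @export
steady_state <- function(gate, E) {
  a <- rate_value(gate, "alpha", E)
  b <- rate_value(gate, "beta", E)
  s <- a + b
  if (any(s <= 0))
    stop("degenerate input: alpha + beta must be positive")
  a / s
}

#' Gate relaxation time constant
#'
#' `1 / (alpha + beta)` in ms: the exponential relaxation time of the gate
#' toward its steady state at fixed voltage.
#'
#' @inheritParams rate_value
#' @export
time_constant <- function(gate, E) {
  a <- rate_value(gate, "alpha", E)
  b <- rate_value(gate, "beta", E)
  s <- a + b
  if (any(s <= 0))
    stop("degenerate input: alpha + beta must be positive")
  1 / s
}

#' Voltage log-slope of the opening/closing rate ratio
#'
#' Central-difference estimate of `d/dE ln(alpha/beta)` in mV^-1. For gates
#' whose alpha and beta are both pure exponentials the result is
#' voltage-independent and equals the sum of the reciprocal e-fold scales;
#' for composite forms it is a local slope. Via the identity
#' `d xi_inf/dE = xi_inf (1 - xi_inf) d/dE ln(alpha/beta)` this slope is the
#' local voltage sensitivity of the steady-state activation curve.
#'
#' @inheritParams rate_value
#' @param h central-difference step in mV.
#' @export
log_ratio_derivative <- function(gate, E, h = 1e-3) {
  stopifnot(h > 0)
  lr <- function(v) {
    a <- rate_value(gate, "alpha", v)
    b <- rate_value(gate, "beta", v)
    if (any(a <= 0) || any(b <= 0))
      stop("alpha and beta must be positive on the difference stencil")
    log(a / b)
  }
  (lr(E + h) - lr(E - h)) / (2 * h)
}

#' Tabulate a gate's voltage dependence
#'
#' Evaluates alpha, beta, the steady state and the time constant on a
#' voltage grid; the table the `rates` command-line subcommand writes.
#'
#' @inheritParams rate_value
#' @param from,to,step voltage grid, mV.
#' @return A `data.frame` with columns `E_mV, alpha_ms1, beta_ms1, xinf,
#'   tau_ms`.
#' @export
rate_table <- function(gate, from = -100, to = 40, step = 1) {
  E <- seq(from, to, by = step)
  a <- rate_value(gate, "alpha", E)
  b <- rate_value(gate, "beta", E)
  data.frame(E_mV = E, alpha_ms1 = a, beta_ms1 = b,
             xinf = a / (a + b), tau_ms = 1 / (a + b))
}
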