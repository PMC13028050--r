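# Full Hodgkin-Huxley membrane dynamics: four coupled ODEs for
# (E, m, h, n) under current clamp, or the three gate ODEs at prescribed
# voltage under voltage clamp. Fixed-step classical RK4 throughout so that
# runs are deterministic and bitwise reproducible.

#' Membrane parameters
#'
#' Maximal conductances (mS/cm^2), reversal potentials (mV), specific
#' capacitance (uF/cm^2) and temperature (degrees C) of the membrane patch.
#' Defaults are the classical squid-axon values in the absolute-voltage
#' convention.
#'
#' @param gNa_max,gK_max,gL_max maximal sodium, potassium and leak
#'   conductances, mS/cm^2; must be nonnegative.
#' @param ENa,EK,EL reversal potentials, mV.
#' @param CM membrane capacitance, uF/cm^2; must be positive.
#' @param temperature bath temperature, degrees C (the original squid
#'   recordings were at 6.3 C).
#' @return An object of class `membrane_params`.
#' @export
membrane_params <- function(gNa_max = 120, gK_max = 36, gL_max = 0.3,
                            ENa = 50, EK = -77, EL = -54.387,
                            CM = 1, temperature = 6.3) {
  vals <- list(gNa_max = gNa_max, gK_max = gK_max, gL_max = gL_max,
               ENa = ENa, EK = EK, EL = EL, CM = CM,
               temperature = temperature)
  for (nm in names(vals))
    if (!is.numeric(vals[[nm]]) || length(vals[[nm]]) != 1L || !is.finite(vals[[nm]]))
      stop("membrane parameter '", nm, "' must be a finite scalar")
  if (gNa_max < 0 || gK_max < 0 || gL_max < 0)
    stop("maximal conductances must be nonnegative")
  if (CM <= 0) stop("membrane capacitance CM must be positive")
  structure(lapply(vals, as.numeric), class = "membrane_params")
}

#' @export
print.membrane_params <- function(x, ...) {
  cat("<membrane_params> gNa =", x$gNa_max, "gK =", x$gK_max,
      "gL =", x$gL_max, "mS/cm2; ENa =", x$ENa, "EK =", x$EK,
      "EL =", x$EL, "mV; CM =", x$CM, "uF/cm2;", x$temperature, "C\n")
  invisible(x)
}

#' Stimulation protocols
#'
#' A protocol is a sequence of constant-level segments. Under current clamp
#' the level is the injected current density (uA/cm^2) and the membrane
#' potential is integrated; under voltage clamp the level is the command
#' potential (mV) and only the gates evolve.
#'
#' @param durations segment durations, ms (all positive).
#' @param levels one level per segment (uA/cm^2 or mV).
#' @return An object of class `hh_protocol`.
#' @export
current_clamp <- function(durations, levels) {
  .protocol("current_clamp", durations, levels)
}

#' @rdname current_clamp
#' @export
voltage_clamp <- function(durations, levels) {
  .protocol("voltage_clamp", durations, levels)
}

.protocol <- function(kind, durations, levels) {
  if (length(durations) != length(levels) || length(durations) == 0L)
    stop("durations and levels must be equal-length, nonempty vectors")
  if (!all(is.finite(durations)) || any(durations <= 0))
    stop("segment durations must be positive and finite")
  if (!all(is.finite(levels)))
    stop("segment levels must be finite")
  structure(list(kind = kind,
                 segments = data.frame(duration = as.numeric(durations),
                                       level = as.numeric(levels))),
            class = "hh_protocol")
}

#' First-order gate kinetics right-hand side
#'
#' `d xi/dt = alpha (1 - xi) - beta xi`: opening of the closed fraction
#' minus closing of the open fraction.
#'
#' @param xi gate value (dimensionless).
#' @param alpha,beta opening and closing rates, ms^-1.
#' @return Time derivative in ms^-1.
#' @export
gating_derivative <- function(xi, alpha, beta) {
  alpha * (1 - xi) - beta * xi
}

#' Total ionic membrane current
#'
#' Sum of the three Ohmic terms with the classical gating factors:
#' `I = gNa_max m^3 h (E - ENa) + gK_max n^4 (E - EK) + gL_max (E - EL)`,
#' in uA/cm^2.
#'
#' @param state named list or vector with elements `E`, `m`, `h`, `n`.
#' @param params a [membrane_params()].
#' @param tol tolerance on the gate range check.
#' @export
ionic_current <- function(state, params, tol = 1e-9) {
  st <- as.list(state)
  E <- st$E; m <- st$m; h <- st$h; n <- st$n
  gates <- c(m, h, n)
  if (any(gates < -tol | gates > 1 + tol))
    stop("gating variables must lie in [0, 1] (tolerance ", tol, ")")
  params$gNa_max * m^3 * h * (E - params$ENa) +
    params$gK_max * n^4 * (E - params$EK) +
    params$gL_max * (E - params$EL)
}

# One classical RK4 step of dy/dt = f(y); f must not depend on t (within a
# protocol segment the drive is constant, so the RHS is autonomous).
.rk4_step <- function(y, f, dt) {
  k1 <- f(y)
  k2 <- f(y + dt / 2 * k1)
  k3 <- f(y + dt / 2 * k2)
  k4 <- f(y + dt * k3)
  y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Simulate the Hodgkin-Huxley membrane
#'
#' Integrates the full four-variable system (current clamp) or the three
#' gate equations at prescribed command voltage (voltage clamp) with a
#' classical fixed-step 4th-order Runge-Kutta scheme.
#'
#' @param params a [membrane_params()].
#' @param protocol a [current_clamp()] or [voltage_clamp()] protocol.
#' @param dt time step, ms. The default stability contract requires
#'   `dt <= 0.05`; larger steps are accepted with a recorded warning.
#' @param t_end optional total duration, ms; when longer than the protocol,
#'   the final segment is extended, when shorter the protocol is truncated.
#' @param init optional named list `list(E=, m=, h=, n=)` overriding the
#'   default initial state. By default gates start at their steady state at
#'   the holding voltage (first command level under voltage clamp, `E_rest`
#'   under current clamp) so that protocols carry no hidden state.
#' @param E_rest resting potential used for the default current-clamp
#'   initial state, mV.
#' @param gates gate specifications, by default [canonical_gates()].
#' @param t0 time origin of the returned grid, ms (the dynamics are
#'   autonomous; `t0` only relabels the axis but the integration arithmetic
#'   is identical for any origin).
#' @return A `data.frame` of class `hh_trajectory` with columns
#'   `t` (ms), `E` (mV), `m`, `h`, `n` (dimensionless), and the derived
#'   instantaneous conductances `gNa = gNa_max m^3 h`, `gK = gK_max n^4`
#'   (mS/cm^2). Attributes record `params`, `protocol`, `dt` and any
#'   stability warning.
#' @examples
#' p <- membrane_params()
#' traj <- simulate_membrane(p, current_clamp(50, 10), dt = 0.01)
#' max(traj$E)   # spike overshoot, mV
#' @export
simulate_membrane <- function(params, protocol, dt = 0.01, t_end = NULL,
                              init = NULL, E_rest = -65,
                              gates = canonical_gates(), t0 = 0) {
  stopifnot(inherits(params, "membrane_params"),
            inherits(protocol, "hh_protocol"))
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive")
  warn <- NULL
  if (dt > 0.05) {
    warn <- paste0("dt = ", dt, " ms exceeds the 0.05 ms stability contract")
    warning(warn)
  }
  segs <- protocol$segments
  if (!is.null(t_end)) {
    if (t_end <= 0) stop("t_end must be positive")
    total <- sum(segs$duration)
    if (t_end > total) {
      segs$duration[nrow(segs)] <- segs$duration[nrow(segs)] + (t_end - total)
    } else {
      keep <- cumsum(segs$duration) - segs$duration < t_end
      segs <- segs[keep, , drop = FALSE]
      segs$duration[nrow(segs)] <-
        t_end - (cumsum(segs$duration)[nrow(segs)] - segs$duration[nrow(segs)])
    }
  }

  vclamp <- protocol$kind == "voltage_clamp"
  E_hold <- if (vclamp) segs$level[1L] else E_rest
  if (is.null(init)) {
    init <- list(E = E_hold,
                 m = steady_state(gates$m, E_hold),
                 h = steady_state(gates$h, E_hold),
                 n = steady_state(gates$n, E_hold))
  }
  y <- c(E = init$E, m = init$m, h = init$h, n = init$n)
  if (any(!is.finite(y))) stop("initial state must be finite")

  n_steps_seg <- round(segs$duration / dt)
  if (any(abs(n_steps_seg * dt - segs$duration) > 1e-9))
    warning("segment durations rounded to a whole number of steps")
  n_steps_seg <- pmax(n_steps_seg, 1L)
  n_total <- sum(n_steps_seg)

  out <- matrix(NA_real_, nrow = n_total + 1L, ncol = 4L,
                dimnames = list(NULL, c("E", "m", "h", "n")))
  out[1L, ] <- y
  row <- 1L

  for (s in seq_len(nrow(segs))) {
    lev <- segs$level[s]
    if (vclamp) {
      y[["E"]] <- lev
      out[row, "E"] <- lev  # command voltage applies from segment onset
      f <- function(yy) {
        E <- lev
        c(E = 0,
          m = gating_derivative(yy[["m"]], rate_value(gates$m, "alpha", E),
                                rate_value(gates$m, "beta", E)),
          h = gating_derivative(yy[["h"]], rate_value(gates$h, "alpha", E),
                                rate_value(gates$h, "beta", E)),
          n = gating_derivative(yy[["n"]], rate_value(gates$n, "alpha", E),
                                rate_value(gates$n, "beta", E)))
      }
    } else {
      f <- function(yy) {
        E <- yy[["E"]]
        I_ion <- params$gNa_max * yy[["m"]]^3 * yy[["h"]] * (E - params$ENa) +
          params$gK_max * yy[["n"]]^4 * (E - params$EK) +
          params$gL_max * (E - params$EL)
        c(E = (lev - I_ion) / params$CM,
          m = gating_derivative(yy[["m"]], rate_value(gates$m, "alpha", E),
                                rate_value(gates$m, "beta", E)),
          h = gating_derivative(yy[["h"]], rate_value(gates$h, "alpha", E),
                                rate_value(gates$h, "beta", E)),
          n = gating_derivative(yy[["n"]], rate_value(gates$n, "alpha", E),
                                rate_value(gates$n, "beta", E)))
      }
    }
    for (k in seq_len(n_steps_seg[s])) {
      y <- .rk4_step(y, f, dt)
      if (any(!is.finite(y)))
        stop("non-finite state at step ", row,
             " (t = ", signif(t0 + row * dt, 6), " ms); integration aborted")
      row <- row + 1L
      out[row, ] <- y
    }
  }

  t <- t0 + (seq_len(n_total + 1L) - 1L) * dt
  traj <- data.frame(t = t, E = out[, "E"], m = out[, "m"],
                     h = out[, "h"], n = out[, "n"])
  traj$gNa <- params$gNa_max * traj$m^3 * traj$h
  traj$gK <- params$gK_max * traj$n^4
  attr(traj, "params") <- params
  attr(traj, "protocol") <- protocol
  attr(traj, "dt") <- dt
  attr(traj, "stability_warning") <- warn
  class(traj) <- c("hh_trajectory", "data.frame")
  traj
}

#' Closed-form gate relaxation under voltage clamp
#'
#' At fixed voltage the gate ODE is linear, with the explicit solution
#' `xi(t) = xi_inf + (xi0 - xi_inf) exp(-t / tau)`. Used as the analytic
#' oracle for the integrator and as the generator of synthetic clamp data.
#'
#' @param gate a [gate_spec()].
#' @param E clamp voltage, mV.
#' @param t time since the step, ms (vectorised).
#' @param xi0 initial gate value.
#' @export
gate_relaxation <- function(gate, E, t, xi0) {
  xinf <- steady_state(gate, E)
  tau <- time_constant(gate, E)
  xinf + (xi0 - xinf) * exp(-t / tau)
}
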