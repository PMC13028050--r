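# Synthetic voltage-clamp conductance traces. The fixtures emulate the
# classical step-clamp experiments: hold at rest, step to a command
# voltage, record the macroscopic conductance g(t) = gmax * act^p * inact^q.
# Gates are evolved by the closed-form exponential relaxation (not the ODE
# integrator) so the traces are oracle-exact and any fitting error is
# attributable to the fitter.

#' Synthesize a voltage-clamp conductance dataset
#'
#' Generates one conductance trace per step voltage. For channel `"Na"` the
#' activation gate is `m` and the inactivation gate is `h`
#' (`g = gNa_max m^p h^q`); for channel `"K"` the activation gate is `n`
#' and `q > 0` describes a hypothetical inactivating potassium channel
#' (allowed, recorded in the metadata). Non-integer exponents are accepted
#' to emulate symmetry-broken channels for the fractional-exponent
#' diagnostic.
#'
#' @param params a [membrane_params()]; supplies the maximal conductance.
#' @param channel `"Na"` or `"K"`.
#' @param steps command voltages, mV; must lie in \[-120, 60\].
#' @param hold holding voltage, mV; gates start at steady state here.
#' @param duration trace duration after the step, ms.
#' @param dt sampling interval, ms.
#' @param exponents numeric `c(p, q)`: activation exponent `p >= 1` and
#'   inactivation exponent `q >= 0` (use `q = 0` for a non-inactivating
#'   channel).
#' @param noise_sd standard deviation of additive i.i.d. Gaussian noise on
#'   the conductance, mS/cm^2; `0` gives exactly reproducible noiseless
#'   traces.
#' @param seed integer seed recorded in the dataset; the generator is
#'   deterministic given the seed and leaves the global RNG state
#'   untouched.
#' @param gates gate specifications, by default [canonical_gates()].
#' @return An object of class `hh_clamp`: a list with `traces` (a
#'   `data.frame` with columns `trace_id, channel, hold_mV, step_mV, t_ms,
#'   g_mS_cm2`), and metadata `channel`, `noise_sd`, `seed`,
#'   `true_exponents`, `dt`, `g_max`.
#' @examples
#' ds <- synthesize_clamp(membrane_params(), "K",
#'                        steps = c(-40, -20, 0, 20), hold = -65,
#'                        duration = 20, dt = 0.05,
#'                        exponents = c(4, 0), noise_sd = 0, seed = 1)
#' nrow(ds$traces)
#' @export
synthesize_clamp <- function(params, channel = c("Na", "K"), steps,
                             hold = -65, duration = 20, dt = 0.05,
                             exponents, noise_sd = 0, seed = 0L,
                             gates = canonical_gates()) {
  stopifnot(inherits(params, "membrane_params"))
  channel <- match.arg(channel)
  if (any(steps < -120 | steps > 60))
    stop("step voltages must lie in [-120, 60] mV")
  if (length(exponents) != 2L || any(!is.finite(exponents)))
    stop("exponents must be numeric c(p, q)")
  p <- exponents[1L]; q <- exponents[2L]
  if (p < 1 || q < 0) stop("require activation exponent p >= 1 and q >= 0")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (duration <= 0 || dt <= 0) stop("duration and dt must be positive")

  act <- if (channel == "Na") gates$m else gates$n
  inact <- if (channel == "Na") gates$h else gates$n
  hypothetical <- channel == "K" && q > 0
  g_max <- if (channel == "Na") params$gNa_max else params$gK_max

  # duration should span the slowest relaxation among the commanded steps
  taus <- vapply(steps, function(E) {
    max(time_constant(act, E), if (q > 0) time_constant(inact, E) else 0)
  }, numeric(1))
  if (duration < 5 * max(taus))
    warning("duration covers fewer than 5 relaxation time constants; ",
            "slow gates will not reach steady state")

  t <- seq(0, duration, by = dt)
  act0 <- steady_state(act, hold)
  inact0 <- steady_state(inact, hold)

  rng_state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(rng_state)) assign(".Random.seed", rng_state, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))

  traces <- do.call(rbind, lapply(seq_along(steps), function(i) {
    E <- steps[i]
    g <- g_max * gate_relaxation(act, E, t, act0)^p
    if (q > 0) g <- g * gate_relaxation(inact, E, t, inact0)^q
    if (noise_sd > 0) g <- g + stats::rnorm(length(t), 0, noise_sd)
    data.frame(trace_id = sprintf("%s_step_%+04.0f", channel, E),
               channel = channel, hold_mV = hold, step_mV = E,
               t_ms = t, g_mS_cm2 = g)
  }))

  structure(list(traces = traces, channel = channel, noise_sd = noise_sd,
                 seed = as.integer(seed), true_exponents = c(p = p, q = q),
                 dt = dt, hold = hold, g_max = g_max,
                 hypothetical_inactivation = hypothetical),
            class = "hh_clamp")
}

#' @export
print.hh_clamp <- function(x, ...) {
  cat("<hh_clamp>", x$channel, "channel,",
      length(unique(x$traces$step_mV)), "steps,",
      "hold", x$hold, "mV, noise_sd", x$noise_sd,
      "mS/cm2, seed", x$seed, "\n")
  cat("  true exponents: p =", x$true_exponents[["p"]],
      "q =", x$true_exponents[["q"]], "\n")
  invisible(x)
}

#' Write / read a clamp dataset as CSV plus JSON metadata
#'
#' The trace table goes to `<path>.csv` (columns `trace_id, channel,
#' hold_mV, step_mV, t_ms, g_mS_cm2`) and the provenance (seed, noise,
#' exponents, maximal conductance) to `<path>.json`.
#'
#' @param dataset an `hh_clamp`.
#' @param path file stem (without extension).
#' @return `write_clamp_csv` returns the paths invisibly;
#'   `read_clamp_csv` returns the reconstructed `hh_clamp`.
#' @export
write_clamp_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "hh_clamp"))
  csv <- paste0(path, ".csv"); meta <- paste0(path, ".json")
  utils::write.csv(dataset$traces, csv, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(channel = dataset$channel, noise_sd = dataset$noise_sd,
         seed = dataset$seed,
         true_exponents = as.list(dataset$true_exponents),
         dt = dataset$dt, hold = dataset$hold, g_max = dataset$g_max,
         package_version = as.character(utils::packageVersion("hhsym"))),
    meta, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, metadata = meta))
}

#' @rdname write_clamp_csv
#' @export
read_clamp_csv <- function(path) {
  csv <- paste0(path, ".csv"); meta <- paste0(path, ".json")
  traces <- utils::read.csv(csv, stringsAsFactors = FALSE)
  need <- c("trace_id", "channel", "hold_mV", "step_mV", "t_ms", "g_mS_cm2")
  if (!all(need %in% names(traces)))
    stop("clamp CSV must have columns: ", paste(need, collapse = ", "))
  md <- if (file.exists(meta)) jsonlite::read_json(meta, simplifyVector = TRUE)
        else list()
  structure(list(traces = traces,
                 channel = traces$channel[1L],
                 noise_sd = md$noise_sd %||% NA_real_,
                 seed = md$seed %||% NA_integer_,
                 true_exponents = if (!is.null(md$true_exponents))
                   unlist(md$true_exponents) else NULL,
                 dt = md$dt %||% diff(traces$t_ms[1:2]),
                 hold = md$hold %||% traces$hold_mV[1L],
                 g_max = md$g_max %||% NA_real_),
            class = "hh_clamp")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
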