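# Configuration and serialization shared by all modules. Units are fixed
# package-wide (mV, ms, mS/cm^2, uA/cm^2, uF/cm^2); there is no unit
# conversion layer.

.CONFIG_KEYS <- c("params", "protocol", "dt", "seed", "tolerances",
                  "package_version")
.PARAM_KEYS <- c("gNa_max", "gK_max", "gL_max", "ENa", "EK", "EL",
                 "CM", "temperature")
.TOL_KEYS <- c("bounds", "timeshift")

#' Load and validate a run configuration
#'
#' Reads a YAML (`.yml`/`.yaml`) or JSON configuration with the keys
#' `params` (any subset of the [membrane_params()] fields), `protocol`
#' (`kind`, `durations`, `levels`), `dt`, `seed` and `tolerances`
#' (`bounds`, `timeshift`). Missing fields are filled with the documented
#' defaults and every defaulted field is recorded in the returned object's
#' `defaulted` attribute; unknown keys are rejected with the offending
#' field named.
#'
#' @param path path to the configuration file; an empty file yields the
#'   all-defaults configuration.
#' @return An object of class `hh_config`: list with `params`
#'   (a `membrane_params`), `protocol` (an `hh_protocol` or `NULL`), `dt`,
#'   `seed`, `tolerances`; attribute `defaulted` lists the filled fields.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("configuration must be a mapping/object")

  unknown <- setdiff(names(raw), .CONFIG_KEYS)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))

  defaulted <- character()

  p_raw <- raw$params
  if (is.null(p_raw)) p_raw <- list()
  bad <- setdiff(names(p_raw), .PARAM_KEYS)
  if (length(bad))
    stop("unknown params field(s): ", paste(bad, collapse = ", "))
  defaulted <- c(defaulted,
                 paste0("params.", setdiff(.PARAM_KEYS, names(p_raw))))
  params <- do.call(membrane_params, p_raw)

  protocol <- NULL
  if (!is.null(raw$protocol)) {
    pr <- raw$protocol
    bad <- setdiff(names(pr), c("kind", "durations", "levels"))
    if (length(bad))
      stop("unknown protocol field(s): ", paste(bad, collapse = ", "))
    if (is.null(pr$kind) || !pr$kind %in% c("current_clamp", "voltage_clamp"))
      stop("protocol.kind must be 'current_clamp' or 'voltage_clamp'")
    protocol <- .protocol(pr$kind, unlist(pr$durations), unlist(pr$levels))
  } else defaulted <- c(defaulted, "protocol")

  dt <- raw$dt
  if (is.null(dt)) { dt <- 0.01; defaulted <- c(defaulted, "dt") }
  if (!is.numeric(dt) || dt <= 0) stop("dt must be a positive number (ms)")

  seed <- raw$seed
  if (is.null(seed)) { seed <- 0L; defaulted <- c(defaulted, "seed") }
  seed <- as.integer(seed)

  tol_raw <- raw$tolerances
  if (is.null(tol_raw)) tol_raw <- list()
  bad <- setdiff(names(tol_raw), .TOL_KEYS)
  if (length(bad))
    stop("unknown tolerances field(s): ", paste(bad, collapse = ", "))
  defaulted <- c(defaulted,
                 paste0("tolerances.", setdiff(.TOL_KEYS, names(tol_raw))))
  tolerances <- list(bounds = tol_raw$bounds %||% 1e-9,
                     timeshift = tol_raw$timeshift %||% 1e-10)

  structure(list(params = params, protocol = protocol, dt = dt,
                 seed = seed, tolerances = tolerances),
            class = "hh_config", defaulted = defaulted)
}

#' Serialize a result object to JSON or CSV
#'
#' JSON output has deterministic field ordering (insertion order of the
#' object) and a `package_version` stamp; writing the same object twice
#' yields identical bytes. CSV is available for tabular objects
#' (trajectories and clamp trace tables).
#'
#' @param obj an `hh_audit`, `exponent_fit`, `structure_constant_report`,
#'   `hh_config`, `hh_trajectory`, `hh_clamp`, or plain list/data.frame.
#' @param path output path.
#' @param format `"json"` or `"csv"`.
#' @return The path, invisibly.
#' @export
write_report <- function(obj, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    tab <- if (inherits(obj, "hh_clamp")) obj$traces
      else if (is.data.frame(obj)) as.data.frame(obj)
      else stop("CSV output requires a tabular object")
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  payload <- .to_plain(obj)
  payload$package_version <- as.character(utils::packageVersion("hhsym"))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

.to_plain <- function(obj) {
  if (inherits(obj, "hh_config")) {
    pr <- obj$protocol
    list(params = unclass(obj$params),
         protocol = if (is.null(pr)) NULL else
           list(kind = pr$kind, durations = pr$segments$duration,
                levels = pr$segments$level),
         dt = obj$dt, seed = obj$seed, tolerances = obj$tolerances)
  } else if (inherits(obj, "hh_clamp")) {
    out <- unclass(obj); out$traces <- NULL
    out$true_exponents <- as.list(out$true_exponents)
    out
  } else if (inherits(obj, "exponent_fit")) {
    out <- unclass(obj)
    out$sse_by_candidate <- as.list(out$sse_by_candidate)
    out
  } else if (inherits(obj, "structure_constant_report")) {
    out <- unclass(obj)
    out$per_gate_scales <- as.list(out$per_gate_scales)
    out
  } else if (is.data.frame(obj)) {
    as.list(as.data.frame(obj))
  } else if (is.list(obj)) {
    unclass(obj)
  } else stop("cannot serialize object of class ", paste(class(obj), collapse = "/"))
}
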