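#' Read and write membrane-potential traces as CSV
#'
#' Canonical trace schema: columns `t_ms`, `v_mV` and optionally `m`, `h`,
#' `n`. Values round-trip at full double precision.
#'
#' @param trace an `hh_trace`.
#' @param path file path.
#' @return `read_trace_csv` returns an `hh_trace` (without model metadata).
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(format(as.data.frame(trace), digits = 15, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  d <- utils::read.csv(path)
  if (nrow(d) == 0) stop("empty trace file: ", path)
  if (!all(c("t_ms", "v_mV") %in% names(d)))
    stop("trace schema error: file must have columns t_ms, v_mV")
  out <- list(t = d$t_ms, v = d$v_mV, dt = d$t_ms[2] - d$t_ms[1])
  for (g in c("m", "h", "n")) if (g %in% names(d)) out[[g]] <- d[[g]]
  structure(out, class = "hh_trace")
}

#' Read and write clamp trace sets in long format
#'
#' Long-format schema: columns `step_mV`, `t_ms`, `i`. Step order is
#' restored from the protocol's sorted levels on read.
#'
#' @param traces a `current_trace_set`.
#' @param path file path.
#' @return `read_clamp_csv` returns a list with `t`, `i` (matrix),
#'   `step_levels`, `dt`.
#' @export
write_clamp_csv <- function(traces, path) {
  long <- data.frame(
    step_mV = rep(traces$step_levels, each = length(traces$t)),
    t_ms = rep(traces$t, times = length(traces$step_levels)),
    i = as.vector(traces$i))
  utils::write.csv(format(long, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_clamp_csv
#' @export
read_clamp_csv <- function(path) {
  d <- utils::read.csv(path)
  if (nrow(d) == 0) stop("empty clamp file: ", path)
  if (!all(c("step_mV", "t_ms", "i") %in% names(d)))
    stop("clamp schema error: file must have columns step_mV, t_ms, i")
  levels <- sort(unique(d$step_mV))
  t <- sort(unique(d$t_ms))
  i <- vapply(levels, function(s) d$i[d$step_mV == s][order(d$t_ms[d$step_mV == s])],
              numeric(length(t)))
  list(t = t, i = i, step_levels = levels, dt = t[2] - t[1])
}

#' Read and write spike-time tables
#'
#' Schema: columns `unit_id`, `epoch` (`"pre"` or `"post"`), `t_ms`.
#'
#' @param spikes data frame in the spike schema.
#' @param path file path.
#' @return `read_spikes_csv` returns the validated data frame.
#' @export
write_spikes_csv <- function(spikes, path) {
  stopifnot(all(c("unit_id", "epoch", "t_ms") %in% names(spikes)))
  utils::write.csv(spikes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spikes_csv
#' @export
read_spikes_csv <- function(path) {
  d <- utils::read.csv(path)
  if (nrow(d) == 0) stop("empty spikes file: ", path)
  if (!all(c("unit_id", "epoch", "t_ms") %in% names(d)))
    stop("spikes schema error: file must have columns unit_id, epoch, t_ms")
  d
}

# Default run configuration: every recognised key with its default value.
.default_config <- function() {
  list(
    model = list(rate_set = "traub", C = 0.75, gNa_max = NULL,
                 gK_max = NULL, gL = NULL, vNa = NULL, vK = NULL, vL = NULL,
                 k_gate_exponent = 4, leak_gated = FALSE),
    modulation = list(beta_K = 0, beta_Na = 0, intensity = 0),
    protocol = list(segments = data.frame(start = 0, duration = 500,
                                          amplitude = 0)),
    T = 500, dt = 0.01, seed = 1)
}

#' Load and validate a run configuration
#'
#' Reads a YAML (`.yml`/`.yaml`) or JSON configuration, rejects unknown keys
#' (naming the offending field), fills defaults for missing ones and
#' validates the resulting parameter objects. Units throughout: mV, ms,
#' mS/cm², µA/cm², µF/cm².
#'
#' @param path configuration file path.
#' @return An object of class `run_config`: list with `model` (an
#'   [hh_params()]), `mod` (a [conductance_modulation()]), `protocol` (a
#'   [stimulus_protocol()]), `T`, `dt`, `seed` and the `resolved` raw list.
#' @export
load_validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  def <- .default_config()
  unknown_top <- setdiff(names(raw), names(def))
  if (length(unknown_top))
    stop("validation error: unknown config key '", unknown_top[1], "'")
  for (sec in c("model", "modulation")) {
    if (!is.null(raw[[sec]])) {
      bad <- setdiff(names(raw[[sec]]), names(def[[sec]]))
      if (length(bad))
        stop("validation error: unknown config key '", sec, ".", bad[1], "'")
    }
  }
  merged <- def
  for (k in names(raw)) {
    if (k %in% c("model", "modulation")) {
      for (kk in names(raw[[k]])) merged[[k]][[kk]] <- raw[[k]][[kk]]
    } else merged[[k]] <- raw[[k]]
  }
  segments <- as.data.frame(merged$protocol$segments)
  model_args <- merged$model[!vapply(merged$model, is.null, logical(1))]
  params <- do.call(hh_params, model_args)
  mod <- do.call(conductance_modulation, merged$modulation)
  structure(list(model = params, mod = mod,
                 protocol = stimulus_protocol(segments),
                 T = merged$T, dt = merged$dt, seed = merged$seed,
                 resolved = merged),
            class = "run_config")
}

#' Write the fully resolved configuration next to results
#'
#' @param config a `run_config`.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_resolved_config <- function(config, path) {
  out <- config$resolved
  out$package_version <- as.character(utils::packageVersion("thzneuron"))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
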