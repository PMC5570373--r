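# tiny stable content hash (FNV-1a over the serialised object); used only
# for run manifests, not for cryptographic purposes
.content_hash <- function(x) {
  b <- as.integer(serialize(x, NULL, version = 2))
  # 31-bit multiplicative hash in double arithmetic (exact below 2^53)
  h <- 17
  for (v in b) h <- (h * 65599 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Export simulation traces and summary
#'
#' Writes the trace bundle of a run as plain CSV files (calcium + voltage
#' trace table, glutamate zone peaks, receptor occupancies if stored), the
#' summary as JSON, and a run manifest recording the configuration hash,
#' protocol and perturbation.
#'
#' @param sim a `spine_sim`.
#' @param dir output directory (created if missing).
#' @param seed seed recorded in the manifest (runs are deterministic).
#' @return Invisibly, the manifest list.
#' @export
export_simulation <- function(sim, dir, seed = NA_integer_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(sim$traces, file.path(dir, "traces.csv"), row.names = FALSE)
  if (!is.null(sim$occupancies)) {
    occ <- cbind(time = sim$traces$time, as.data.frame(sim$occupancies))
    write.csv(occ, file.path(dir, "occupancies.csv"), row.names = FALSE)
  }
  s <- summarize_simulation(sim)
  jsonlite::write_json(setNames(as.list(s$value), s$output),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "spinesim",
    version = as.character(utils::packageVersion("spinesim")),
    config_hash = .content_hash(sim$config),
    protocol = sim$protocol[c("label", "duration")],
    n_pulses = length(sim$protocol$pulses),
    perturbation = unclass(sim$perturbation),
    seed = seed,
    dt = sim$dt, stride = sim$stride,
    created = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' Export glutamate zone traces as CSV
#'
#' Columns: `time_ms`, `glu_synaptic_uM`, `glu_perisynaptic_uM`,
#' `glu_extrasynaptic_uM`.
#'
#' @param pulse_times release times, ms.
#' @param path output CSV path.
#' @param config a [spine_config()].
#' @param duration trace length, ms.
#' @param dt sampling interval, ms.
#' @export
export_glutamate_csv <- function(pulse_times, path, config = spine_config(),
                                 duration = NULL, dt = 0.01) {
  if (is.null(duration))
    duration <- if (length(pulse_times)) max(pulse_times) + 50 else 50
  z <- .zone_traces(config, duration, dt, pulses = pulse_times)
  df <- data.frame(time_ms = z$times,
                   glu_synaptic_uM = z$conc[, 1],
                   glu_perisynaptic_uM = z$conc[, 2],
                   glu_extrasynaptic_uM = z$conc[, 3])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export PRCC results in heat-map layout
#'
#' @param result a `sensitivity_experiment` or `sensitivity_result`.
#' @param path CSV output path.
#' @export
export_prcc_csv <- function(result, path) {
  pr <- if (inherits(result, "sensitivity_experiment")) result$prcc else result
  write.csv(pr, path, row.names = FALSE)
  invisible(path)
}

#' Export posterior draws as CSV
#' @param posterior a `posterior_sample`.
#' @param path CSV output path.
#' @export
export_chains_csv <- function(posterior, path) {
  df <- posterior$draws
  df$seed <- posterior$seed
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
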