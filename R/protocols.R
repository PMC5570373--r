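#' Stimulation protocols
#'
#' Constructors for the presynaptic stimulation patterns used throughout:
#' a single pulse, low-frequency (10 Hz) and high-frequency (100 Hz) trains,
#' pairing variants (postsynaptic depolarisation during the train),
#' theta-burst stimulation, astrocytic glutamate pulses and the
#' backpropagating-action-potential calibration stimulus.
#'
#' @name protocols
NULL

.new_protocol <- function(pulses, duration, pairing = NULL, astro = NULL,
                          bap = NULL, label = "custom") {
  if (length(pulses) && (is.unsorted(pulses) || any(pulses < 0)))
    stop("pulse times must be sorted and non-negative", call. = FALSE)
  if (length(pulses) && max(pulses) > duration)
    stop("pulse times must fall within the protocol duration", call. = FALSE)
  structure(list(pulses = as.numeric(pulses), duration = duration,
                 pairing = pairing, astro = astro, bap = bap, label = label),
            class = "spine_protocol")
}

#' @export
print.spine_protocol <- function(x, ...) {
  cat("<spine_protocol> ", x$label, ": ", length(x$pulses), " pulses over ",
      x$duration, " ms", sep = "")
  if (!is.null(x$pairing)) cat(" + pairing depolarisation")
  if (!is.null(x$astro)) cat(" + astrocytic pulse")
  if (!is.null(x$bap)) cat(" + bAP")
  cat("\n")
  invisible(x)
}

#' @rdname protocols
#' @param frequency pulse frequency, Hz.
#' @param n_pulses number of pulses (alternative to `duration_s`).
#' @param duration_s train length in seconds.
#' @param pairing logical; clamp the postsynaptic membrane to the configured
#'   pairing potential for the duration of the train.
#' @param tail_ms quiet time appended after the last pulse, ms.
#' @return A `spine_protocol` object.
#' @export
#' @examples
#' make_train(100, duration_s = 1)   # HFS: 100 pulses, 10 ms apart
#' make_train(10, duration_s = 1)    # LFS
#' make_train(100, n_pulses = 1)     # single stimulus
make_train <- function(frequency, n_pulses = NULL, duration_s = NULL,
                       pairing = FALSE, tail_ms = 300) {
  stopifnot(frequency > 0)
  if (is.null(n_pulses)) {
    if (is.null(duration_s)) stop("give n_pulses or duration_s", call. = FALSE)
    n_pulses <- round(duration_s * frequency)
  }
  isi <- 1000 / frequency
  pulses <- (seq_len(n_pulses) - 1) * isi
  train_end <- max(pulses) + isi
  pairing_spec <- if (pairing) list(onset = 0, offset = train_end) else NULL
  label <- if (n_pulses == 1) "1pulse"
           else if (frequency >= 100) "hfs"
           else if (frequency <= 10) "lfs"
           else paste0(frequency, "Hz")
  if (pairing) label <- paste0("pairing-", label)
  .new_protocol(pulses, max(pulses) + tail_ms, pairing = pairing_spec,
                label = label)
}

#' @rdname protocols
#' @param trains number of theta-burst trains; each train is 10 bursts at
#'   5 Hz, each burst 4 pulses at 100 Hz.
#' @param inter_train_ms gap between trains, ms.
#' @export
#' @examples
#' length(make_tbs(1)$pulses)   # 40
make_tbs <- function(trains = 4, pairing = TRUE, inter_train_ms = 2000,
                     tail_ms = 300) {
  stopifnot(trains >= 1)
  burst <- (0:3) * 10                      # 4 pulses at 100 Hz
  train <- as.vector(outer(burst, (0:9) * 200, "+"))  # 10 bursts at 5 Hz
  train_len <- max(train) + 10
  pulses <- as.vector(outer(train, (seq_len(trains) - 1) * inter_train_ms, "+"))
  pulses <- sort(pulses)
  pairing_spec <- if (pairing)
    list(onset = 0, offset = max(pulses) + 10) else NULL
  .new_protocol(pulses, max(pulses) + tail_ms, pairing = pairing_spec,
                label = if (pairing) paste0("pairing-tbs", trains)
                        else paste0("tbs", trains))
}

#' @rdname protocols
#' @param duration astrocytic pulse duration, ms.
#' @param amplitude_mM pulse amplitude, mM.
#' @param onset pulse onset, ms.
#' @export
make_astro_protocol <- function(duration = 20, amplitude_mM = 1, onset = 5,
                                tail_ms = 200) {
  stopifnot(duration > 0, amplitude_mM >= 0)
  .new_protocol(numeric(0), onset + duration + tail_ms,
                astro = list(onset = onset, duration = duration,
                             amplitude_mM = amplitude_mM),
                label = "astro")
}

#' @rdname protocols
#' @param onset bAP onset, ms.
#' @param duration_ms total simulated time for the bAP run, ms.
#' @export
make_bap_protocol <- function(onset = 5, duration_ms = 150) {
  .new_protocol(numeric(0), duration_ms, bap = list(onset = onset),
                label = "bap")
}

#' Control perturbation set
#'
#' The condition without amyloid-beta disturbances: 1500 glutamate molecules
#' per release, 0.5 mM transporters, 0.25 uM resting glutamate, receptor
#' complement {12 sNR2A, 8 sNR2B, 3 pNR2B, 8 eNR2B, 85 sAMPAR,
#' 20 eAMPAR/um^2} and no desensitisation inhibition.
#'
#' @return A `perturbation_set` list.
#' @export
#' @examples
#' p <- control_perturbation()
#' p$counts$s_nr2a + p$counts$s_nr2b   # 20 NMDARs in the PSD
control_perturbation <- function() {
  structure(list(
    molecules_per_release = 1500,
    b_total_scale = 1,
    glu_rest = 0.25,
    counts = list(s_nr2a = 12, s_nr2b = 8, p_nr2b = 3, e_nr2b = 8,
                  s_ampar = 85, e_ampar_density = 20),
    desens_inhibition = list(s_nr2a = 0, s_nr2b = 0, p_nr2b = 0, e_nr2b = 0,
                             s_ampar = 0, e_ampar = 0)
  ), class = "perturbation_set")
}

#' @export
print.perturbation_set <- function(x, ...) {
  cat("<perturbation_set> G0 =", x$molecules_per_release,
      "| B_total scale =", x$b_total_scale,
      "| [Glu]_rest =", x$glu_rest, "uM\n")
  cat("  counts:", paste(names(x$counts), unlist(x$counts), sep = "=",
                         collapse = " "), "\n")
  di <- unlist(x$desens_inhibition)
  if (any(di > 0))
    cat("  desens inhibition:", paste(names(di)[di > 0], di[di > 0],
                                      sep = "=", collapse = " "), "\n")
  invisible(x)
}

# the fifteen sweepable factor names (sensitivity-analysis factor set)
.factor_names <- c("G0", "Glu_rest", "TP", "Ds2A", "Ds2B", "DsAMPAR",
                   "Dp2B", "De2B", "DeAMPAR", "n_sNR2A", "n_sNR2B",
                   "n_sAMPAR", "n_pNR2B", "n_eNR2B", "n_eAMPAR")

# apply one named factor value to a perturbation set
.apply_factor <- function(pert, name, value) {
  switch(name,
    G0       = { pert$molecules_per_release <- value },
    Glu_rest = { pert$glu_rest <- value },
    TP       = { pert$b_total_scale <- value / 0.5 },  # value in mM
    Ds2A     = { pert$desens_inhibition$s_nr2a <- value },
    Ds2B     = { pert$desens_inhibition$s_nr2b <- value },
    DsAMPAR  = { pert$desens_inhibition$s_ampar <- value },
    Dp2B     = { pert$desens_inhibition$p_nr2b <- value },
    De2B     = { pert$desens_inhibition$e_nr2b <- value },
    DeAMPAR  = { pert$desens_inhibition$e_ampar <- value },
    n_sNR2A  = { pert$counts$s_nr2a <- round(value) },
    n_sNR2B  = { pert$counts$s_nr2b <- round(value) },
    n_sAMPAR = { pert$counts$s_ampar <- round(value) },
    n_pNR2B  = { pert$counts$p_nr2b <- round(value) },
    n_eNR2B  = { pert$counts$e_nr2b <- round(value) },
    n_eAMPAR = { pert$counts$e_ampar_density <- value },
    stop("unknown perturbation factor: ", name, call. = FALSE)
  )
  pert
}

#' One-factor perturbation sweep
#'
#' Builds one perturbation set per value of a named factor, all other
#' parameters at control.  Factor names follow the sensitivity-analysis
#' table: `G0`, `Glu_rest` (uM), `TP` (transporter concentration, mM),
#' `Ds2A`/`Ds2B`/`DsAMPAR`/`Dp2B`/`De2B`/`DeAMPAR` (desensitisation
#' inhibition fractions) and `n_sNR2A`, `n_sNR2B`, `n_sAMPAR`, `n_pNR2B`,
#' `n_eNR2B`, `n_eAMPAR` (receptor counts / density).
#'
#' @param parameter factor name.
#' @param values numeric values to sweep.
#' @return A list of `perturbation_set` objects (possibly empty).
#' @export
#' @examples
#' length(sweep_perturbations("G0", c(500, 1500, 5000, 10000)))
sweep_perturbations <- function(parameter, values) {
  if (!parameter %in% .factor_names)
    stop("unknown perturbation factor: ", parameter, call. = FALSE)
  lapply(values, function(v) .apply_factor(control_perturbation(), parameter, v))
}

#' NR2A:NR2B ratio perturbation at fixed PSD total
#'
#' @param nr2a,nr2b PSD receptor numbers; must sum to `total`.
#' @param total total PSD NMDAR count held constant (20).
#' @export
#' @examples
#' ratio_perturbation(15, 5)
ratio_perturbation <- function(nr2a, nr2b, total = 20) {
  if (nr2a + nr2b != total)
    stop("NR2A + NR2B must equal the fixed PSD total of ", total, call. = FALSE)
  p <- control_perturbation()
  p$counts$s_nr2a <- nr2a
  p$counts$s_nr2b <- nr2b
  p
}
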