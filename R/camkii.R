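# CaMKII state-transition stage defaults.
#
# The cascade is a structural reimplementation of the staged scheme the
# calcium model feeds (CaM loading -> CaMKII activation -> autophosphorylation
# -> PSD translocation -> anchoring on NR2B), with all rates configurable.
# The published parameterisation of the original holoenzyme model is not
# reproduced; rates are calibrated so the qualitative behaviour of the
# downstream readouts (supralinear calcium dependence, blocking threshold,
# interior optimum of the NR2A:NR2B ratio) holds.  See the methods vignette.
.camkii_defaults <- function() list(
  cam_total = 30,        # uM total calmodulin (spine head)
  camkii_total = 20,     # uM total CaMKII subunits
  k1 = 1e-3,             # /uM^2/ms  Ca pair binding, N-lobe
  k1m = 27.2,            # /ms       (lobe Ca_half = 165 uM; operating range of
  k2 = 1e-3,             # /uM^2/ms   the pairing-protocol calcium drive)
  k2m = 49.6,            # /ms       (C-lobe Ca_half = 223 uM)
  kb = 3e-4,             # /uM/ms    Ca4CaM binding to CaMKII
  kbm = 2e-3,            # /ms       unbinding
  kp = 5e-3,             # /ms       autophosphorylation scale (x active fraction)
  kpp = 1e-5,            # /ms       dephosphorylation
  kt = 1e-3,             # /ms       translocation into PSD
  ktm = 2e-4,            # /ms       return from PSD
  kn = 1e-2,             # /uM/ms    binding to NR2B slots
  knm = 1e-5,            # /ms       complex dissociation
  slots_per_nr2b = 6,    # CaMKII subunit binding sites per NR2B tail
  ca_tail_tau = 30       # ms; decay of the Ca drive after the simulated window
)

# extend a simulated Ca trace to t_end (ms) with an exponential tail to rest
.extend_ca <- function(times, ca, t_end, rest, tau) {
  if (max(times) >= t_end) return(list(times = times, ca = ca))
  t0 <- max(times)
  c0 <- ca[length(ca)]
  extra <- unique(c(seq(t0 + 1, min(t0 + 10 * tau, t_end), by = tau / 4),
                    seq(min(t0 + 10 * tau, t_end), t_end, length.out = 50)))
  list(times = c(times, extra),
       ca = c(ca, rest + (c0 - rest) * exp(-(extra - t0) / tau)))
}

#' Calmodulin loading by a calcium time course
#'
#' Sequential two-lobe loading `CaM + 2Ca <-> CaM2 + 2Ca <-> Ca4CaM` as
#' mass-action ODEs with lobe rates quadratic in free calcium.
#'
#' @param times,ca driving calcium trace (ms, uM).
#' @param config a [spine_config()] (section `camkii`).
#' @param out_times output grid (defaults to `times`).
#' @return tibble `time`, `cam0`, `cam2`, `cam4` (uM).
#' @export
cam_loading <- function(times, ca, config = spine_config(), out_times = NULL) {
  p <- config$camkii
  caf <- approxfun(times, ca, rule = 2)
  if (is.null(out_times)) out_times <- times
  rhs <- function(t, y, parms) {
    c2 <- caf(t)^2
    f1 <- p$k1 * c2 * y[1] - p$k1m * y[2]
    f2 <- p$k2 * c2 * y[2] - p$k2m * y[3]
    list(c(-f1, f1 - f2, f2))
  }
  y0 <- c(p$cam_total, 0, 0)
  sol <- deSolve::lsoda(y0, out_times, rhs, parms = NULL, rtol = 1e-8, atol = 1e-10)
  tibble::tibble(time = sol[, 1], cam0 = sol[, 2], cam2 = sol[, 3], cam4 = sol[, 4])
}

# closed-form equilibrium Ca4CaM fraction at clamped Ca (test oracle partner)
.cam_equilibrium <- function(ca, p) {
  l1 <- p$k1 * ca^2 / p$k1m
  l2 <- p$k2 * ca^2 / p$k2m
  p$cam_total * l1 * l2 / (1 + l1 + l1 * l2)
}

#' CaMKII state-transition cascade driven by spine calcium
#'
#' ODE cascade: inactive subunits bind Ca4CaM, active subunits
#' autophosphorylate (neighbour catalysis approximated by a quadratic
#' dependence on the active fraction), translocate to the PSD and anchor on
#' NR2B tails with saturable capacity `slots_per_nr2b * nr2b_count`.
#'
#' @param times,ca spine-head calcium drive (ms, uM).
#' @param nr2b_count PSD NR2B-NMDAR count (capacity factor).
#' @param config a [spine_config()].
#' @param t_end total simulated time, ms (drive is extended with an
#'   exponential tail to rest).
#' @param rest resting calcium, uM.
#' @return A `camkii_run`: list with `traces` (tibble: time, cam4, w_i, w_b,
#'   w_p, w_psd, w_n) and `outputs` (tibble of the four summary readouts:
#'   peak Ca4CaM, peak autophosphorylated subunits, peak PSD CaMKII, final
#'   CaMKII-NMDAR complex, in uM of subunits).
#' @export
camkii_transition <- function(times, ca, nr2b_count,
                              config = spine_config(), t_end = 3e5,
                              rest = config$calcium$ca_rest) {
  stopifnot(nr2b_count >= 0)
  p <- config$camkii
  ext <- .extend_ca(times, ca, t_end, rest, p$ca_tail_tau)
  caf <- approxfun(ext$times, ext$ca, rule = 2)
  cap <- p$slots_per_nr2b * nr2b_count /
    (602.2140857 * .geom(config)$psd_volume) # receptors -> uM in the PSD
  wt <- p$camkii_total
  rhs <- function(t, y, parms) {
    cam0 <- y[1]; cam2 <- y[2]; cam4 <- y[3]
    wi <- y[4]; wb <- y[5]; wp <- y[6]; wpsd <- y[7]; wn <- y[8]
    c2 <- caf(t)^2
    f1 <- p$k1 * c2 * cam0 - p$k1m * cam2
    f2 <- p$k2 * c2 * cam2 - p$k2m * cam4
    act <- (wb + wp + wpsd + wn) / wt
    bind <- p$kb * cam4 * wi - p$kbm * wb
    phos <- p$kp * wb * act
    deph <- p$kpp * wp
    tloc <- p$kt * wp - p$ktm * wpsd
    free_cap <- max(cap - wn, 0)
    anch <- p$kn * wpsd * free_cap - p$knm * wn
    list(c(-f1, f1 - f2, f2 - 0,
           -bind + deph, bind - phos, phos - deph - tloc,
           tloc - anch, anch))
  }
  y0 <- c(p$cam_total, 0, 0, p$camkii_total, 0, 0, 0, 0)
  out_times <- unique(c(seq(0, min(5000, t_end), by = 5),
                        seq(min(5000, t_end), t_end, length.out = 400)))
  sol <- deSolve::lsoda(y0, out_times, rhs, parms = NULL,
                        rtol = 1e-8, atol = 1e-12)
  tr <- tibble::tibble(time = sol[, 1], cam4 = sol[, 4],
                       w_i = sol[, 5], w_b = sol[, 6], w_p = sol[, 7],
                       w_psd = sol[, 8], w_n = sol[, 9])
  outputs <- tibble::tibble(
    output = c("ca4cam_peak", "phospho_peak", "psd_peak", "complex_final"),
    value = c(max(tr$cam4),
              max(tr$w_p + tr$w_psd + tr$w_n),
              max(tr$w_psd + tr$w_n),
              tr$w_n[nrow(tr)]),
    unit = "uM"
  )
  structure(list(traces = tr, outputs = outputs, capacity = cap),
            class = "camkii_run")
}

#' @export
print.camkii_run <- function(x, ...) {
  cat("<camkii_run> capacity", signif(x$capacity, 3), "uM\n")
  print(x$outputs)
  invisible(x)
}

#' Run the calcium model and feed the CaMKII cascade
#'
#' @param protocol a `spine_protocol` (typically pairing HFS or TBS).
#' @param perturbation a `perturbation_set`.
#' @param config a [spine_config()].
#' @param t_end cascade horizon, ms.
#' @return A `camkii_run` with the driving `spine_sim` attached as `$sim`.
#' @export
camkii_experiment <- function(protocol, perturbation = control_perturbation(),
                              config = spine_config(), t_end = 3e5) {
  sim <- run_simulation(protocol, perturbation, config, keep_occupancies = FALSE)
  run <- camkii_transition(sim$traces$time, sim$traces$ca_spine,
                           nr2b_count = perturbation$counts$s_nr2b,
                           config = config, t_end = t_end)
  run$sim <- sim
  run
}

#' NR2A:NR2B ratio experiment
#'
#' Runs the full pipeline for a set of PSD subunit ratios at fixed total (20
#' NMDARs), normalises the four downstream outputs to the control (12:8) run
#' and reports the ratio maximising CaMKII-NMDAR complex formation.
#'
#' @param nr2a_counts NR2A counts to test (NR2B = total - NR2A).
#' @param protocol a pairing protocol (default 1 s pairing HFS).
#' @param config a [spine_config()].
#' @param total fixed PSD NMDAR total.
#' @param t_end cascade horizon, ms.
#' @return A tibble: `nr2a`, `nr2b`, `ca_peak_spine`, the four raw outputs
#'   and their control-normalised versions (`*_norm`), with the argmax ratio
#'   in attribute `"optimum"`.
#' @export
ratio_experiment <- function(nr2a_counts = c(1, 3, 6, 9, 12, 15, 17, 19),
                             protocol = make_train(100, duration_s = 1,
                                                   pairing = TRUE),
                             config = spine_config(), total = 20,
                             t_end = 3e5) {
  stopifnot(all(nr2a_counts >= 0), all(nr2a_counts <= total))
  counts <- sort(unique(c(nr2a_counts, 12)))
  rows <- lapply(counts, function(a) {
    pert <- ratio_perturbation(a, total - a, total)
    run <- camkii_experiment(protocol, pert, config, t_end)
    v <- setNames(run$outputs$value, run$outputs$output)
    tibble::tibble(nr2a = a, nr2b = total - a,
                   ca_peak_spine = max(run$sim$traces$ca_spine),
                   ca4cam_peak = v[["ca4cam_peak"]],
                   phospho_peak = v[["phospho_peak"]],
                   psd_peak = v[["psd_peak"]],
                   complex_final = v[["complex_final"]])
  })
  out <- dplyr::bind_rows(rows)
  ctrl <- out[out$nr2a == 12, ]
  norm <- function(x, x0) ifelse(rep(x0 > 0, length(x)), x / x0, NA_real_)
  out$ca4cam_norm <- norm(out$ca4cam_peak, ctrl$ca4cam_peak)
  out$phospho_norm <- norm(out$phospho_peak, ctrl$phospho_peak)
  out$psd_norm <- norm(out$psd_peak, ctrl$psd_peak)
  out$complex_norm <- norm(out$complex_final, ctrl$complex_final)
  out <- out[out$nr2a %in% nr2a_counts, ]
  attr(out, "optimum") <- out$nr2a[which.max(out$complex_final)]
  out
}
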