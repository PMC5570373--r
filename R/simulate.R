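# Assemble the full engine parameter set for a config + perturbation.
.sim_params <- function(config, pert) {
  cfg <- config
  # perturbation onto config
  cfg$glutamate$molecules_per_vesicle <- pert$molecules_per_release
  cfg$glutamate$glu_rest <- pert$glu_rest
  b_total <- config$glutamate$b_total * pert$b_total_scale
  cnt <- pert$counts
  di <- pert$desens_inhibition

  geom <- .geom(cfg)
  e <- cfg$electrics
  ca <- cfg$calcium
  pas <- .passive(cfg)

  sc <- list(
    s_nr2a = build_scheme("NR2A", cfg, di$s_nr2a),
    s_nr2b = build_scheme("NR2B", cfg, di$s_nr2b),
    p_nr2b = build_scheme("NR2B", cfg, di$p_nr2b),
    e_nr2b = build_scheme("NR2B", cfg, di$e_nr2b),
    s_ampar = build_scheme("AMPAR", cfg, di$s_ampar),
    e_ampar = build_scheme("AMPAR", cfg, di$e_ampar)
  )
  schemes <- lapply(sc, function(s)
    list(Q0 = s$Q0, Q1 = s$Q1, open = match(s$open_state, s$states)))
  counts <- c(cnt$s_nr2a, cnt$s_nr2b, cnt$p_nr2b, cnt$e_nr2b,
              cnt$s_ampar, cnt$e_ampar_density * geom$shaft_area)
  zones <- c(0L, 0L, 1L, 2L, 0L, 2L)

  vol <- c(geom$psd_volume, geom$cyt_volume, geom$neck_volume, geom$shaft_volume)
  area <- c(geom$psd_area, geom$head_area, geom$neck_area, geom$shaft_area)
  spine_side <- c(TRUE, TRUE, TRUE, FALSE)
  qp <- .q10_factor(cfg, "pump_kinetics")
  pmca_dens <- ifelse(spine_side, ca$pmca$density_spine, ca$pmca$density_shaft)
  ncx_dens <- ifelse(spine_side, ca$ncx$density_spine, ca$ncx$density_shaft)
  pmca_vmax <- pmca_dens * area * ca$pmca$turnover * qp
  ncx_vmax <- ncx_dens * area * ca$ncx$turnover * qp
  rest <- ca$ca_rest
  leak_in <- pmca_vmax * rest / (rest + ca$pmca$km) +
             ncx_vmax * rest / (rest + ca$ncx$km)

  qb <- .q10_factor(cfg, "buffer_kinetics")
  btot <- ifelse(spine_side, ca$buffer$btot_spine, ca$buffer$btot_dend)
  kon_b <- ifelse(spine_side, ca$buffer$kon_spine, ca$buffer$kon_dend) * qb
  koff_b <- ifelse(spine_side, ca$buffer$koff_spine, ca$buffer$koff_dend) * qb

  # inter-compartment diffusional couplings D*A/dist (um^3/ms)
  h_psd <- geom$psd_volume / geom$psd_area
  d1 <- h_psd / 2 + geom$head_radius / 2
  d2 <- geom$head_radius / 2 + geom$neck_length / 2
  d3 <- geom$neck_length / 2 + geom$shaft_radius
  a_neck <- pi * geom$neck_radius^2
  gdiff <- ca$d_ca * c(geom$psd_area / d1, a_neck / d2, a_neck / d3)

  qv <- .q10_factor(cfg, "vdcc_conductance")
  pars <- list(
    schemes = unname(schemes), counts = counts, zones = zones,
    cm_s = pas$cm_s, cm_d = pas$cm_d, gl_s = pas$gl_s, gl_d = pas$gl_d,
    e_leak = e$e_leak, g_neck = pas$g_neck,
    g_nmda = sc$s_nr2a$conductance, g_ampa = sc$s_ampar$conductance,
    e_syn = e$e_syn, mg = e$mg, mg_k0 = e$mg_k0, mg_slope = e$mg_slope,
    vdcc_n_s = e$vdcc$density_spine * geom$head_area,
    vdcc_n_d = e$vdcc$density_shaft * geom$shaft_area,
    vdcc_vh = e$vdcc$vh, vdcc_k = e$vdcc$k,
    vdcc_tau = e$vdcc$tau / .q10_factor(cfg, "vdcc_kinetics"),
    p_vdcc = e$vdcc$p_ca * qv, p_nmda = cfg$receptors$p_ca_nmda,
    ca_out = ca$ca_out, rt_f = .rt_over_f(cfg$temperature),
    vol = vol, pmca_vmax = pmca_vmax, ncx_vmax = ncx_vmax,
    pmca_km = ca$pmca$km, ncx_km = ca$ncx$km, leak_in = leak_in,
    btot = btot, kon_b = kon_b, koff_b = koff_b, gdiff = gdiff
  )
  list(pars = pars, schemes = sc, cfg = cfg, geom = geom,
       b_total = b_total, rest = rest,
       kd_b = koff_b / kon_b, btot_eff = btot)
}

# initial state: receptor steady states at zone resting glutamate, resting
# potential and resting calcium/buffer loads
.sim_init <- function(sp) {
  cfg <- sp$cfg
  rest_glu <- c(synaptic = 0, perisynaptic = cfg$glutamate$glu_rest,
                extrasynaptic = cfg$glutamate$glu_rest)
  zone_of_scheme <- c(1, 1, 2, 3, 1, 3)
  y <- numeric(64)
  off <- 0
  for (i in seq_along(sp$schemes)) {
    s <- sp$schemes[[i]]
    ss <- steady_state(s, rest_glu[zone_of_scheme[i]])
    y[off + seq_along(s$states)] <- as.numeric(ss[1, s$states])
    off <- off + length(s$states)
  }
  el <- cfg$electrics$e_leak
  y[47] <- el; y[48] <- el
  g <- .vdcc_gate(cfg)
  y[49] <- g$minf(el); y[50] <- g$minf(el)
  rest <- sp$rest
  y[51:54] <- rest
  y[55:58] <- sp$btot_eff * rest / (rest + sp$kd_b)
  y
}

#' Run the integrated spine simulation
#'
#' The full pipeline: glutamate zone traces for the protocol, deterministic
#' receptor state-fraction kinetics, two-compartment membrane potential with
#' Mg-block and VDCC gating, and the four-compartment calcium system with
#' pumps, immobile buffers and inter-compartment diffusion, integrated
#' jointly by a fixed-step RK4 core.
#'
#' @param protocol a `spine_protocol` (see [make_train()]).
#' @param perturbation a `perturbation_set` (default [control_perturbation()]).
#' @param config a [spine_config()].
#' @param dt integration step, ms.
#' @param stride output is stored every `stride` steps.
#' @param keep_occupancies keep receptor occupancy traces in the result.
#' @return A `spine_sim` object; see [summarize_simulation()], [tidy()],
#'   [glance()], [autoplot()].
#' @export
#' @examples
#' \donttest{
#' sim <- run_simulation(make_train(100, n_pulses = 1))
#' glance(sim)
#' }
run_simulation <- function(protocol, perturbation = control_perturbation(),
                           config = spine_config(),
                           dt = config$protocol$dt,
                           stride = config$protocol$stride,
                           keep_occupancies = TRUE) {
  stopifnot(inherits(protocol, "spine_protocol"))
  sp <- .sim_params(config, perturbation)
  cfg <- sp$cfg
  duration <- protocol$duration
  n_steps <- ceiling(duration / dt)
  dt_half <- dt / 2

  zt <- .zone_traces(cfg, n_steps * dt, dt_half, pulses = protocol$pulses,
                     molecules = perturbation$molecules_per_release,
                     b_total = sp$b_total, glu_rest = perturbation$glu_rest,
                     astro = protocol$astro)

  # command clamps on the dt grid
  nt <- n_steps + 1L
  tgrid <- (seq_len(nt) - 1L) * dt
  vcmd_s <- numeric(0); gcl_s <- numeric(0)
  vcmd_d <- numeric(0); gcl_d <- numeric(0)
  el <- cfg$electrics$e_leak
  if (!is.null(protocol$pairing)) {
    on <- tgrid >= protocol$pairing$onset & tgrid <= protocol$pairing$offset
    vcmd_s <- vcmd_d <- rep(el, nt)
    vcmd_s[on] <- cfg$electrics$pairing_v
    vcmd_d[on] <- cfg$electrics$pairing_v
    gcl_s <- gcl_d <- ifelse(on, cfg$electrics$pairing_g, 0)
  }
  if (!is.null(protocol$bap)) {
    w <- bap_waveform(cfg, t = tgrid, onset = protocol$bap$onset)
    vcmd_d <- w$v
    gcl_d <- rep(cfg$electrics$bap$g_clamp, nt)
    if (!length(vcmd_s)) { vcmd_s <- rep(el, nt); gcl_s <- rep(0, nt) }
  }

  y0 <- .sim_init(sp)

  # balance the resting state exactly: the constant leak term absorbs both
  # the pump activity at resting calcium and the resting-glutamate trickle
  # through tonically open NMDARs, so an unstimulated run stays flat
  blk0 <- mg_block_factor(cfg$electrics$e_leak, config = cfg)
  phi0 <- .ghk_flux(cfg$receptors$p_ca_nmda, cfg$electrics$e_leak,
                    sp$rest, cfg$calcium$ca_out, cfg$temperature)
  cnt <- sp$pars$counts
  open0 <- y0[c(8, 16, 24, 32)]
  f0 <- cnt[1:4] * open0 * blk0 * phi0
  rest_influx <- c(f0[1] + f0[2], f0[3], 0, f0[4])
  sp$pars$leak_in <- pmax(sp$pars$leak_in - rest_influx, 0)

  res <- engine_cpp(sp$pars, y0, dt, n_steps, stride, zt$conc,
                    vcmd_s, gcl_s, vcmd_d, gcl_d)

  st <- res$state
  vol <- sp$pars$vol
  head_w <- vol[1:2] / sum(vol[1:2])
  ca_spine <- st[, 51] * head_w[1] + st[, 52] * head_w[2]

  traces <- tibble::tibble(
    time = res$time,
    ca_psd = st[, 51], ca_cyt = st[, 52], ca_neck = st[, 53],
    ca_shaft = st[, 54], ca_spine = ca_spine,
    buf_psd = st[, 55], buf_cyt = st[, 56], buf_neck = st[, 57],
    buf_shaft = st[, 58],
    v_spine = st[, 47], v_shaft = st[, 48],
    open_s_nr2a = st[, 8], open_s_nr2b = st[, 16],
    open_p_nr2b = st[, 24], open_e_nr2b = st[, 32],
    open_s_ampar = st[, 36], open_e_ampar = st[, 43]
  )
  counters <- setNames(as.numeric(st[nrow(st), 59:64]),
                       c("ca_ions_snr2a", "ca_ions_snr2b", "ca_ions_pnr2b",
                         "ca_ions_enr2b", "ca_ions_vdcc_spine",
                         "ca_ions_vdcc_shaft"))
  occ <- if (keep_occupancies) {
    occ_names <- unlist(lapply(names(sp$schemes), function(nm)
      paste0(nm, ".", sp$schemes[[nm]]$states)))
    m <- st[, 1:46, drop = FALSE]
    colnames(m) <- occ_names
    m
  } else NULL

  glu_peaks <- apply(zt$conc, 2, max)

  out <- structure(list(
    traces = traces, counters = counters, occupancies = occ,
    glu_peaks = glu_peaks, protocol = protocol, perturbation = perturbation,
    config = cfg, volumes = vol, dt = dt, stride = stride
  ), class = "spine_sim")
  out
}

#' @export
print.spine_sim <- function(x, ...) {
  s <- summarize_simulation(x)
  cat("<spine_sim> protocol ", x$protocol$label, ", ",
      nrow(x$traces), " stored steps over ", max(x$traces$time), " ms\n", sep = "")
  cat("  spine [Ca]_peak ", signif(s$value[s$output == "ca_peak_spine"], 3),
      " uM | shaft ", signif(s$value[s$output == "ca_peak_shaft"], 3),
      " uM | spine EPSP ", signif(s$value[s$output == "epsp_spine"], 3), " mV\n",
      sep = "")
  invisible(x)
}

#' Summary outputs of a simulation
#'
#' The eight sensitivity-analysis outputs -- cumulative calcium entry
#' through each NMDAR class, peak spine-head and shaft calcium, peak spine
#' and shaft membrane potential -- plus EPSP amplitudes and glutamate peaks.
#'
#' @param sim a `spine_sim`.
#' @return A tibble `output`, `value`, `unit`.
#' @export
summarize_simulation <- function(sim) {
  tr <- sim$traces
  el <- sim$config$electrics$e_leak
  tibble::tibble(
    output = c("ca_by_snr2a", "ca_by_snr2b", "ca_by_pnr2b", "ca_by_enr2b",
               "ca_peak_spine", "ca_peak_shaft", "v_peak_spine",
               "v_peak_shaft", "epsp_spine", "epsp_shaft",
               "ca_ions_vdcc_spine", "ca_ions_vdcc_shaft",
               "glu_peak_synaptic", "glu_peak_perisynaptic",
               "glu_peak_extrasynaptic"),
    value = c(unname(sim$counters[1:4]),
              max(tr$ca_spine), max(tr$ca_shaft),
              max(tr$v_spine), max(tr$v_shaft),
              max(tr$v_spine) - el, max(tr$v_shaft) - el,
              unname(sim$counters[5:6]),
              unname(sim$glu_peaks)),
    unit = c(rep("ions", 4), "uM", "uM", "mV", "mV", "mV", "mV",
             "ions", "ions", "uM", "uM", "uM")
  )
}

#' Receptor dwell-time and influx differences between two runs
#'
#' Per-receptor-class, per-state additional dwell time (`t_add`, ms) and
#' additional calcium entry (`ca_add`, ions) of a perturbed run relative to
#' a control run on the same protocol.
#'
#' @param sim,control `spine_sim` objects with stored occupancies and
#'   identical time grids.
#' @return tibble `class`, `state`, `t_add`, plus one `ca_add` row per class.
#' @export
sim_receptor_metrics <- function(sim, control) {
  stopifnot(!is.null(sim$occupancies), !is.null(control$occupancies))
  if (!isTRUE(all.equal(sim$traces$time, control$traces$time)))
    stop("runs are on different time grids", call. = FALSE)
  tt <- sim$traces$time
  trapz <- function(y) sum(diff(tt) * (head(y, -1) + tail(y, -1)) / 2)
  d <- sim$occupancies - control$occupancies
  parts <- strsplit(colnames(d), ".", fixed = TRUE)
  out <- tibble::tibble(
    class = vapply(parts, `[`, "", 1),
    state = vapply(parts, `[`, "", 2),
    t_add = apply(d, 2, trapz)
  )
  ca <- tibble::tibble(
    class = c("s_nr2a", "s_nr2b", "p_nr2b", "e_nr2b"),
    ca_add = unname(sim$counters[1:4] - control$counters[1:4])
  )
  dplyr::left_join(out, ca, by = "class")
}
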