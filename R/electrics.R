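#' Voltage-dependent magnesium block of the NMDAR
#'
#' Standard extracellular-Mg sigmoidal voltage dependence
#' `1 / (1 + [Mg] exp(-slope V) / K0)`: monotonically increasing in V,
#' approaching 1 at depolarised potentials and equal to 1 without Mg.
#'
#' @param v membrane potential, mV (vectorised).
#' @param mg external magnesium, mM.
#' @param config a [spine_config()] supplying `K0` and the voltage slope.
#' @return Unblocked fraction in (0, 1\].
#' @export
#' @examples
#' mg_block_factor(c(-70, 0), mg = 1)
mg_block_factor <- function(v, mg = NULL, config = spine_config()) {
  e <- config$electrics
  if (is.null(mg)) mg <- e$mg
  stopifnot(mg >= 0)
  1 / (1 + mg / e$mg_k0 * exp(-e$mg_slope * v))
}

# VDCC activation steady state and (Q10-scaled) time constant
.vdcc_gate <- function(config) {
  v <- config$electrics$vdcc
  list(minf = function(V) 1 / (1 + exp(-(V - v$vh) / v$k)),
       tau = v$tau / .q10_factor(config, "vdcc_kinetics"))
}

#' VDCC activation gate driven by a voltage trace
#'
#' First-order Hodgkin-Huxley-type activation `dm/dt = (m_inf(V) - m)/tau`;
#' the channel open probability used by the calcium model is `m^2`.
#'
#' @param times,v voltage trace (ms, mV).
#' @param config a [spine_config()].
#' @param m0 initial gate value (defaults to `m_inf(v[1])`).
#' @return A tibble `time`, `m`, `open` (`= m^2`).
#' @export
vdcc_open_fraction <- function(times, v, config = spine_config(), m0 = NULL) {
  g <- .vdcc_gate(config)
  vf <- approxfun(times, v, rule = 2)
  if (is.null(m0)) m0 <- g$minf(v[1])
  sol <- deSolve::lsoda(c(m = m0), times,
                        function(t, y, p) list((g$minf(vf(t)) - y) / g$tau),
                        parms = NULL, rtol = 1e-8, atol = 1e-10)
  tibble::tibble(time = sol[, 1], m = sol[, 2], open = sol[, 2]^2)
}

#' Backpropagating action potential command waveform
#'
#' Stereotyped AP-shaped depolarisation imposed on the dendritic shaft
#' (difference of exponentials, normalised to the configured amplitude
#' above rest); the spine is depolarised only through the neck resistance.
#'
#' @param config a [spine_config()].
#' @param t times at which to evaluate, ms.
#' @param onset waveform onset, ms.
#' @return A tibble `time`, `v` (mV, absolute command potential).
#' @export
bap_waveform <- function(config = spine_config(), t = seq(0, 50, by = 0.01),
                         onset = 5) {
  b <- config$electrics$bap
  e <- config$electrics$e_leak
  s <- pmax(t - onset, 0)
  w <- exp(-s / b$tau_decay) - exp(-s / b$tau_rise)
  w[s == 0] <- 0
  tp <- b$tau_rise * b$tau_decay / (b$tau_decay - b$tau_rise) *
    log(b$tau_decay / b$tau_rise)
  wmax <- exp(-tp / b$tau_decay) - exp(-tp / b$tau_rise)
  tibble::tibble(time = t, v = e + b$amplitude * w / wmax)
}

# compartment passive parameters derived from geometry (pF, nS)
.passive <- function(config) {
  geom <- .geom(config)
  e <- config$electrics
  # 1 uF/cm^2 = 0.01 pF/um^2
  cm_s <- e$cm * 0.01 * geom$head_area
  cm_d <- e$c_shaft_load            # dendritic load dominates the shaft node
  list(cm_s = cm_s, cm_d = cm_d,
       gl_s = e$g_leak_spine, gl_d = e$g_leak_shaft,
       g_neck = 1e3 / e$r_neck)  # MOhm -> nS
}

#' Two-compartment membrane-potential simulation
#'
#' Integrates the spine-head and dendritic-shaft RC compartments coupled by
#' the neck resistance, driven by receptor open-fraction traces (synaptic
#' conductances enter the spine; extrasynaptic conductances and the optional
#' command clamp enter as configured).  This is the reference electrical
#' path; [run_simulation()] solves the same circuit jointly with the calcium
#' model.
#'
#' @param times common time grid, ms.
#' @param g_spine,g_shaft total synaptic conductance traces entering each
#'   compartment, nS (already multiplied by open fractions, receptor counts
#'   and, for NMDARs, the Mg block if desired).
#' @param config a [spine_config()].
#' @param vcmd_shaft,gclamp_shaft optional command potential trace (mV) and
#'   clamp conductance (nS) applied to the shaft.
#' @return A `voltage_trace` tibble `time`, `v_spine`, `v_shaft` with EPSP
#'   peak attributes.
#' @export
simulate_potential <- function(times, g_spine = 0, g_shaft = 0,
                               config = spine_config(),
                               vcmd_shaft = NULL, gclamp_shaft = 0) {
  p <- .passive(config)
  e <- config$electrics
  gs <- if (length(g_spine) == 1) rep(g_spine, length(times)) else g_spine
  gd <- if (length(g_shaft) == 1) rep(g_shaft, length(times)) else g_shaft
  gsf <- approxfun(times, gs, rule = 2)
  gdf <- approxfun(times, gd, rule = 2)
  vcf <- if (is.null(vcmd_shaft)) function(t) e$e_leak
         else approxfun(times, vcmd_shaft, rule = 2)
  rhs <- function(t, y, parms) {
    vs <- y[1]; vd <- y[2]
    i_neck <- p$g_neck * (vs - vd)
    dvs <- -(p$gl_s * (vs - e$e_leak) + gsf(t) * (vs - e$e_syn) + i_neck) / p$cm_s
    dvd <- -(p$gl_d * (vd - e$e_leak) + gdf(t) * (vd - e$e_syn) - i_neck +
               gclamp_shaft * (vd - vcf(t))) / p$cm_d
    list(c(dvs, dvd))
  }
  sol <- deSolve::lsoda(c(e$e_leak, e$e_leak), times, rhs, parms = NULL,
                        rtol = 1e-8, atol = 1e-8)
  out <- tibble::tibble(time = sol[, 1], v_spine = sol[, 2], v_shaft = sol[, 3])
  class(out) <- c("voltage_trace", class(out))
  attr(out, "epsp_spine") <- max(out$v_spine) - e$e_leak
  attr(out, "epsp_shaft") <- max(out$v_shaft) - e$e_leak
  out
}

# GHK single-channel Ca flux, ions/ms, positive inward (R-side mirror of the
# engine kernel; used for steady-state influx readouts and tests)
.ghk_flux <- function(p_cm3s, v, ca_in_uM, ca_out_mM, temp_c = 34) {
  rtf <- .rt_over_f(temp_c)
  u <- 2 * v / rtf
  ci <- ca_in_uM * 1e-9
  co <- ca_out_mM * 1e-6
  small <- abs(u) < 1e-6
  u_safe <- ifelse(small, 1e-6, u)
  num <- ci - co * exp(-u_safe)
  den <- 1 - exp(-u_safe)
  zF <- 2 * 96485.332
  iA <- p_cm3s * zF * u_safe * num / den
  -iA / (2 * 1.602176634e-19) * 1e-3
}

#' Resting calcium influx through a single NMDAR
#'
#' Combines the steady-state open fraction at clamped glutamate with the
#' Mg-block factor at the given potential and the unitary GHK calcium flux.
#'
#' @param subtype `"NR2A"` or `"NR2B"`.
#' @param glu clamped glutamate, uM.
#' @param v membrane potential, mV.
#' @param config a [spine_config()].
#' @return A tibble `subtype`, `glu`, `open`, `block`, `ions_per_s`.
#' @export
#' @examples
#' resting_nmdar_influx("NR2A", glu = 10)
resting_nmdar_influx <- function(subtype = c("NR2A", "NR2B"), glu = 10,
                                 v = NULL, config = spine_config()) {
  subtype <- match.arg(subtype)
  if (is.null(v)) v <- config$electrics$e_leak
  sc <- build_scheme(subtype, config)
  ss <- steady_state(sc, glu)
  blk <- mg_block_factor(v, config = config)
  phi <- .ghk_flux(config$receptors$p_ca_nmda, v, config$calcium$ca_rest,
                   config$calcium$ca_out, config$temperature)
  tibble::tibble(subtype = subtype, glu = glu, open = ss$open, block = blk,
                 ions_per_s = ss$open * blk * phi * 1e3)
}
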