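#' Default model configuration
#'
#' Builds the full parameter configuration of the spine model: geometry,
#' temperature/Q10 context, glutamate-field parameters, receptor kinetic
#' schemes and counts, membrane electrics, calcium handling and the CaMKII
#' cascade.  Every value can be overridden either through `...` using dotted
#' keys (e.g. `spine_config("glutamate.b_total" = 0)`) or by editing the
#' returned nested list.
#'
#' Kinetic rate constants are stored at their reference temperatures and are
#' scaled to `temperature` with the per-process Q10 classes (see
#' [q10_adjust()]) when the simulation parameter set is assembled.
#'
#' Where a parameter has no published value in the main text of the source
#' literature, the default is a documented calibration choice (see the
#' methods vignette); all such values live here and nowhere else.
#'
#' @param ... dotted-key overrides, e.g. `"receptors.counts.s_nr2a" = 6`.
#' @param temperature simulation temperature, degrees Celsius.
#' @return A nested list of class `spine_config`.
#' @export
#' @examples
#' cfg <- spine_config()
#' cfg$geometry$head_volume
#' cfg2 <- spine_config("glutamate.b_total" = 0)
spine_config <- function(..., temperature = 34) {
  cfg <- list(
    temperature = temperature,
    q10 = list(
      # class = c(q10, reference temperature degC)
      diffusion             = c(1.3, 25),
      nmdar_kinetics        = c(3.0, 23),
      ampar_kinetics        = c(2.4, 23),
      vdcc_kinetics         = c(3.0, 23),
      pump_kinetics         = c(3.0, 34),
      buffer_kinetics       = c(2.15, 34),
      transporter_kinetics  = c(3.0, 23),
      nmdar_conductance     = c(1.6, 24),
      ampar_conductance     = c(1.5, 24),
      vdcc_conductance      = c(1.5, 24),
      none                  = c(1.0, 34)
    ),
    geometry = list(
      head_volume = 0.1,          # um^3
      cleft_height = 0.02,        # um
      psd_outer_radius = 0.150,   # um
      perisynaptic_outer_radius = 0.365, # um
      psd_volume_fraction = 0.1,
      neck_length = 0.5,          # um
      neck_radius = 0.1,          # um
      shaft_radius = 0.5,         # um
      shaft_length = 1.0          # um
    ),
    glutamate = list(
      d_glu = 0.4,                # um^2/ms at reference temperature (diffusion class)
      lambda = 1.4,               # tortuosity
      alpha = 0.15,               # extracellular volume fraction beyond the cleft
      b_total = 0.5,              # mM transporter concentration
      k_on_transporter = 10,      # /mM/ms at reference temperature
      glu_rest = 0.25,            # uM resting extrasynaptic level
      molecules_per_vesicle = 1500,
      r_synaptic = 0.075,         # um, mid-PSD sampling radius
      r_perisynaptic = 0.315,     # um, outer perisynaptic annulus
      r_extrasynaptic = NULL,     # um; NULL = cleft radius + head radius + neck length
      pde_n_cells = 600,
      pde_r_max = 5,              # um
      impulse_window = 80         # ms of impulse response retained for superposition
    ),
    receptors = list(
      counts = list(s_nr2a = 12, s_nr2b = 8, p_nr2b = 3, e_nr2b = 8,
                    s_ampar = 85, e_ampar_density = 20),  # density per um^2
      desens_inhibition = list(s_nr2a = 0, s_nr2b = 0, p_nr2b = 0, e_nr2b = 0,
                               s_ampar = 0, e_ampar = 0),
      nr2a = .nr2a_rates(),
      nr2b = .nr2b_rates(),
      ampar = .ampar_rates(),
      g_nmda = 50,                # pS at reference temperature (nmdar_conductance)
      g_ampa = 9.5,               # pS at reference temperature (ampar_conductance)
      p_ca_nmda = 2.5606e-14,     # cm^3/s at 34 C; calibrated to resting influx
      ca_fraction_note = "Ca flux carried by GHK permeability; ~10% of total current"
    ),
    electrics = list(
      cm = 1.0,                   # uF/cm^2
      r_neck = 157,               # MOhm
      e_leak = -70,               # mV
      e_syn = 0,                  # mV, AMPAR/NMDAR reversal
      g_leak_spine = 0.05,        # nS
      g_leak_shaft = 0.5,         # nS (local input conductance of the shaft node)
      c_shaft_load = 10,          # pF effective capacitive load of the adjacent dendrite
      mg = 1.0,                   # mM external Mg
      mg_k0 = 3.57,               # mM, Jahr-Stevens
      mg_slope = 0.062,           # /mV
      vdcc = list(
        density_spine = 3.0,      # channels per um^2 (MCMC-calibrated class)
        density_shaft = 6.0,
        vh = -10,  k = 6,         # activation V1/2 (mV), slope (mV)
        tau = 1.0,                # ms at reference temperature (vdcc_kinetics)
        p_ca = 5.0e-14            # cm^3/s per channel at 34 C
      ),
      bap = list(amplitude = 100, tau_rise = 0.3, tau_decay = 1.2,  # mV, ms
                 g_clamp = 200),  # nS drive conductance on the shaft
      pairing_v = -20,            # mV pairing depolarisation command
      pairing_g = 200             # nS clamp strength during pairing
    ),
    calcium = list(
      ca_rest = 0.075,            # uM
      ca_out = 2.0,               # mM
      d_ca = 0.15,                # um^2/ms effective free-Ca diffusion
      pmca = list(density_spine = 200, density_shaft = 300,  # pumps/um^2
                  turnover = 0.05, km = 0.4),                # ions/ms per pump, uM
      ncx = list(density_spine = 4, density_shaft = 2,       # fast low-affinity exchanger
                 turnover = 2, km = 20),
      buffer = list(btot_spine = 60, kon_spine = 0.1, koff_spine = 0.3,
                    btot_dend = 40, kon_dend = 0.1, koff_dend = 0.3)
      # btot uM, kon /uM/ms, koff /ms at reference temperature (buffer class)
    ),
    camkii = .camkii_defaults(),
    protocol = list(lfs_hz = 10, hfs_hz = 100, train_s = 1,
                    tail_ms = 300, dt = 0.01, stride = 10)
  )
  class(cfg) <- c("spine_config", "list")
  overrides <- list(...)
  if (length(overrides)) {
    for (k in names(overrides)) cfg <- config_set(cfg, k, overrides[[k]])
  }
  cfg
}

#' Set a configuration value by dotted key
#'
#' @param config a [spine_config()] object.
#' @param key dotted path, e.g. `"calcium.pmca.density_spine"`.
#' @param value replacement value.
#' @return The modified configuration.
#' @export
config_set <- function(config, key, value) {
  path <- strsplit(key, ".", fixed = TRUE)[[1]]
  # validate that the parent path exists (a new leaf may be created)
  ref <- config
  for (p in path[-length(path)]) {
    if (is.null(ref[[p]])) stop("unknown config section: ", p, call. = FALSE)
    ref <- ref[[p]]
  }
  config[[path]] <- value
  config
}

#' Read a configuration value by dotted key
#' @param config a [spine_config()] object.
#' @param key dotted path.
#' @export
config_get <- function(config, key) {
  config[[strsplit(key, ".", fixed = TRUE)[[1]]]]
}

#' Load a configuration from a YAML file
#'
#' The file may contain any subset of the sections of [spine_config()]
#' (geometry, receptors, kinetics, electrics, calcium, glutamate, camkii,
#' protocol); values given there override the defaults.
#'
#' @param path YAML file path.
#' @return A `spine_config` object.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- spine_config()
  cfg2 <- utils::modifyList(cfg, user)
  class(cfg2) <- class(cfg)
  .validate_config(cfg2)
  cfg2
}

.validate_config <- function(cfg) {
  g <- cfg$geometry
  if (g$head_volume <= 0) stop("head_volume must be positive", call. = FALSE)
  if (!(g$psd_volume_fraction > 0 && g$psd_volume_fraction < 1))
    stop("psd_volume_fraction must lie in (0,1)", call. = FALSE)
  cnt <- cfg$receptors$counts
  if (any(unlist(cnt) < 0)) stop("receptor counts must be non-negative", call. = FALSE)
  glu <- cfg$glutamate
  if (glu$d_glu <= 0) stop("d_glu must be positive", call. = FALSE)
  if (glu$lambda < 1) stop("tortuosity lambda must be >= 1", call. = FALSE)
  if (glu$b_total < 0 || glu$glu_rest < 0)
    stop("glutamate concentrations must be non-negative", call. = FALSE)
  invisible(cfg)
}

#' Temperature scaling of a rate constant
#'
#' Scales a rate from its reference temperature to the target temperature
#' using the process Q10: `rate * q10^((temp - t_ref)/10)`.
#'
#' @param rate rate constant (any unit).
#' @param q10 Q10 coefficient (> 0).
#' @param temp target temperature, degrees C.
#' @param t_ref reference temperature, degrees C.
#' @export
#' @examples
#' q10_adjust(1, 3, 33, 23)   # one decade: x3
q10_adjust <- function(rate, q10, temp, t_ref) {
  stopifnot(q10 > 0)
  rate * q10^((temp - t_ref) / 10)
}

# scale factor for a named q10 class under a config
.q10_factor <- function(config, class) {
  q <- config$q10[[class]]
  if (is.null(q)) stop("unknown Q10 class: ", class, call. = FALSE)
  q[1]^((config$temperature - q[2]) / 10)
}
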