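# impulse-response cache: the radial PDE solution for one release is reused
# across pulses, protocols and design rows with identical field parameters
.glu_cache <- new.env(parent = emptyenv())

# Effective (temperature-scaled) glutamate field parameters
.glu_params <- function(config, b_total = NULL) {
  g <- config$glutamate
  geom <- .geom(config)
  d <- g$d_glu * .q10_factor(config, "diffusion")
  kon <- g$k_on_transporter * .q10_factor(config, "transporter_kinetics")
  bt <- if (is.null(b_total)) g$b_total else b_total
  r_extra <- g$r_extrasynaptic
  if (is.null(r_extra))
    r_extra <- geom$cleft_radius + geom$head_radius + geom$neck_length
  list(d_cleft = d, d_extra = d / g$lambda^2, k_up = kon * bt,
       r_cleft = geom$cleft_radius, h = geom$cleft_height, alpha = g$alpha,
       radii = c(g$r_synaptic, g$r_perisynaptic, r_extra),
       n_cells = g$pde_n_cells, r_max = g$pde_r_max, window = g$impulse_window)
}

# Single-release impulse response at the three zone radii on a uniform grid.
# Returns list(dt, conc [nt x 3]); conc[1,] corresponds to t = dt.
.glu_impulse <- function(config, molecules, b_total = NULL, dt = 0.0025) {
  p <- .glu_params(config, b_total)
  key <- paste(signif(c(molecules, p$d_cleft, p$d_extra, p$k_up, p$r_cleft,
                        p$h, p$alpha, p$radii, p$n_cells, p$r_max, p$window, dt), 10),
               collapse = "|")
  hit <- .glu_cache[[key]]
  if (!is.null(hit)) return(hit)
  tt <- seq(dt, p$window, by = dt)
  sol <- glu_pde_cpp(molecules, p$d_cleft, p$d_extra, p$k_up, p$r_cleft, p$h,
                     p$alpha, p$r_max, p$n_cells, tt, p$radii, FALSE)
  res <- list(dt = dt, conc = sol$conc)
  .glu_cache[[key]] <- res
  res
}

#' Glutamate concentration after one vesicular release
#'
#' Concentration at radial/path distance `r` and time `t` after an
#' instantaneous release of `molecules` glutamate molecules at the cleft
#' centre.  Inside the cleft the solution is a radial disc source in the
#' 20-nm slab; beyond the rim a hemispheric porous medium with effective
#' diffusivity `D/lambda^2` and first-order transporter uptake
#' `k_on * B_total`; the two regimes are joined conservatively at the rim
#' by a finite-volume solver.
#'
#' @param r distance(s) from the release site, um (all `r >= 0`).
#' @param t time(s) since release, ms (all `t >= 0`).
#' @param config a [spine_config()].
#' @param molecules released molecule count.
#' @param b_total transporter concentration (mM); default from config.
#' @return A tibble `time`, `r`, `conc` (uM) over the grid of `t` by `r`.
#' @export
impulse_response <- function(r, t, config = spine_config(),
                             molecules = config$glutamate$molecules_per_vesicle,
                             b_total = NULL) {
  if (any(t < 0) || any(r < 0))
    stop("times and distances must be non-negative", call. = FALSE)
  p <- .glu_params(config, b_total)
  tq <- sort(unique(pmax(t, 1e-4)))
  sol <- glu_pde_cpp(molecules, p$d_cleft, p$d_extra, p$k_up, p$r_cleft, p$h,
                     p$alpha, p$r_max, p$n_cells, tq, r, FALSE)
  conc <- sol$conc[match(pmax(t, 1e-4), tq), , drop = FALSE]
  conc[t == 0, ] <- 0
  out <- tidyr::crossing(r = r, time = t)
  out$conc <- as.vector(conc[cbind(match(out$time, t), match(out$r, r))])
  out[, c("time", "r", "conc")]
}

# zone traces on the engine half-grid; internal workhorse.
# pulses: release times (ms); astro: list(onset, duration, amplitude_mM) or NULL
.zone_traces <- function(config, duration, dt_half,
                         pulses = numeric(0),
                         molecules = config$glutamate$molecules_per_vesicle,
                         b_total = NULL, glu_rest = NULL, astro = NULL) {
  nt <- round(duration / dt_half) + 1L
  times <- (seq_len(nt) - 1L) * dt_half
  rest <- if (is.null(glu_rest)) config$glutamate$glu_rest else glu_rest
  tr <- matrix(0, nt, 3)
  if (length(pulses)) {
    imp <- .glu_impulse(config, molecules, b_total, dt = dt_half)
    ni <- nrow(imp$conc)
    for (tp in pulses) {
      i0 <- round(tp / dt_half) + 1L       # sample index of the release time
      span <- min(ni, nt - i0)             # impulse sample k -> time tp + k*dt
      if (span <= 0) next
      idx <- (i0 + 1L):(i0 + span)
      tr[idx, ] <- tr[idx, ] + imp$conc[seq_len(span), ]
    }
  }
  tr[, 2] <- tr[, 2] + rest
  tr[, 3] <- tr[, 3] + rest
  if (!is.null(astro)) {
    on <- times >= astro$onset & times < astro$onset + astro$duration
    tr[on, 3] <- tr[on, 3] + astro$amplitude_mM * 1e3
  }
  colnames(tr) <- c("synaptic", "perisynaptic", "extrasynaptic")
  list(times = times, conc = tr)
}

#' Glutamate time course at a zone for a pulse protocol
#'
#' Linear superposition of single-release impulse responses at the zone's
#' representative location, plus the resting extrasynaptic level at the
#' perisynaptic and extrasynaptic zones.
#'
#' @param pulse_times release times, ms (sorted, non-negative).
#' @param zone `"synaptic"`, `"perisynaptic"` or `"extrasynaptic"`.
#' @param config a [spine_config()].
#' @param duration trace length, ms.
#' @param molecules molecules per release.
#' @param b_total transporter concentration override, mM.
#' @param dt output sampling interval, ms.
#' @return A `glutamate_trace` tibble (`time`, `conc`, uM) with attributes
#'   `zone` and `peak`.
#' @export
#' @examples
#' tr <- trace_at_zone(0, "perisynaptic", duration = 20)
#' attr(tr, "peak")
trace_at_zone <- function(pulse_times, zone = c("synaptic", "perisynaptic",
                                                "extrasynaptic"),
                          config = spine_config(), duration = NULL,
                          molecules = config$glutamate$molecules_per_vesicle,
                          b_total = NULL, dt = 0.0025) {
  zone <- match.arg(zone)
  if (length(pulse_times) && (is.unsorted(pulse_times) || any(pulse_times < 0)))
    stop("pulse times must be sorted and non-negative", call. = FALSE)
  if (is.null(duration))
    duration <- if (length(pulse_times)) max(pulse_times) + 50 else 50
  z <- .zone_traces(config, duration, dt, pulses = pulse_times,
                    molecules = molecules, b_total = b_total)
  out <- tibble::tibble(time = z$times, conc = z$conc[, zone])
  class(out) <- c("glutamate_trace", class(out))
  attr(out, "zone") <- zone
  attr(out, "peak") <- max(out$conc)
  out
}

#' Extrasynaptic square glutamate pulse (astrocytic release)
#'
#' A brief square pulse of glutamate applied at the extrasynaptic site only;
#' synaptic and perisynaptic concentrations keep their resting values.
#'
#' @param duration pulse length, ms (> 0).
#' @param amplitude pulse amplitude, mM.
#' @param config a [spine_config()].
#' @param onset pulse onset, ms.
#' @param total_duration trace length, ms.
#' @return A `glutamate_trace` tibble for the extrasynaptic zone.
#' @export
astrocytic_pulse_trace <- function(duration, amplitude = 1,
                                   config = spine_config(), onset = 5,
                                   total_duration = onset + duration + 100) {
  stopifnot(duration > 0, amplitude >= 0)
  z <- .zone_traces(config, total_duration, 0.0025,
                    astro = list(onset = onset, duration = duration,
                                 amplitude_mM = amplitude))
  out <- tibble::tibble(time = z$times, conc = z$conc[, "extrasynaptic"])
  class(out) <- c("glutamate_trace", class(out))
  attr(out, "zone") <- "extrasynaptic"
  attr(out, "peak") <- max(out$conc)
  out
}

#' Peak glutamate per zone for a single release
#'
#' @param config a [spine_config()].
#' @param molecules molecules released.
#' @param b_total transporter concentration, mM (default from config).
#' @return tibble with `zone`, `peak` (uM, release-evoked component only).
#' @export
glu_peaks <- function(config = spine_config(),
                      molecules = config$glutamate$molecules_per_vesicle,
                      b_total = NULL) {
  imp <- .glu_impulse(config, molecules, b_total)
  tibble::tibble(zone = c("synaptic", "perisynaptic", "extrasynaptic"),
                 peak = apply(imp$conc, 2, max))
}
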