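# Default kinetic rate tables.
#
# Rates are stored at the reference temperature of their Q10 class
# (NMDAR/AMPAR kinetics: 23 C) in /ms, binding steps in /uM/ms.  The NMDAR
# topology is the standard subtype-specific eight-state scheme
#   U <-> G1 <-> G2 <-> {D1 slow desens, D2 fast desens, C1 <-> C2 <-> O}
# and the AMPAR the seven-state
#   U <-> G1 <-> G2 <-> O with desensitised D1 (from G1), D2 (from G2),
#   D3 (deep, from D2).
#
# The absolute magnitudes are in the literature range for the two NR2
# subtypes (NR2B: higher glutamate affinity, lower open probability, slower
# deactivation); the equilibrium constants of the gating and desensitisation
# branches are calibrated so that the steady-state dose-response reproduces
# the reported saturating open fractions (0.08 / 0.02) and desensitised
# plateau (0.81) of both subtypes -- see the methods vignette.

.nr2a_rates <- function() list(
  kon = 2.2e-3,   koff = 5.5e-3,
  kd1p = 13.5e-3, kd1m = 0.3333e-3, # slow desensitisation
  kd2p = 40.5e-3, kd2m = 1e-3,      # fast desensitisation
  ksp = 150e-3,   ksm = 37.5e-3,    # slow pre-open gating
  kfp = 1500e-3,  kfm = 1000e-3,    # fast pre-open gating
  kop = 2000e-3,  kom = 1500e-3     # opening
)

.nr2b_rates <- function() list(
  kon = 2.2e-3,   koff = 1.32e-3,
  kd1p = 6.75e-3,  kd1m = 0.1667e-3,
  kd2p = 20.25e-3, kd2m = 0.5e-3,
  ksp = 90e-3,    ksm = 15e-3,
  kfp = 500e-3,   kfm = 300e-3,
  kop = 200e-3,   kom = 1000e-3
)

.ampar_rates <- function() list(
  kon = 2e-3,    koff = 1.5,       # low affinity: Kd = 750 uM
  beta = 2.3,    alpha = 1.15,     # opening / closing
  kd1p = 0.038,  kd1m = 0.019,     # desens from singly bound
  kd2p = 0.8,    kd2m = 0.038,     # desens from doubly bound
  kd3p = 0.019,  kd3m = 0.064      # deep desensitisation
)

.scheme_transitions <- function(subtype, r) {
  if (subtype %in% c("NR2A", "NR2B")) {
    data.frame(
      from = c("U",  "G1", "G1", "G2", "G2", "D1", "G2", "D2", "G2", "C1", "C1", "C2", "C2", "O"),
      to   = c("G1", "U",  "G2", "G1", "D1", "G2", "D2", "G2", "C1", "G2", "C2", "C1", "O",  "C2"),
      rate = c(2 * r$kon, r$koff, r$kon, 2 * r$koff, r$kd1p, r$kd1m, r$kd2p,
               r$kd2m, r$ksp, r$ksm, r$kfp, r$kfm, r$kop, r$kom),
      glu_order = c(1, 0, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
      desens = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE,
                 FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)
    )
  } else {
    data.frame(
      from = c("U",  "G1", "G1", "G2", "G2", "O", "G1", "D1", "G2", "D2", "D2", "D3"),
      to   = c("G1", "U",  "G2", "G1", "O",  "G2", "D1", "G1", "D2", "G2", "D3", "D2"),
      rate = c(2 * r$kon, r$koff, r$kon, 2 * r$koff, r$beta, r$alpha,
               r$kd1p, r$kd1m, r$kd2p, r$kd2m, r$kd3p, r$kd3m),
      glu_order = c(1, 0, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0),
      desens = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE,
                 TRUE, FALSE, FALSE, FALSE)
    )
  }
}

#' Build a receptor kinetic scheme
#'
#' Assembles the validated kinetic scheme for one receptor subtype with all
#' rates Q10-scaled to the configuration temperature.  NMDAR subtypes have
#' eight states (unbound, two bound, slow and fast desensitised, two
#' pre-open intermediates, open); the AMPAR has seven (three closed binding
#' states, open, three desensitised).  Desensitisation inhibition multiplies
#' the desensitisation entry rates by `1 - desens_inhibition`.
#'
#' @param subtype `"NR2A"`, `"NR2B"` or `"AMPAR"`.
#' @param config a [spine_config()].
#' @param desens_inhibition fraction in \[0, 1\].
#' @return A `kinetic_scheme` object: state names, designated open /
#'   desensitised / unbound states, transition table (rates at simulation
#'   temperature) and the `Q0`/`Q1` generator decomposition with the
#'   glutamate-dependent generator `Q(glu) = Q0 + glu * Q1`.
#' @export
#' @examples
#' sc <- build_scheme("NR2A", spine_config())
#' length(sc$states)
build_scheme <- function(subtype = c("NR2A", "NR2B", "AMPAR"),
                         config = spine_config(),
                         desens_inhibition = 0) {
  subtype <- match.arg(subtype)
  stopifnot(desens_inhibition >= 0, desens_inhibition <= 1)
  key <- switch(subtype, NR2A = "nr2a", NR2B = "nr2b", AMPAR = "ampar")
  r <- config$receptors[[key]]
  needed <- if (subtype == "AMPAR")
    c("kon", "koff", "beta", "alpha", "kd1p", "kd1m", "kd2p", "kd2m", "kd3p", "kd3m")
  else
    c("kon", "koff", "kd1p", "kd1m", "kd2p", "kd2m", "ksp", "ksm", "kfp", "kfm", "kop", "kom")
  miss <- setdiff(needed, names(r))
  if (length(miss))
    stop("missing rate constant(s) for ", subtype, ": ",
         paste0("receptors.", key, ".", miss, collapse = ", "), call. = FALSE)

  q10_class <- if (subtype == "AMPAR") "ampar_kinetics" else "nmdar_kinetics"
  fac <- .q10_factor(config, q10_class)
  tr <- .scheme_transitions(subtype, r)
  tr$rate <- tr$rate * fac
  tr$rate[tr$desens] <- tr$rate[tr$desens] * (1 - desens_inhibition)

  states <- if (subtype == "AMPAR") c("U", "G1", "G2", "O", "D1", "D2", "D3")
            else c("U", "G1", "G2", "D1", "D2", "C1", "C2", "O")
  n <- length(states)
  Q0 <- matrix(0, n, n, dimnames = list(states, states))
  Q1 <- Q0
  for (i in seq_len(nrow(tr))) {
    a <- tr$from[i]; b <- tr$to[i]
    if (tr$glu_order[i] == 1) Q1[a, b] <- Q1[a, b] + tr$rate[i]
    else Q0[a, b] <- Q0[a, b] + tr$rate[i]
  }

  g_key <- if (subtype == "AMPAR") "g_ampa" else "g_nmda"
  g_class <- if (subtype == "AMPAR") "ampar_conductance" else "nmdar_conductance"
  structure(list(
    subtype = subtype,
    states = states,
    open_state = "O",
    desens_states = if (subtype == "AMPAR") c("D1", "D2", "D3") else c("D1", "D2"),
    unbound_state = "U",
    transitions = tibble::as_tibble(tr),
    Q0 = Q0, Q1 = Q1,
    conductance = config$receptors[[g_key]] * .q10_factor(config, g_class),
    desens_inhibition = desens_inhibition
  ), class = "kinetic_scheme")
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("<kinetic_scheme> ", x$subtype, ": ", length(x$states), " states (",
      paste(x$states, collapse = " "), ")\n", sep = "")
  cat("  open:", x$open_state, " desensitised:",
      paste(x$desens_states, collapse = ","),
      " conductance:", signif(x$conductance, 4), "pS\n")
  invisible(x)
}

# generator matrix Q(glu): Q[i,j] = rate i->j, diagonal = -rowsum
.generator <- function(scheme, glu) {
  Q <- scheme$Q0 + glu * scheme$Q1
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

#' Steady-state occupancies at clamped glutamate
#'
#' Solves the null space of the scheme generator at a fixed glutamate
#' concentration, normalised to the occupancy simplex.
#'
#' @param scheme a [build_scheme()] object.
#' @param glu clamped glutamate concentration, uM (may be a vector).
#' @return A tibble with columns `glu`, one column per state, and
#'   `open`, `desensitised` summaries.
#' @export
#' @examples
#' steady_state(build_scheme("NR2A"), c(0, 1, 10, 100))
steady_state <- function(scheme, glu) {
  stopifnot(all(glu >= 0))
  rows <- lapply(glu, function(g) {
    Q <- .generator(scheme, g)
    n <- nrow(Q)
    M <- rbind(t(Q)[-n, , drop = FALSE], rep(1, n))
    p <- tryCatch(solve(M, c(rep(0, n - 1), 1)),
                  error = function(e) stop("degenerate generator at glu = ", g,
                                           ": ", conditionMessage(e), call. = FALSE))
    p[abs(p) < 1e-15] <- 0
    p
  })
  occ <- do.call(rbind, rows)
  colnames(occ) <- scheme$states
  out <- tibble::as_tibble(occ)
  out$glu <- glu
  out$open <- unname(occ[, scheme$open_state])
  out$desensitised <- unname(rowSums(occ[, scheme$desens_states, drop = FALSE]))
  dplyr::relocate(out, "glu")
}

#' Integrate a kinetic scheme against a glutamate time course
#'
#' Deterministic state-fraction ODEs driven by a (piecewise-linear)
#' glutamate trace, solved with a stiff integrator.  The initial condition
#' is the steady state at the trace's initial concentration (the receptor's
#' resting zone glutamate).
#'
#' @param scheme a [build_scheme()] object.
#' @param times sample times of the driving trace, ms.
#' @param glu glutamate concentrations at `times`, uM.
#' @param out_times output times (defaults to `times`).
#' @param init optional initial occupancy vector.
#' @return A `state_trajectory` tibble: `time`, one column per state, plus
#'   `open` and `desensitised`.
#' @export
integrate_scheme <- function(scheme, times, glu, out_times = times, init = NULL) {
  stopifnot(length(times) == length(glu), !is.unsorted(times))
  if (min(out_times) < min(times) || max(out_times) > max(times) + 1e-9)
    stop("trace does not cover the requested output interval", call. = FALSE)
  gfun <- approxfun(times, glu, rule = 2)
  if (is.null(init)) {
    ss <- steady_state(scheme, gfun(times[1]))
    init <- as.numeric(ss[1, scheme$states])
  }
  n <- length(scheme$states)
  Q0t <- t(scheme$Q0); Q1t <- t(scheme$Q1)
  d0 <- -rowSums(scheme$Q0); d1 <- -rowSums(scheme$Q1)
  rhs <- function(t, y, p) {
    g <- gfun(t)
    list(as.vector(Q0t %*% y + g * (Q1t %*% y)) + (d0 + g * d1) * y)
  }
  sol <- deSolve::lsoda(init, out_times, rhs, parms = NULL,
                        rtol = 1e-8, atol = 1e-10)
  if (attr(sol, "istate")[1] < 0)
    stop("scheme integration failed at t = ", max(sol[, 1]), call. = FALSE)
  occ <- sol[, -1, drop = FALSE]
  colnames(occ) <- scheme$states
  out <- tibble::as_tibble(occ)
  out$time <- sol[, 1]
  out$open <- unname(occ[, scheme$open_state])
  out$desensitised <- unname(rowSums(occ[, scheme$desens_states, drop = FALSE]))
  out <- dplyr::relocate(out, "time")
  class(out) <- c("state_trajectory", class(out))
  attr(out, "scheme") <- scheme$subtype
  out
}

#' Per-state dwell-time and calcium-influx differences versus control
#'
#' Computes, per state, the additional time spent in the state relative to a
#' control trajectory (trapezoidal integral of the occupancy difference) and
#' optionally the additional calcium entry from per-receptor flux series.
#'
#' @param trajectory,control `state_trajectory` tibbles on identical time grids.
#' @param ca_flux,ca_flux_control optional instantaneous Ca influx series
#'   (ions/ms) matched to the same grid.
#' @return A tibble with `state`, `t_add` (ms) rows, plus an attribute-free
#'   `ca_add` row (`state = "ca_ions"`) when fluxes are supplied.
#' @export
metrics_vs_control <- function(trajectory, control,
                               ca_flux = NULL, ca_flux_control = NULL) {
  if (!isTRUE(all.equal(trajectory$time, control$time)))
    stop("trajectory and control are on different time grids", call. = FALSE)
  states <- setdiff(intersect(names(trajectory), names(control)),
                    c("time", "open", "desensitised"))
  tt <- trajectory$time
  trapz <- function(y) sum(diff(tt) * (head(y, -1) + tail(y, -1)) / 2)
  t_add <- vapply(states, function(s)
    trapz(trajectory[[s]] - control[[s]]), numeric(1))
  out <- tibble::tibble(state = states, t_add = unname(t_add))
  if (!is.null(ca_flux)) {
    stopifnot(length(ca_flux) == length(tt),
              length(ca_flux_control) == length(tt))
    out <- dplyr::bind_rows(out, tibble::tibble(
      state = "ca_ions", t_add = trapz(ca_flux - ca_flux_control)))
  }
  out
}
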