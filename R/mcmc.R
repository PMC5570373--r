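# The ten calibrated calcium-handling parameters, as dotted config keys.
# Buffer binding/unbinding rates are shared between spine and dendrite (one
# kinetic pair), giving 3 channel/pump densities x2 locations + 2 buffer
# totals + 2 shared buffer rates = 10.
.calib_params <- function() {
  tibble::tibble(
    name = c("vdcc_spine", "vdcc_shaft", "pmca_spine", "pmca_dend",
             "ncx_spine", "ncx_dend", "btot_spine", "btot_dend",
             "kon_buf", "koff_buf"),
    key = c("electrics.vdcc.density_spine", "electrics.vdcc.density_shaft",
            "calcium.pmca.density_spine", "calcium.pmca.density_shaft",
            "calcium.ncx.density_spine", "calcium.ncx.density_shaft",
            "calcium.buffer.btot_spine", "calcium.buffer.btot_dend",
            "calcium.buffer.kon_spine", "calcium.buffer.koff_spine")
  )
}

.apply_calib <- function(config, theta) {
  pr <- .calib_params()
  for (i in seq_len(nrow(pr)))
    config <- config_set(config, pr$key[i], theta[[pr$name[i]]])
  # shared buffer kinetics
  config <- config_set(config, "calcium.buffer.kon_dend", theta[["kon_buf"]])
  config <- config_set(config, "calcium.buffer.koff_dend", theta[["koff_buf"]])
  config
}

# decay time constant: first time after the peak at which the transient has
# fallen to 1/e of its amplitude (linear interpolation); deterministic and
# robust for the single-exponential-like bAP transients
.decay_tau <- function(times, x, rest) {
  ip <- which.max(x)
  amp <- x[ip] - rest
  if (amp <= 0) return(NA_real_)
  target <- rest + amp / exp(1)
  seg <- ip:length(x)
  below <- which(x[seg] <= target)
  if (!length(below)) return(NA_real_)
  i2 <- seg[below[1]]
  if (i2 == ip) return(0)
  i1 <- i2 - 1
  f <- (x[i1] - target) / (x[i1] - x[i2])
  times[i1] + f * (times[i2] - times[i1]) - times[ip]
}

#' bAP-evoked calcium transient features
#'
#' Simulates a single backpropagating action potential and extracts the
#' calibration features: transient amplitude above rest and 1/e decay time
#' constant, for the spine head and the dendritic shaft.
#'
#' @param config a [spine_config()].
#' @param duration_ms simulated time.
#' @param smooth_ms boxcar width (ms) applied before feature extraction,
#'   mimicking indicator equilibration.
#' @return tibble `feature`, `value` (amplitudes uM, taus ms) with the
#'   driving `spine_sim` attached as attribute `"sim"`.
#' @export
bap_features <- function(config = spine_config(), duration_ms = 150,
                         smooth_ms = 2) {
  sim <- run_simulation(make_bap_protocol(duration_ms = duration_ms),
                        config = config, keep_occupancies = FALSE)
  tr <- sim$traces
  rest <- config$calcium$ca_rest
  # short boxcar mimicking indicator equilibration; removes the sub-ms
  # free-Ca spike that precedes local buffer equilibration
  dt <- tr$time[2] - tr$time[1]
  w <- max(1L, round(smooth_ms / dt))
  smooth <- function(x) as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  cs <- smooth(tr$ca_spine); cd <- smooth(tr$ca_shaft)
  ok <- !is.na(cs)
  out <- tibble::tibble(
    feature = c("amp_spine", "tau_spine", "amp_dend", "tau_dend"),
    value = c(max(cs[ok]) - rest,
              .decay_tau(tr$time[ok], cs[ok], rest),
              max(cd[ok]) - rest,
              .decay_tau(tr$time[ok], cd[ok], rest))
  )
  attr(out, "sim") <- sim
  out
}

#' Synthetic calibration targets for the bAP transients
#'
#' Simulates the bAP protocol at a set of "true" parameters, extracts the
#' transient features and adds seeded Gaussian noise.  These synthetic
#' targets stand in for experimental bAP-evoked transient datasets, which
#' are not packaged.
#'
#' @param config the true-parameter configuration.
#' @param noise relative noise level (sd as a fraction of the feature value).
#' @param seed RNG seed.
#' @param path optional JSON output path.
#' @return A `calibration_target` tibble `feature`, `value`, `sd`, with the
#'   noiseless values as attribute `"truth"`.
#' @export
generate_fixture_targets <- function(config = spine_config(), noise = 0.05,
                                     seed = 1, path = NULL) {
  ft <- bap_features(config)
  set.seed(seed)
  sdv <- pmax(noise * abs(ft$value), 1e-12)
  out <- tibble::tibble(feature = ft$feature,
                        value = ft$value + rnorm(nrow(ft), 0, sdv),
                        sd = pmax(sdv, 0.05 * abs(ft$value), 1e-9))
  if (any(out$value <= 0)) out$value <- pmax(out$value, 1e-6)
  attr(out, "truth") <- ft$value
  class(out) <- c("calibration_target", class(out))
  if (!is.null(path))
    jsonlite::write_json(out, path, dataframe = "rows", digits = NA)
  out
}

#' Read calibration targets from JSON
#' @param path file written by [generate_fixture_targets()].
#' @export
read_targets <- function(path) {
  out <- tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  class(out) <- c("calibration_target", class(out))
  out
}

# Goodman-Weare affine-invariant ensemble sampler (stretch move).
# log_post: function(theta numeric vector) -> scalar
.ensemble_sampler <- function(log_post, init, n_steps, a = 2) {
  n_walk <- nrow(init); ndim <- ncol(init)
  pos <- init
  lp <- apply(pos, 1, log_post)
  chain <- array(NA_real_, c(n_steps, n_walk, ndim))
  lpchain <- matrix(NA_real_, n_steps, n_walk)
  n_accept <- 0
  for (s in seq_len(n_steps)) {
    for (w in seq_len(n_walk)) {
      other <- sample(setdiff(seq_len(n_walk), w), 1)
      z <- ((a - 1) * runif(1) + 1)^2 / a
      prop <- pos[other, ] + z * (pos[w, ] - pos[other, ])
      lp_prop <- log_post(prop)
      log_r <- (ndim - 1) * log(z) + lp_prop - lp[w]
      if (is.finite(lp_prop) && log(runif(1)) < log_r) {
        pos[w, ] <- prop
        lp[w] <- lp_prop
        n_accept <- n_accept + 1
      }
    }
    chain[s, , ] <- pos
    lpchain[s, ] <- lp
  }
  list(chain = chain, log_post = lpchain,
       acceptance = n_accept / (n_steps * n_walk))
}

# split-Rhat and a crude ESS on a steps x walkers matrix
.rhat <- function(m) {
  ns <- nrow(m) %/% 2
  halves <- cbind(m[seq_len(ns), , drop = FALSE],
                  m[ns + seq_len(ns), , drop = FALSE])
  w <- mean(apply(halves, 2, var))
  b <- ns * var(colMeans(halves))
  sqrt(((ns - 1) / ns * w + b / ns) / w)
}
.ess <- function(m) {
  v <- as.vector(m)
  n <- length(v)
  if (sd(v) == 0) return(n)
  rho <- acf(v, lag.max = min(100, n - 1), plot = FALSE)$acf[-1]
  cut <- which(rho < 0.05)[1]
  if (is.na(cut)) cut <- length(rho)
  n / (1 + 2 * sum(rho[seq_len(cut)]))
}

#' MCMC calibration of the calcium-handling parameters
#'
#' Samples the posterior of the ten uncertain parameters (VDCC, PMCA and
#' NCX densities and immobile-buffer concentration for spine and dendrite,
#' plus one shared buffer kinetic pair) under a Gaussian likelihood on the
#' bAP transient features, using an affine-invariant ensemble sampler in
#' log-parameter space with log-uniform priors spanning `prior_span`-fold
#' around the configuration defaults.
#'
#' @param targets a `calibration_target` tibble (see
#'   [generate_fixture_targets()]).
#' @param config base configuration (its values centre the priors).
#' @param n_steps ensemble steps.
#' @param n_walkers walkers (>= 2 x dimensions recommended).
#' @param seed RNG seed; runs are exactly reproducible for a fixed seed.
#' @param prior_span multiplicative half-width of the log-uniform priors.
#' @param burn fraction of initial steps discarded in summaries.
#' @param bap_ms bAP simulation length per likelihood evaluation.
#' @return A `posterior_sample`: draws tibble (post burn-in), full chain
#'   array, acceptance rate, and per-parameter posterior summaries with
#'   split-Rhat and effective sample size.
#' @export
mcmc_calibrate <- function(targets, config = spine_config(), n_steps = 80,
                           n_walkers = 20, seed = 1, prior_span = 10,
                           burn = 0.5, bap_ms = 150) {
  stopifnot(all(is.finite(targets$value)), all(targets$sd > 0))
  pr <- .calib_params()
  ndim <- nrow(pr)
  centre <- log(vapply(pr$key, function(k) config_get(config, k), numeric(1)))
  lo <- centre - log(prior_span)
  hi <- centre + log(prior_span)
  tv <- targets$value
  tsd <- targets$sd
  feat_order <- targets$feature

  log_post <- function(ltheta) {
    if (any(ltheta < lo | ltheta > hi)) return(-Inf)
    th <- setNames(as.list(exp(ltheta)), pr$name)
    ft <- tryCatch(bap_features(.apply_calib(config, th), duration_ms = bap_ms),
                   error = function(e) NULL)
    if (is.null(ft)) return(-Inf)
    mv <- ft$value[match(feat_order, ft$feature)]
    if (any(!is.finite(mv))) return(-Inf)
    -0.5 * sum(((mv - tv) / tsd)^2)
  }

  set.seed(seed)
  jitter_sd <- min(0.05, log(prior_span) / 4)
  init <- matrix(rep(centre, each = n_walkers), n_walkers, ndim) +
    matrix(rnorm(n_walkers * ndim, 0, jitter_sd), n_walkers, ndim)
  init <- pmin(pmax(init, matrix(rep(lo, each = n_walkers), n_walkers)),
               matrix(rep(hi, each = n_walkers), n_walkers))
  res <- .ensemble_sampler(log_post, init, n_steps)

  keep <- seq.int(floor(burn * n_steps) + 1, n_steps)
  draws_log <- res$chain[keep, , , drop = FALSE]
  flat <- matrix(draws_log, ncol = ndim)
  colnames(flat) <- pr$name
  draws <- tibble::as_tibble(exp(flat))

  summ <- tibble::tibble(
    parameter = pr$name,
    mean = colMeans(draws),
    median = apply(draws, 2, median),
    q2.5 = apply(draws, 2, quantile, 0.025),
    q97.5 = apply(draws, 2, quantile, 0.975),
    rhat = vapply(seq_len(ndim), function(d) .rhat(draws_log[, , d]), 0),
    ess = vapply(seq_len(ndim), function(d) .ess(draws_log[, , d]), 0)
  )
  structure(list(draws = draws, chain = res$chain, log_post = res$log_post,
                 acceptance = res$acceptance, summary = summ,
                 parameters = pr, seed = seed,
                 prior = tibble::tibble(parameter = pr$name,
                                        lo = exp(lo), hi = exp(hi))),
            class = "posterior_sample")
}

#' @export
print.posterior_sample <- function(x, ...) {
  cat("<posterior_sample> ", nrow(x$draws), " draws, acceptance ",
      round(x$acceptance, 3), "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @rdname mcmc_calibrate
#' @param truth named vector of true parameter values.
#' @param posterior a `posterior_sample`.
#' @return `coverage_check()`: tibble with `parameter`, `truth`, `covered`
#'   (inside the central 95% interval).
#' @export
coverage_check <- function(posterior, truth) {
  s <- posterior$summary
  tv <- unname(truth[s$parameter])
  tibble::tibble(parameter = s$parameter, truth = tv,
                 covered = tv >= s$q2.5 & tv <= s$q97.5)
}
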