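test_that("Mg block has the documented sigmoidal voltage dependence", {
  expect_equal(mg_block_factor(-70, mg = 0), 1)
  expect_equal(mg_block_factor(200, mg = 1), 1, tolerance = 1e-4)
  # closed form at -70 mV, 1 mM: 1 / (1 + exp(0.062*70)/3.57)
  expect_equal(mg_block_factor(-70, mg = 1),
               1 / (1 + exp(0.062 * 70) / 3.57), tolerance = 1e-12)
  v <- seq(-90, 40, by = 5)
  expect_true(all(diff(mg_block_factor(v, mg = 1)) > 0))
  expect_error(mg_block_factor(-70, mg = -1))
})

test_that("VDCC gate relaxes exponentially at clamped voltage", {
  cfg <- spine_config()
  g <- spinesim:::.vdcc_gate(cfg)
  vclamp <- -20
  tt <- seq(0, 5, by = 0.01)
  out <- vdcc_open_fraction(tt, rep(vclamp, length(tt)), cfg, m0 = 0)
  analytic <- g$minf(vclamp) * (1 - exp(-tt / g$tau))
  expect_equal(out$m, analytic, tolerance = 1e-6)
  expect_equal(out$open, out$m^2)
  # resting potential: essentially closed
  expect_lt(g$minf(-70)^2, 1e-8)
})

test_that("bAP waveform is a normalised AP-shaped depolarisation", {
  cfg <- spine_config()
  w <- bap_waveform(cfg, t = seq(0, 30, by = 0.005))
  expect_equal(min(w$v), cfg$electrics$e_leak)
  expect_equal(max(w$v) - cfg$electrics$e_leak, cfg$electrics$bap$amplitude,
               tolerance = 1e-3)
  expect_true(all(w$v[w$time <= 5] == cfg$electrics$e_leak))
})

test_that("passive circuit: no stimulus stays at rest; bAP attenuates into the spine", {
  cfg <- spine_config()
  tt <- seq(0, 50, by = 0.01)
  flat <- simulate_potential(tt, 0, 0, cfg)
  expect_equal(unique(round(flat$v_spine, 9)), cfg$electrics$e_leak)
  # spine peak cannot exceed shaft peak when driven through the passive neck
  sim <- run_simulation(make_bap_protocol(duration_ms = 60),
                        keep_occupancies = FALSE)
  expect_lte(max(sim$traces$v_spine), max(sim$traces$v_shaft) + 1e-6)
  expect_gt(max(sim$traces$v_shaft), 0)   # the commanded AP arrives
})

test_that("engine electrical solution matches an independent two-node integration", {
  # drive the shaft with the eAMPAR conductance recorded from an astro run and
  # compare the engine's shaft voltage against a full capacitive integration
  cfg <- spine_config()
  sim <- fx_astro()
  tr <- sim$traces
  geom <- attr(derive_geometry(cfg), "geometry")
  g_ampa <- cfg$receptors$g_ampa * spinesim:::.q10_factor(cfg, "ampar_conductance")
  n_eampar <- cfg$receptors$counts$e_ampar_density * geom$shaft_area
  g_shaft <- g_ampa * 1e-3 * n_eampar * tr$open_e_ampar   # nS
  ref <- simulate_potential(tr$time, g_spine = 0, g_shaft = g_shaft, cfg)
  el <- cfg$electrics$e_leak
  depol_ref <- max(ref$v_shaft) - el
  depol_engine <- max(tr$v_shaft) - el
  expect_lt(abs(depol_engine - depol_ref) / depol_ref, 0.1)
})

test_that("EPSP amplitude grows monotonically with synaptic AMPAR count", {
  peaks <- vapply(c(40, 85, 130), function(n) {
    p <- control_perturbation()
    p$counts$s_ampar <- n
    sim <- run_simulation(make_train(100, n_pulses = 1, tail_ms = 50), p,
                          keep_occupancies = FALSE)
    max(sim$traces$v_spine)
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})
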