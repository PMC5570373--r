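test_that("calmodulin loading conserves CaM and needs calcium", {
  cfg <- spine_config()
  tt <- seq(0, 2000, by = 1)
  zero <- cam_loading(tt, rep(0, length(tt)), cfg)
  expect_equal(max(zero$cam4), 0, tolerance = 1e-12)
  drive <- cam_loading(tt, rep(80, length(tt)), cfg)
  tot <- drive$cam0 + drive$cam2 + drive$cam4
  expect_equal(tot, rep(cfg$camkii$cam_total, length(tt)), tolerance = 1e-8)
  expect_gt(drive$cam4[length(tt)], 0)
})

test_that("clamped-calcium equilibrium matches the closed-form solution", {
  cfg <- spine_config()
  for (ca in c(30, 100, 250)) {
    tt <- seq(0, 5000, by = 5)
    run <- cam_loading(tt, rep(ca, length(tt)), cfg)
    expect_equal(run$cam4[length(tt)],
                 spinesim:::.cam_equilibrium(ca, cfg$camkii),
                 tolerance = 1e-5)
  }
})

test_that("cascade conserves CaMKII and respects the NR2B capacity limit", {
  tt <- seq(0, 1000, by = 1)
  ca <- rep(150, length(tt))   # strong clamped drive
  run <- camkii_transition(tt, ca, nr2b_count = 8, t_end = 6e4)
  tr <- run$traces
  tot <- tr$w_i + tr$w_b + tr$w_p + tr$w_psd + tr$w_n
  expect_equal(tot, rep(20, nrow(tr)), tolerance = 1e-6)
  expect_true(all(tr$w_n <= run$capacity + 1e-9))
  # no NR2B anchors: the complex is identically zero
  r0 <- camkii_transition(tt, ca, nr2b_count = 0, t_end = 6e4)
  expect_equal(max(r0$traces$w_n), 0, tolerance = 1e-12)
  expect_gt(run$outputs$value[run$outputs$output == "complex_final"], 0)
})

test_that("sub-threshold calcium leaves the cascade silent", {
  sim <- fx_1pulse()
  run <- camkii_transition(sim$traces$time, sim$traces$ca_spine,
                           nr2b_count = 8, t_end = 6e4)
  v <- setNames(run$outputs$value, run$outputs$output)
  expect_lt(v[["phospho_peak"]], 1e-3)
  expect_lt(v[["complex_final"]], 1e-3)
})

test_that("complex formation is non-monotone in the NR2A:NR2B ratio", {
  tab <- fx_get("ratio_tab", function()
    ratio_experiment(c(1, 6, 12, 15, 19), t_end = 3e5))
  expect_equal(tab$complex_norm[tab$nr2a == 12], 1)
  # blocked at and below 6:14
  expect_lt(tab$complex_norm[tab$nr2a == 6], 0.3)
  expect_lt(tab$complex_norm[tab$nr2a == 1], 0.1)
  # interior optimum: 15:5 beats both the control and the 19:1 extreme
  expect_gt(tab$complex_norm[tab$nr2a == 15], 1.2)
  expect_gt(tab$complex_norm[tab$nr2a == 15], tab$complex_norm[tab$nr2a == 19])
  expect_equal(attr(tab, "optimum"), 15)
  # spine calcium itself increases monotonically with the NR2A share
  expect_true(all(diff(tab$ca_peak_spine) > 0))
})

test_that("50% synaptic NR2A reduction blocks the downstream readouts", {
  ph <- make_train(100, duration_s = 1, pairing = TRUE)
  ctrl <- fx_get("camkii_ctrl", function() camkii_experiment(ph, t_end = 3e5))
  red <- control_perturbation()
  red$counts$s_nr2a <- 6    # NR2B count unchanged at 8
  halved <- camkii_experiment(ph, red, t_end = 3e5)
  v0 <- setNames(ctrl$outputs$value, ctrl$outputs$output)
  v1 <- setNames(halved$outputs$value, halved$outputs$output)
  expect_lt(v1[["complex_final"]] / v0[["complex_final"]], 0.3)
  expect_lt(v1[["phospho_peak"]] / v0[["phospho_peak"]], 0.5)
})
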