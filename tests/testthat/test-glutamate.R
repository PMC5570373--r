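test_that("impulse response is causal and conserves mass without uptake", {
  cfg <- spine_config()
  ir <- impulse_response(r = c(0.5, 1), t = c(0, 0.002), config = cfg)
  expect_equal(ir$conc[ir$time == 0], c(0, 0))
  # far from the source just after release: essentially nothing has arrived
  expect_lt(max(ir$conc[ir$time > 0 & ir$r == 1]), 1e-6)

  # explicit PDE call: molecule count in solution is conserved when B_total=0
  p <- spinesim:::.glu_params(cfg, b_total = 0)
  sol <- spinesim:::glu_pde_cpp(1500, p$d_cleft, p$d_extra, 0, p$r_cleft, p$h,
                                p$alpha, p$r_max, p$n_cells,
                                c(0.01, 0.1, 1, 10, 40), p$radii, FALSE)
  expect_equal(sol$mass, rep(1500, 5), tolerance = 1e-9)
})

test_that("zone peaks scale linearly with released molecules", {
  cfg <- spine_config()
  p1 <- glu_peaks(cfg, molecules = 1500)
  p2 <- glu_peaks(cfg, molecules = 3000)
  p3 <- glu_peaks(cfg, molecules = 7500)
  expect_equal(p2$peak / p1$peak, rep(2, 3), tolerance = 1e-9)
  expect_equal(p3$peak / p1$peak, rep(5, 3), tolerance = 1e-9)
  # strictly increasing in molecule count at every zone
  expect_true(all(p2$peak > p1$peak))
})

test_that("transporter removal spares the synaptic peak and raises the others", {
  cfg <- spine_config()
  with_tp <- glu_peaks(cfg)                  # B_total = 0.5 mM
  no_tp <- glu_peaks(cfg, b_total = 0)
  expect_lt(abs(no_tp$peak[1] - with_tp$peak[1]) / with_tp$peak[1], 0.01)
  expect_gt(no_tp$peak[2], with_tp$peak[2])
  expect_gt(no_tp$peak[3], with_tp$peak[3])
  # decay is slowed: late-time perisynaptic concentration is higher without uptake
  a <- trace_at_zone(0, "perisynaptic", cfg, duration = 20)
  b <- trace_at_zone(0, "perisynaptic", cfg, duration = 20, b_total = 0)
  late <- a$time > 5
  expect_true(all(b$conc[late] >= a$conc[late] - 1e-12))
})

test_that("peak concentrations converge under grid refinement", {
  cfg <- spine_config()
  coarse <- glu_peaks(cfg)
  fine <- glu_peaks(spine_config("glutamate.pde_n_cells" = 1200))
  rel <- abs(fine$peak - coarse$peak) / fine$peak
  expect_lt(max(rel[1:2]), 0.05)   # synaptic and perisynaptic peaks < 5%
})

test_that("resting level and superposition behave as documented", {
  cfg <- spine_config()
  # zero pulses: constant trace at the resting level of the zone
  tr <- trace_at_zone(numeric(0), "extrasynaptic", cfg, duration = 5)
  expect_equal(unique(tr$conc), cfg$glutamate$glu_rest)
  trs <- trace_at_zone(numeric(0), "synaptic", cfg, duration = 5)
  expect_equal(unique(trs$conc), 0)
  # two pulses: the trace equals the sum of shifted single-pulse traces
  one <- trace_at_zone(0, "perisynaptic", cfg, duration = 40)
  two <- trace_at_zone(c(0, 10), "perisynaptic", cfg, duration = 40)
  rest <- cfg$glutamate$glu_rest
  shift <- round(10 / (one$time[2] - one$time[1]))
  evoked <- one$conc - rest
  expected <- evoked
  idx <- (shift + 1):length(expected)
  expected[idx] <- expected[idx] + evoked[seq_len(length(expected) - shift)]
  expect_equal(two$conc, expected + rest, tolerance = 1e-10)
})

test_that("astrocytic pulses reach only the extrasynaptic site", {
  tr <- astrocytic_pulse_trace(20, amplitude = 1, onset = 5)
  expect_equal(attr(tr, "peak"), 1000 + spine_config()$glutamate$glu_rest)
  during <- tr$time >= 5 & tr$time < 25
  expect_true(all(tr$conc[during] > 999))
  expect_true(all(tr$conc[tr$time > 26] < 1))
  short <- astrocytic_pulse_trace(1e-3, amplitude = 1, onset = 5)
  # vanishing duration: at most a couple of grid samples are elevated
  expect_lt(sum(short$conc > 1), 3)
  expect_error(astrocytic_pulse_trace(0, 1))
})
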