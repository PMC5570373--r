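test_that("no stimulus leaves every trace at its resting value", {
  empty <- spinesim:::.new_protocol(numeric(0), 100, label = "rest")
  sim <- run_simulation(empty, keep_occupancies = FALSE)
  tr <- sim$traces
  rest <- sim$config$calcium$ca_rest
  expect_lt(max(abs(tr$ca_spine - rest)), 1e-4)
  expect_lt(max(abs(tr$ca_shaft - rest)), 1e-4)
  # tonic receptor conductances at the resting glutamate level shift the
  # resting potential by well under a tenth of a millivolt
  expect_lt(max(abs(tr$v_spine - (-70))), 0.12)
  s <- summarize_simulation(sim)
  expect_lt(s$value[s$output == "epsp_spine"], 0.12)
})

test_that("calcium bookkeeping: influx equals accumulation without pumps/buffers", {
  cfg <- spine_config(
    "calcium.pmca.density_spine" = 0, "calcium.pmca.density_shaft" = 0,
    "calcium.ncx.density_spine" = 0, "calcium.ncx.density_shaft" = 0,
    "calcium.buffer.btot_spine" = 0, "calcium.buffer.btot_dend" = 0)
  sim <- run_simulation(make_train(100, n_pulses = 5, tail_ms = 50),
                        config = cfg, keep_occupancies = FALSE)
  tr <- sim$traces
  vols <- sim$volumes
  last <- nrow(tr)
  rest <- cfg$calcium$ca_rest
  total_gain <- sum((c(tr$ca_psd[last], tr$ca_cyt[last], tr$ca_neck[last],
                       tr$ca_shaft[last]) - rest) * vols) * 602.2140857
  total_influx <- sum(sim$counters)
  expect_equal(total_gain, total_influx, tolerance = 5e-3)
})

test_that("simulation runs are deterministic", {
  p <- make_train(100, n_pulses = 2, tail_ms = 50)
  a <- run_simulation(p, keep_occupancies = FALSE)
  b <- run_simulation(p, keep_occupancies = FALSE)
  expect_identical(a$traces, b$traces)
  expect_identical(a$counters, b$counters)
})

test_that("engine receptor kinetics agree with the stiff reference integrator", {
  # drive one NR2A scheme with the synaptic glutamate of a 2-pulse protocol
  # in both the C++ engine (via run_simulation occupancies) and deSolve
  proto <- make_train(100, n_pulses = 2, tail_ms = 80)
  sim <- run_simulation(proto, keep_occupancies = TRUE)
  sc <- build_scheme("NR2A", sim$config)
  tr <- trace_at_zone(proto$pulses, "synaptic", sim$config,
                      duration = proto$duration)
  ref <- integrate_scheme(sc, tr$time, tr$conc, out_times = sim$traces$time)
  eng_open <- sim$occupancies[, "s_nr2a.O"]
  expect_equal(max(abs(eng_open - ref$O)), 0, tolerance = 2e-3)
  expect_lt(abs(max(eng_open) - max(ref$O)) / max(ref$O), 0.02)
})

test_that("summary outputs match independent scans of the stored traces", {
  sim <- fx_control_hfs()
  s <- summarize_simulation(sim)
  v <- setNames(s$value, s$output)
  w <- sim$volumes[1:2] / sum(sim$volumes[1:2])
  pooled <- sim$traces$ca_psd * w[1] + sim$traces$ca_cyt * w[2]
  expect_equal(unname(v["ca_peak_spine"]), max(pooled))
  expect_equal(unname(v["ca_peak_shaft"]), max(sim$traces$ca_shaft))
  expect_equal(unname(v["v_peak_spine"]), max(sim$traces$v_spine))
  # cumulative influx counters are non-decreasing by construction
  expect_true(all(s$value[1:4] >= 0))
})

test_that("receptor-class knockouts reproduce the documented asymmetry", {
  ctrl <- fx_control_hfs()
  peak0 <- max(ctrl$traces$ca_spine)
  no2b <- control_perturbation(); no2b$counts$s_nr2b <- 0
  s2b <- run_simulation(fx_hfs(), no2b, keep_occupancies = FALSE)
  drop2b <- peak0 - max(s2b$traces$ca_spine)
  no2a <- control_perturbation(); no2a$counts$s_nr2a <- 0
  s2a <- run_simulation(fx_hfs(), no2a, keep_occupancies = FALSE)
  drop2a <- peak0 - max(s2a$traces$ca_spine)
  # removing synaptic NR2B costs on the order of 1 uM, far less than NR2A
  expect_gt(drop2b, 0.2)
  expect_lt(drop2b, 1.6)
  expect_gt(drop2a, 2 * drop2b)
  # shaft peak under synaptic HFS is dominated by diffusion from the spine:
  # removing extrasynaptic NR2B changes it by < 10%
  noe <- control_perturbation(); noe$counts$e_nr2b <- 0
  se <- run_simulation(fx_hfs(), noe, keep_occupancies = FALSE)
  expect_lt(abs(max(se$traces$ca_shaft) - max(ctrl$traces$ca_shaft)) /
              max(ctrl$traces$ca_shaft), 0.1)
})

test_that("desensitisation inhibition of sNR2A raises the HFS peak monotonically", {
  peaks <- vapply(c(0, 0.5, 1), function(f) {
    p <- control_perturbation()
    p$desens_inhibition$s_nr2a <- f
    if (f == 0) return(max(fx_control_hfs()$traces$ca_spine))
    if (f == 1) return(max(fx_desinh_hfs()$traces$ca_spine))
    max(run_simulation(fx_hfs(), p, keep_occupancies = FALSE)$traces$ca_spine)
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
  # full inhibition sustains an elevated level through the train
  di <- fx_desinh_hfs()$traces
  late <- di$ca_spine[di$time > 800 & di$time < 1000]
  expect_gt(min(late), 0.5 * max(di$ca_spine))
})

test_that("receptor metrics between runs difference dwell times and influx", {
  ctrl <- fx_control_hfs()
  p <- control_perturbation(); p$molecules_per_release <- 5000
  hi <- run_simulation(fx_hfs(), p, keep_occupancies = TRUE)
  m <- sim_receptor_metrics(hi, ctrl)
  expect_true(all(c("class", "state", "t_add", "ca_add") %in% names(m)))
  # control against itself: identically zero
  m0 <- sim_receptor_metrics(ctrl, ctrl)
  expect_equal(max(abs(m0$t_add)), 0)
  # larger release: non-negative additional calcium through perisynaptic NR2B
  expect_gte(m$ca_add[m$class == "p_nr2b"][1], 0)
})

test_that("tidy/glance/autoplot provide the tabular and graphical views", {
  sim <- fx_1pulse()
  td <- tidy(sim)
  expect_true(all(c("time", "series", "value") %in% names(td)))
  expect_true("ca_spine" %in% unique(td$series))
  g <- glance(sim)
  expect_equal(nrow(g), 1)
  expect_true(all(c("ca_peak_spine", "epsp_spine", "protocol") %in% names(g)))
  pl <- autoplot(sim)
  expect_s3_class(pl, "ggplot")
})
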