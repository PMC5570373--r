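test_that("pulse trains have the right counts and spacing", {
  hfs <- make_train(100, duration_s = 1)
  expect_length(hfs$pulses, 100)
  expect_equal(unique(diff(hfs$pulses)), 10)
  lfs <- make_train(10, duration_s = 1)
  expect_length(lfs$pulses, 10)
  expect_equal(unique(diff(lfs$pulses)), 100)
  one <- make_train(100, n_pulses = 1)
  expect_equal(one$pulses, 0)
  pair <- make_train(100, duration_s = 1, pairing = TRUE)
  expect_false(is.null(pair$pairing))
  expect_gte(pair$pairing$offset, max(pair$pulses))
  expect_error(make_train(0, n_pulses = 1))
})

test_that("theta-burst composition: 4 pulses @100 Hz, 10 bursts @5 Hz", {
  tbs1 <- make_tbs(1)
  expect_length(tbs1$pulses, 40)
  # burst onsets within a train are 200 ms apart
  onsets <- tbs1$pulses[seq(1, 40, by = 4)]
  expect_equal(unique(diff(onsets)), 200)
  expect_equal(tbs1$pulses[1:4], c(0, 10, 20, 30))
  tbs4 <- make_tbs(4)
  expect_length(tbs4$pulses, 160)
  expect_false(is.unsorted(tbs4$pulses))
})

test_that("control perturbation encodes the standard condition", {
  p <- control_perturbation()
  expect_equal(p$molecules_per_release, 1500)
  expect_equal(p$b_total_scale, 1)
  expect_equal(p$glu_rest, 0.25)
  expect_equal(unlist(p$counts),
               c(s_nr2a = 12, s_nr2b = 8, p_nr2b = 3, e_nr2b = 8,
                 s_ampar = 85, e_ampar_density = 20))
  expect_equal(p$counts$s_nr2a + p$counts$s_nr2b, 20)
  expect_true(all(unlist(p$desens_inhibition) == 0))
  expect_identical(control_perturbation(), control_perturbation())
})

test_that("sweeps build one perturbation per value with others at control", {
  s <- sweep_perturbations("G0", c(500, 1500, 5000, 10000))
  expect_length(s, 4)
  expect_equal(vapply(s, function(x) x$molecules_per_release, 1),
               c(500, 1500, 5000, 10000))
  expect_equal(s[[1]]$glu_rest, 0.25)
  expect_length(sweep_perturbations("Ds2A", numeric(0)), 0)
  expect_error(sweep_perturbations("bogus", 1), "unknown")
  # TP is specified in mM and maps onto the B_total scale
  tp <- sweep_perturbations("TP", c(0, 0.25, 0.5))
  expect_equal(vapply(tp, function(x) x$b_total_scale, 1), c(0, 0.5, 1))
})

test_that("ratio perturbations conserve the PSD total of 20", {
  p <- ratio_perturbation(15, 5)
  expect_equal(p$counts$s_nr2a, 15)
  expect_equal(p$counts$s_nr2b, 5)
  expect_error(ratio_perturbation(15, 6), "20")
})
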