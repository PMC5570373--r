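test_that("scheme construction validates topology and rates", {
  a <- build_scheme("NR2A")
  b <- build_scheme("NR2B")
  m <- build_scheme("AMPAR")
  expect_length(a$states, 8)
  expect_length(b$states, 8)
  expect_length(m$states, 7)
  # generator rows sum to zero by construction
  for (sc in list(a, b, m)) {
    Q <- spinesim:::.generator(sc, 10)
    expect_equal(rowSums(Q), setNames(rep(0, nrow(Q)), rownames(Q)),
                 tolerance = 1e-12)
    # only binding steps carry glutamate dependence
    expect_true(all(sc$transitions$glu_order[sc$transitions$rate > 0] %in% c(0, 1)))
  }
  # NR2A and NR2B differ in binding and desensitisation rates
  expect_false(isTRUE(all.equal(a$Q0, b$Q0)))
  # a missing rate constant is reported by key
  cfg <- spine_config()
  cfg$receptors$nr2a$kop <- NULL
  expect_error(build_scheme("NR2A", cfg), "receptors.nr2a.kop")
})

test_that("steady state solves the generator null space", {
  a <- build_scheme("NR2A")
  # no glutamate: everything unbound
  ss0 <- steady_state(a, 0)
  expect_equal(ss0$U, 1)
  expect_equal(ss0$open, 0)
  # occupancies form a simplex at every concentration
  ss <- steady_state(a, c(0.01, 0.1, 1, 10, 100))
  occ <- as.matrix(ss[, a$states])
  expect_true(all(occ >= -1e-12))
  expect_equal(rowSums(occ), rep(1, 5), tolerance = 1e-10)
  # open and desensitised fractions increase monotonically with glutamate
  expect_true(all(diff(ss$open) > 0))
  expect_true(all(diff(ss$desensitised) > 0))
})

test_that("null-space solution matches long-time ODE integration", {
  for (subtype in c("NR2A", "AMPAR")) {
    sc <- build_scheme(subtype)
    glu <- 5
    ss <- as.numeric(steady_state(sc, glu)[1, sc$states])
    # integrate 10 s from a different start
    n <- length(sc$states)
    init <- rep(1 / n, n)
    traj <- integrate_scheme(sc, times = c(0, 1e4), glu = c(glu, glu),
                             out_times = c(0, 1e4), init = init)
    final <- as.numeric(traj[nrow(traj), sc$states])
    expect_equal(final, ss, tolerance = 1e-6)
  }
})

test_that("trajectories preserve the occupancy simplex under pulsed drive", {
  sc <- build_scheme("NR2A")
  tr <- trace_at_zone(c(0, 10, 20, 30), "synaptic", duration = 80)
  traj <- integrate_scheme(sc, tr$time, tr$conc,
                           out_times = seq(0, 80, by = 0.5))
  occ <- as.matrix(traj[, sc$states])
  expect_true(all(occ > -1e-8 & occ < 1 + 1e-8))
  expect_equal(rowSums(occ), rep(1, nrow(occ)), tolerance = 1e-8)
  # constant glutamate drive converges to the clamped steady state
  traj2 <- integrate_scheme(sc, times = c(0, 5e3), glu = c(20, 20),
                            out_times = c(0, 5e3))
  expect_equal(as.numeric(traj2[2, sc$states]),
               as.numeric(steady_state(sc, 20)[1, sc$states]),
               tolerance = 1e-6)
})

test_that("desensitisation inhibition scales only the entry rates", {
  full <- build_scheme("NR2A", desens_inhibition = 1)
  half <- build_scheme("NR2A", desens_inhibition = 0.5)
  base <- build_scheme("NR2A")
  din <- base$transitions$desens
  expect_equal(full$transitions$rate[din], rep(0, sum(din)))
  expect_equal(half$transitions$rate[din], base$transitions$rate[din] / 2)
  expect_equal(half$transitions$rate[!din], base$transitions$rate[!din])
  # with desensitisation removed the saturating open fraction rises ~5x
  expect_gt(steady_state(full, 100)$open / steady_state(base, 100)$open, 4)
  expect_error(build_scheme("NR2A", desens_inhibition = 1.5))
})

test_that("dwell-time metrics difference a run against its control", {
  sc <- build_scheme("NR2B")
  tr <- trace_at_zone(0, "perisynaptic", duration = 50)
  traj <- integrate_scheme(sc, tr$time, tr$conc, out_times = seq(0, 50, 0.1))
  m0 <- metrics_vs_control(traj, traj)
  expect_equal(m0$t_add, rep(0, nrow(m0)))
  # doubled release: non-negative extra open time
  tr2 <- trace_at_zone(0, "perisynaptic", duration = 50, molecules = 3000)
  traj2 <- integrate_scheme(sc, tr2$time, tr2$conc, out_times = seq(0, 50, 0.1))
  m <- metrics_vs_control(traj2, traj)
  expect_gt(m$t_add[m$state == "O"], 0)
  # trapezoid integral at halved step agrees to < 0.1%
  fine <- integrate_scheme(sc, tr2$time, tr2$conc, out_times = seq(0, 50, 0.05))
  finec <- integrate_scheme(sc, tr$time, tr$conc, out_times = seq(0, 50, 0.05))
  mf <- metrics_vs_control(fine, finec)
  o <- m$t_add[m$state == "O"]
  of <- mf$t_add[mf$state == "O"]
  expect_lt(abs(o - of) / abs(of), 1e-3)
  expect_error(metrics_vs_control(traj, fine), "time grids")
})
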