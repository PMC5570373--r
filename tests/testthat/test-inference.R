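test_that("Latin hypercube designs are stratified, bounded and reproducible", {
  n <- 20
  d <- lhs_design(n, seed = 42)
  rg <- sensitivity_ranges()
  expect_equal(dim(d), c(n, 15))
  for (j in seq_len(ncol(d))) {
    lo <- rg$min[j]; hi <- rg$max[j]
    expect_true(all(d[[j]] >= lo - 1e-9 & d[[j]] <= hi + 1e-9))
    if (!rg$integer[j]) {
      # exactly one sample per equal-probability bin
      bins <- floor((d[[j]] - lo) / (hi - lo) * n)
      bins[bins == n] <- n - 1
      expect_equal(sort(bins), 0:(n - 1))
    }
  }
  expect_equal(lhs_design(n, seed = 42), d)
  expect_false(isTRUE(all.equal(lhs_design(n, seed = 43), d)))
  expect_error(lhs_design(1), "n >= 2")
  expect_true(all(d$G0 >= 500 & d$G0 <= 10000))
})

test_that("PRCC isolates the driving factor in a constructed problem", {
  set.seed(1)
  n <- 120
  x <- lhs_design(n, seed = 5)
  y <- exp(x$G0 / 4000) + rnorm(n, 0, 0.01)      # monotone in G0 only
  pr <- prcc(x, y)
  g0 <- pr$prcc[pr$factor == "G0"]
  expect_gt(g0, 0.95)
  expect_lt(max(abs(pr$prcc[pr$factor != "G0"])), 0.4)
  expect_true(pr$significant[pr$factor == "G0"])
  # invariance under strictly monotone transforms of factors and outputs
  x2 <- x; x2$G0 <- log(x2$G0)
  pr2 <- prcc(x2, y^3)
  expect_equal(pr2$prcc, pr$prcc, tolerance = 1e-12)
})

test_that("PRCC equals brute-force partial correlation of rank residuals", {
  set.seed(7)
  n <- 60
  x <- as.data.frame(matrix(runif(n * 4), n, 4))
  names(x) <- paste0("f", 1:4)
  y <- x$f1^2 - 2 * x$f3 + rnorm(n, 0, 0.2)
  pr <- prcc(x, y)
  rx <- apply(as.matrix(x), 2, rank)
  ry <- rank(y)
  for (j in 1:4) {
    others <- rx[, -j, drop = FALSE]
    res_x <- residuals(lm(rx[, j] ~ others))
    res_y <- residuals(lm(ry ~ others))
    expect_equal(pr$prcc[pr$factor == paste0("f", j)],
                 cor(res_x, res_y), tolerance = 1e-10)
  }
  # p-values use the t approximation with df = n - 2 - (k - 1)
  r1 <- pr$prcc[1]
  df <- n - 2 - 3
  expect_equal(pr$p[1], 2 * pt(-abs(r1 * sqrt(df / (1 - r1^2))), df),
               tolerance = 1e-12)
})

test_that("PRCC flags degenerate inputs", {
  x <- as.data.frame(matrix(runif(40), 20, 2)); names(x) <- c("a", "b")
  pr <- prcc(x, rep(1, 20))
  expect_true(all(is.na(pr$prcc)))
  expect_false(any(pr$significant))
  x$b <- x$a
  expect_error(prcc(x, runif(20)), "collinear")
})

test_that("ensemble sampler: seeded runs reproduce; tight priors stay put", {
  targ <- fx_get("bap_targets", function()
    generate_fixture_targets(noise = 0.05, seed = 11))
  a <- mcmc_calibrate(targ, n_steps = 6, n_walkers = 12, seed = 5)
  b <- mcmc_calibrate(targ, n_steps = 6, n_walkers = 12, seed = 5)
  expect_equal(a$draws, b$draws)
  expect_equal(a$acceptance, b$acceptance)
  # near-zero prior width: the posterior collapses onto the default point
  c0 <- mcmc_calibrate(targ, n_steps = 4, n_walkers = 12, seed = 5,
                       prior_span = 1.0001)
  spread <- apply(c0$draws, 2, function(v) diff(range(v)) / median(v))
  expect_lt(max(spread), 5e-4)
})

test_that("synthetic bAP targets: zero noise reproduces the model features", {
  ft <- bap_features()
  targ0 <- generate_fixture_targets(noise = 0, seed = 3)
  expect_equal(targ0$value, ft$value, tolerance = 1e-10)
  expect_equal(attr(targ0, "truth"), ft$value)
  # JSON round trip
  path <- tempfile(fileext = ".json")
  generate_fixture_targets(noise = 0.05, seed = 3, path = path)
  rt <- read_targets(path)
  expect_equal(rt$feature, ft$feature)
  expect_true(all(rt$sd > 0))
})

test_that("sensitivity experiment wires the simulator to PRCC", {
  se <- fx_get("sens_smoke", function()
    sensitivity_experiment("lfs", n = 24, seed = 2))
  expect_s3_class(se$prcc, "sensitivity_result")
  expect_true(all(abs(se$prcc$prcc) <= 1, na.rm = TRUE))
  expect_equal(se$n_used, 24)
  expect_equal(nrow(se$outputs), 24)
  tab <- prcc_table(se)
  expect_equal(nrow(tab), 15)
  expect_s3_class(autoplot(se), "ggplot")
})
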