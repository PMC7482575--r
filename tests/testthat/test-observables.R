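test_that("polarization matches hand-computed configurations", {
  expect_equal(polarization(rep(1.3, 7)), 1, tolerance = 1e-14)
  expect_equal(polarization(c(0, 2 * pi / 3, 4 * pi / 3)), 0,
               tolerance = 1e-14)
  expect_equal(polarization(c(0, pi / 2)), sqrt(2) / 2, tolerance = 1e-14)
  expect_error(polarization(numeric(0)), "at least one agent")
})

test_that("polarization stays in [0, 1] on randomized states", {
  set.seed(101)
  for (i in 1:1000) {
    th <- stats::runif(sample(1:40, 1), -10, 10)
    p <- polarization(th)
    expect_gte(p, 0)
    expect_lte(p, 1)
  }
})

test_that("stationary_mean drops the burn-in window", {
  expect_equal(stationary_mean(rep(1, 10)), 1)
  expect_equal(stationary_mean(c(0, 0, 1, 1), burn_in = 0.5), 1)
  expect_equal(stationary_mean(rep(c(0, 1), 10), burn_in = 0.5), 0.5)
  expect_equal(stationary_mean(1:10, burn_in = 0), mean(1:10))
  expect_error(stationary_mean(numeric(0)), "insufficient data")
})

test_that("variance-peak estimator equals the parabola vertex", {
  # symmetric triple: vertex at the centre
  est <- eta_c_variance_peak(c(0.2, 0.3, 0.4), c(1, 2, 1))
  expect_equal(est$eta_c, 0.3, tolerance = 1e-12)
  expect_identical(est$method, "variance_peak")
  # asymmetric triple, frozen closed-form value
  est <- eta_c_variance_peak(c(0.2, 0.3, 0.4), c(1, 2, 1.5))
  expect_equal(est$eta_c, 0.31666666666667, tolerance = 1e-9)
})

test_that("variance-peak estimator agrees with a dense-grid oracle", {
  set.seed(7)
  for (i in 1:20) {
    # synthetic unimodal variance profile on an irregular grid
    x <- sort(stats::runif(7, 0, 3))
    peak <- x[4]
    y <- 2 - (x - peak)^2 * stats::runif(1, 0.5, 2) + 0
    est <- eta_c_variance_peak(x, y)
    # oracle: fit the same three points with lm and scan a dense grid
    i0 <- which.max(y)
    xx <- x[(i0 - 1):(i0 + 1)]; yy <- y[(i0 - 1):(i0 + 1)]
    fit <- stats::lm(yy ~ xx + I(xx^2))
    grid <- seq(xx[1], xx[3], length.out = 2000001)
    oracle <- grid[which.max(stats::predict(fit, list(xx = grid)))]
    expect_lt(abs(est$eta_c - oracle), 1e-5) # grid resolution limited
    # exact vertex of the fitted quadratic
    co <- stats::coef(fit)
    expect_lt(abs(est$eta_c - unname(-co[2] / (2 * co[3]))), 1e-9)
  }
})

test_that("variance-peak estimator flags degenerate inputs", {
  expect_error(eta_c_variance_peak(c(1, 2, 3), c(2, 2, 2)), "flat")
  expect_error(eta_c_variance_peak(c(1, 2, 3), c(3, 2, 1)), "boundary")
  expect_error(eta_c_variance_peak(c(1, 2, 3), c(1, 2, 3)), "boundary")
  expect_error(eta_c_variance_peak(c(1, 2), c(1, 2)))
})

test_that("branch-loss estimator takes the bracket midpoint", {
  est <- eta_c_branch_loss(c(0.5, 0.55, 0.6), c(0.9, 0.85, 0.1))
  expect_equal(est$eta_c, 0.575, tolerance = 1e-14)
  expect_identical(est$method, "branch_loss")
  expect_equal(est$diagnostics$eta_ordered, 0.55)
  expect_equal(est$diagnostics$eta_disordered, 0.6)
})

test_that("branch-loss estimator requires a bracket", {
  expect_error(eta_c_branch_loss(c(1, 2, 3), c(0.9, 0.8, 0.7)),
               "unbracketed")
  expect_error(eta_c_branch_loss(c(1, 2, 3), c(0.2, 0.1, 0.05)),
               "unbracketed")
})

test_that("branch-loss estimate lies strictly inside its bracket", {
  set.seed(8)
  for (i in 1:50) {
    eta <- sort(stats::runif(6, 0, 2))
    drop_at <- sample(2:5, 1)
    psi <- c(stats::runif(drop_at - 1, 0.6, 1),
             stats::runif(7 - drop_at, 0, 0.4))
    est <- eta_c_branch_loss(eta, psi)
    expect_gt(est$eta_c, eta[drop_at - 1])
    expect_lt(est$eta_c, eta[drop_at])
  }
})

test_that("pooled variance combines runs like one concatenated sample", {
  set.seed(9)
  runs <- lapply(1:4, function(i) stats::runif(20, 0, 1))
  pooled <- pooled_variance(vapply(runs, mean, 0),
                            vapply(runs, stats::var, 0),
                            vapply(runs, length, 0L))
  all_samples <- unlist(runs)
  expect_equal(pooled, mean(all_samples^2) - mean(all_samples)^2,
               tolerance = 1e-12)
})

test_that("sweeps record every configured cell with fresh networks", {
  sw <- bifurcation_sweep("vn", 4, "nn2er", p = c(0, 1), eta = c(0.5, 2),
                          runs = 3, steps = 200, seed = 5)
  expect_s3_class(sw, "sweep_result")
  expect_identical(nrow(sw), 2L * 2L * 3L)
  expect_true(all(table(sw$p, sw$eta) == 3))
  expect_true(all(sw$psi_mean >= 0 & sw$psi_mean <= 1))
  # per-run seeds distinct
  expect_identical(anyDuplicated(sw$seed), 0L)
})

test_that("VN sweep at zero noise from aligned start stays at psi = 1", {
  sw <- bifurcation_sweep("vn", 3, "nn2er", p = 0, eta = 0,
                          runs = 2, steps = 100, seed = 3)
  expect_true(all(abs(sw$psi_mean - 1) < 1e-12))
})

test_that("VN stationary polarization decreases with noise", {
  # fixed topology (p = 0), >= 10 seeds per noise value
  sw <- bifurcation_sweep("vn", 5, "nn2er", p = 0,
                          eta = c(0.5, 1.5, 2.5, 3.5), runs = 10,
                          steps = 1500, seed = 7)
  m <- tapply(sw$psi_mean, sw$eta, mean)
  expect_true(all(diff(m) < 0.02)) # non-increasing up to sampling error
})

test_that("eta_c_from_sweep matches the model-appropriate estimator", {
  sw <- bifurcation_sweep("vn", 6, "nn2er", p = 0,
                          eta = seq(0.5, 4.5, by = 0.5), runs = 4,
                          steps = 1500, seed = 13)
  est <- eta_c_from_sweep(sw)
  expect_identical(est$method, "variance_peak")
  expect_gt(est$eta_c, 0.5)
  expect_lt(est$eta_c, 4.5)
  # manual aggregation reproduces the estimate
  etas <- sort(unique(sw$eta))
  v <- vapply(etas, function(e) {
    cc <- sw[sw$eta == e, ]
    pooled_variance(cc$psi_mean, cc$psi_var, cc$n_samples)
  }, 0)
  expect_equal(est$eta_c, eta_c_variance_peak(etas, v)$eta_c)
})
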