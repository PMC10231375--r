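test_that("Box-Lucas fit recovers exact and near-linear curves", {
  t <- seq(0.5, 10, by = 0.5)
  fit <- fit_progress_curve(t, 10 * (1 - exp(-0.5 * t)))
  expect_equal(fit$a, 10, tolerance = 1e-4)
  expect_equal(fit$b, 0.5, tolerance = 1e-4)
  expect_equal(fit$v0, 5.0, tolerance = 1e-4)
  expect_equal(fit$v0, fit$a * fit$b)

  # short-window linear data: a and b are unidentifiable but v0 = a*b is
  ts <- seq(0.02, 0.2, by = 0.02)
  expect_equal(fit_progress_curve(ts, 3 * ts)$v0, 3, tolerance = 0.02)
})

test_that("Box-Lucas fit tolerates proportional noise", {
  t <- seq(0.5, 10, by = 0.5)
  clean <- 10 * (1 - exp(-0.5 * t))
  set.seed(21)
  for (i in 1:5) {
    noisy <- pmax(clean * (1 + rnorm(length(t), 0, 0.02)), 0)
    expect_equal(fit_progress_curve(t, noisy)$v0, 5, tolerance = 0.10)
  }
})

test_that("Box-Lucas fit rejects bad inputs", {
  expect_error(fit_progress_curve(1:4, rep(0, 4)), "zero")
  expect_error(fit_progress_curve(1:3, c(1, 2, 3)), ">= 4")
  expect_error(fit_progress_curve(c(1, 2, 2, 3), c(1, 2, 3, 4)),
               "increasing")
})

test_that("Michaelis-Menten fits recover exact kinetics", {
  s <- c(1, 2, 5, 10, 50)
  v <- 10 * s / (5 + s)
  nls_fit <- fit_mm_nls(s, v)
  expect_equal(nls_fit$km, 5, tolerance = 1e-6)
  expect_equal(nls_fit$vmax, 10, tolerance = 1e-6)
  # the MM identity v(Km) = Vmax/2
  expect_equal(nls_fit$vmax * 5 / (nls_fit$km + 5), 5, tolerance = 1e-6)

  lb_fit <- fit_lineweaver_burk(s, v)
  expect_equal(lb_fit$km, nls_fit$km, tolerance = 1e-9)
  expect_equal(lb_fit$vmax, nls_fit$vmax, tolerance = 1e-9)
})

test_that("MM fits validate their inputs", {
  expect_error(fit_mm_nls(c(1, 2), c(1, 2)), "3 distinct")
  expect_error(fit_lineweaver_burk(c(1, 2, 5), c(0, 1, 2)),
               "zero velocity")
})

test_that("seeded 5% CV noise keeps Km and Vmax within 15%", {
  s <- c(1, 2, 5, 10, 50)
  v_true <- 10 * s / (5 + s)
  set.seed(17)
  for (i in 1:10) {
    v <- v_true * (1 + rnorm(5, 0, 0.05))
    fit <- fit_mm_nls(s, v)
    expect_lt(abs(fit$km - 5) / 5, 0.30)       # single-replicate spread
    expect_lt(abs(fit$vmax - 10) / 10, 0.15)
  }
  # recovery criterion proper (median over replicates) in test-acceptance.R
})

test_that("kcat and catalytic efficiency arithmetic", {
  expect_equal(kcat_from_vmax(1.0, 0.05), 20.0)
  expect_equal(kcat_from_vmax(0, 2), 0)
  expect_equal(kcat_from_vmax(62.0 * 0.01, 0.01), 62.0)
  expect_error(kcat_from_vmax(1, 0), "positive")

  # printed HDR constants: poplar HDR1 vs HDR2 is ~7-fold
  fold <- efficiency_fold(mm_kinetics(km = 6.0, kcat = 62.0),
                          mm_kinetics(km = 21.4, kcat = 31.6))
  expect_equal(fold, (62 / 6) / (31.6 / 21.4), tolerance = 1e-12)
  expect_equal(fold, 7.0, tolerance = 0.01)
  expect_equal(efficiency_fold(mm_kinetics(km = 3, kcat = 9),
                               mm_kinetics(km = 3, kcat = 9)), 1.0)
  # spruce HDR2 vs HDR1, hand arithmetic: (28/21.2)/(7.8/15.9)
  expect_equal(efficiency_fold(mm_kinetics(km = 21.2, kcat = 28.0),
                               mm_kinetics(km = 15.9, kcat = 7.8)),
               2.6923, tolerance = 1e-4)
  expect_error(efficiency_fold(mm_kinetics(km = 1), mm_kinetics(km = 2)),
               "kcat")
})

test_that("DMADP:IDP ratios normalize and render paper-style", {
  r <- dmadp_idp_ratio(2.0, 42.0)
  expect_equal(r$x, 21)
  expect_equal(format(r), "1:21")
  expect_equal(format(dmadp_idp_ratio(5.0, 30.0)), "1:6")
  expect_equal(format(dmadp_idp_ratio(1.0, 0.0)), "1:0")
  expect_equal(format(dmadp_idp_ratio(3, 19), digits = 1), "1:6.3")
  expect_error(dmadp_idp_ratio(0, 5), "> 0")
})

test_that("v0 from progress curves approaches the MM rate as the window shrinks", {
  # substrate depletion biases v0 low; shrinking the sampling window must
  # shrink the bias monotonically
  s0 <- 10
  v_true <- 10 * s0 / (5 + s0)
  err <- vapply(c(2, 0.5), function(win) {
    a <- simulate_assay(km = 5, vmax = 10, substrate = s0,
                        times = seq(win / 10, win, length.out = 10),
                        cv = 0, seed = 1)
    abs(fit_progress_curve(a$time_min, a$product_uM, s0)$v0 - v_true)
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[2] / v_true, 0.05)
})
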