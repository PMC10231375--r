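POOLS_1234 <- pool_sizes(1, 2, 3, 4)

test_that("estimate_plateau averages the trailing points", {
  tc <- label_timecourse(1:6, c(0.2, 0.5, 0.7, 0.88, 0.90, 0.92))
  expect_equal(estimate_plateau(tc), 0.90)
  expect_equal(estimate_plateau(tc, k_last = 1), 0.92)
  const <- label_timecourse(1:5, rep(0.5, 5))
  expect_equal(estimate_plateau(const), 0.5)
  expect_error(estimate_plateau(tc, k_last = 7), "fewer")
})

test_that("noiseless flux recovery is near-exact", {
  times <- seq(0, 20, length.out = 25)
  tc <- labeling_curve(times, POOLS_1234, flux_params(2, 0.95))
  # with the true plateau supplied, J is recovered to 1e-4 relative
  fit <- fit_flux(tc, POOLS_1234, m = 0.95)
  expect_lt(abs(fit$flux_j - 2) / 2, 1e-4)
  # co-fitting m recovers both parameters
  fit2 <- fit_flux(tc, POOLS_1234, fit_m = TRUE)
  expect_lt(abs(fit2$flux_j - 2) / 2, 1e-4)
  expect_lt(abs(fit2$plateau_m - 0.95), 1e-4)
  expect_true(fit$converged)
  expect_length(fit$residuals, 25)
  # objective at the estimate is no worse than at the truth
  f_true <- fractional_labeling(times, POOLS_1234, flux_params(2, 0.95))
  expect_lte(fit$rss, sum((tc$fraction - f_true)^2) + 1e-12)
})

test_that("fixing m at the true plateau equals co-fitting it (noiseless)", {
  tc <- labeling_curve(seq(0, 20, length.out = 25), POOLS_1234,
                       flux_params(2, 0.95))
  j_fixed <- fit_flux(tc, POOLS_1234, m = 0.95)$flux_j
  j_cofit <- fit_flux(tc, POOLS_1234, fit_m = TRUE)$flux_j
  expect_lt(abs(j_fixed - j_cofit) / j_fixed, 1e-6)
})

test_that("seeded noisy data recover J within 5% and match a grid search", {
  tc <- simulate_labeling(POOLS_1234, flux_j = 2, plateau_m = 0.95,
                          noise_sd = 0.01, seed = 1)
  fit <- fit_flux(tc, POOLS_1234)
  expect_lt(abs(fit$flux_j - 2) / 2, 0.05)
  # brute-force 1-D grid search confirms the optimizer found the optimum
  j_grid <- exp(seq(log(0.5), log(8), length.out = 400))
  j_bf <- grid_search_flux(tc, POOLS_1234, estimate_plateau(tc), j_grid)
  expect_lt(abs(fit$flux_j - j_bf) / j_bf, 0.02)
})

test_that("parameter recovery across seeded replicates is unbiased", {
  # scaled-down version of the 100-replicate study (full run in
  # test-acceptance.R); 30 replicates at sigma = 0.02
  rel_err <- vapply(1:30, function(s) {
    tc <- simulate_labeling(POOLS_1234, 2, 0.95, noise_sd = 0.02, seed = s)
    (fit_flux(tc, POOLS_1234)$flux_j - 2) / 2
  }, numeric(1))
  expect_lt(stats::median(abs(rel_err)), 0.10)
  expect_lt(abs(stats::median(rel_err)), 0.05)
})

test_that("degenerate inputs raise the documented errors", {
  flat <- label_timecourse(0:9, rep(0, 10))
  expect_error(fit_flux(flat, POOLS_1234), "no label incorporation")
  short <- label_timecourse(0:3, c(0, 0.2, 0.4, 0.5))
  expect_error(fit_flux(short, POOLS_1234), "at least 5")
  tc <- labeling_curve(seq(0, 20, length.out = 10), POOLS_1234,
                       flux_params(2, 0.95))
  expect_error(fit_flux(tc, POOLS_1234, weights = rep(-1, 10)), "weights")
})

test_that("bootstrap is deterministic and degenerate on noiseless data", {
  tc <- labeling_curve(seq(0, 20, length.out = 25), POOLS_1234,
                       flux_params(2, 0.95))
  b1 <- bootstrap_flux(tc, POOLS_1234, n_boot = 100, seed = 5, m = 0.95)
  b2 <- bootstrap_flux(tc, POOLS_1234, n_boot = 100, seed = 5, m = 0.95)
  expect_identical(b1$j_boot, b2$j_boot)
  expect_lt(b1$ci_upper - b1$ci_lower, 1e-3)
  expect_error(bootstrap_flux(tc, POOLS_1234, n_boot = 50), ">= 100")
})

test_that("bootstrap intervals cover the true flux at nominal-ish rate", {
  # scaled down from 100 experiments to 20 (runtime); at 95% nominal
  # coverage P(X >= 16 | n = 20, p = 0.93) > 0.98
  covered <- vapply(1:20, function(s) {
    tc <- simulate_labeling(POOLS_1234, 2, 0.95, noise_sd = 0.01, seed = s)
    b <- bootstrap_flux(tc, POOLS_1234, n_boot = 100, seed = 1000 + s)
    b$ci_lower <= 2 && 2 <= b$ci_upper
  }, logical(1))
  expect_gte(sum(covered), 16)
})
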