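test_that("chain coefficients match hand-evaluated partial fractions", {
  cc <- chain_coefficients(pool_sizes(1, 2, 3, 4))
  # c_i = P_i^3 / prod_{j != i}(P_i - P_j), evaluated by hand
  expect_equal(unname(cc), c(-1 / 6, 4, -13.5, 32 / 3), tolerance = 1e-12)
  expect_equal(sum(cc), 1, tolerance = 1e-9)
})

test_that("coefficient sum identity holds for random non-degenerate pools", {
  set.seed(42)
  for (i in 1:50) {
    cc <- chain_coefficients(random_pools())
    expect_equal(sum(cc), 1, tolerance = 1e-9)
  }
})

test_that("near-equal pools raise the degeneracy error", {
  expect_error(chain_coefficients(pool_sizes(1, 1 + 1e-12, 3, 4)),
               class = "mepflux_degenerate_pools")
  expect_silent(chain_coefficients(pool_sizes(1, 1.001, 3, 4)))
})

test_that("fractional labeling matches its limits and the RK4 oracle", {
  p <- pool_sizes(1, 2, 3, 4)
  expect_equal(fractional_labeling(0, p, flux_params(1, 1)), 0)
  expect_equal(fractional_labeling(1e6, p, flux_params(1, 0.9)), 0.9,
               tolerance = 1e-12)
  # frozen from an independent fixed-step RK4 run before the build
  expect_equal(fractional_labeling(10, p, flux_params(1, 1)),
               0.5790813702, tolerance = 1e-7)
  # and re-derivable from the in-suite oracle
  expect_equal(rk4_chain(10, p, 1, 1), 0.5790813702, tolerance = 1e-8)
})

test_that("labeling curve is monotone, bounded and scale-symmetric", {
  set.seed(7)
  for (i in 1:20) {
    p <- random_pools()
    j <- exp(stats::runif(1, log(0.01), log(10)))
    m <- stats::runif(1, 0.2, 1)
    times <- seq(0, 3 * mean_transit_time(p, flux_params(j, m)),
                 length.out = 40)
    tc <- labeling_curve(times, p, flux_params(j, m))
    expect_true(all(diff(tc$fraction) >= -1e-12))
    expect_true(all(tc$fraction >= 0 & tc$fraction <= m + 1e-12))
    # time-flux scaling symmetry: (k*J, t/k) leaves fractions unchanged
    k <- 3.7
    tc2 <- labeling_curve(times / k, p, flux_params(j * k, m))
    expect_equal(tc2$fraction, tc$fraction, tolerance = 1e-12)
  }
})

test_that("closed form agrees with the adaptive ODE integrator", {
  set.seed(11)
  for (i in 1:25) {
    p <- random_pools()
    j <- exp(stats::runif(1, log(0.01), log(10)))
    m <- stats::runif(1, 0.2, 1)
    params <- flux_params(j, m)
    times <- seq(0, 3 * mean_transit_time(p, params), length.out = 50)[-1]
    closed <- fractional_labeling(times, p, params)
    ode <- integrate_chain_ode(times, p, params)$fraction
    expect_lt(max(abs(closed - ode)), 1e-6)
  }
})

test_that("equal pools route to the ODE and reproduce the Erlang CDF", {
  p <- pool_sizes(2, 2, 2, 2)           # rates all J/P = 1
  params <- flux_params(2, 1)
  ts <- c(0.5, 1, 3, 6, 10)
  ode <- integrate_chain_ode(ts, p, params)$fraction
  expect_equal(ode, pgamma(ts, shape = 4, rate = 1), tolerance = 1e-8)
  # fractional_labeling falls back transparently for degenerate pools
  expect_equal(fractional_labeling(3, p, params),
               pgamma(3, 4, 1), tolerance = 1e-8)
})

test_that("zero plateau gives the identically zero curve", {
  tc <- integrate_chain_ode(c(1, 5, 10), pool_sizes(1, 2, 3, 4),
                            flux_params(1, 0))
  expect_equal(tc$fraction, c(0, 0, 0))
})

test_that("mean transit time equals sum(P)/J and the curve's lag area", {
  p <- pool_sizes(1, 2, 3, 4)
  expect_equal(mean_transit_time(p, flux_params(2)), 5)
  p10 <- pool_sizes(10, 20, 30, 40)
  expect_equal(mean_transit_time(p10, flux_params(20)), 5)
  # integral of (1 - f/m) over [0, Inf) equals sum(P)/J
  params <- flux_params(1.3, 0.8)
  area <- stats::integrate(function(t) {
    1 - fractional_labeling(t, p, params) / params$plateau_m
  }, 0, Inf, rel.tol = 1e-9)$value
  expect_equal(area, mean_transit_time(p, params), tolerance = 1e-6)
})

test_that("invalid inputs are rejected", {
  expect_error(pool_sizes(0, 1, 2, 3), "positive")
  expect_error(flux_params(-1), "positive")
  expect_error(label_timecourse(c(0, 1), c(0.2, 1.2)), "\\[0, 1\\]")
  expect_error(label_timecourse(c(1, 1), c(0.2, 0.3)), "increasing")
  expect_error(fractional_labeling(-1, pool_sizes(1, 2, 3, 4),
                                   flux_params(1)), ">= 0")
})
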