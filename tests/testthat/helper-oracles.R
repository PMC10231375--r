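# Independent oracles, kept deliberately dumb and separate from the
# package's own numerics.

# Fixed-step classical RK4 integration of the four-pool labeling chain.
rk4_chain <- function(t_end, pools, flux_j, plateau_m, n_steps = 20000L) {
  h <- t_end / n_steps
  r <- flux_j / as.numeric(pools)
  deriv <- function(l) c(r[1] * (1 - l[1]), r[2] * (l[1] - l[2]),
                         r[3] * (l[2] - l[3]), r[4] * (l[3] - l[4]))
  l <- c(0, 0, 0, 0)
  for (i in seq_len(n_steps)) {
    k1 <- deriv(l); k2 <- deriv(l + h / 2 * k1)
    k3 <- deriv(l + h / 2 * k2); k4 <- deriv(l + h * k3)
    l <- l + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  plateau_m * l[4]
}

# Brute-force grid search for the flux, used to confirm fit_flux optima.
grid_search_flux <- function(tc, pools, m, j_grid) {
  rss <- vapply(j_grid, function(j) {
    f <- fractional_labeling(tc$time_min, pools, flux_params(j, m))
    sum((tc$fraction - f)^2)
  }, numeric(1))
  j_grid[which.min(rss)]
}

random_pools <- function() {
  p <- exp(stats::runif(4, log(0.1), log(100)))
  pool_sizes(p[1], p[2], p[3], p[4])
}
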