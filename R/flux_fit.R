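#' Estimate the labeling plateau from the end of a run
#'
#' The maximal fractional labeling m is taken as the mean of the last
#' `k_last` points of the time course.
#'
#' @param tc A [label_timecourse()].
#' @param k_last Number of trailing points to average (default 3).
#' @return Plateau estimate in \[0, 1\].
#' @examples
#' tc <- label_timecourse(1:5, c(.2, .5, .88, .90, .92))
#' estimate_plateau(tc)  # mean of last three
#' @export
estimate_plateau <- function(tc, k_last = 3L) {
  stopifnot(inherits(tc, "label_timecourse"))
  k_last <- as.integer(k_last)
  if (k_last < 1L) stop("k_last must be >= 1", call. = FALSE)
  n <- nrow(tc)
  if (n < k_last) {
    stop(sprintf("time course has %d points, fewer than k_last = %d",
                 n, k_last), call. = FALSE)
  }
  mean(tc$fraction[(n - k_last + 1L):n])
}

.flux_rss <- function(logj, tc, pools, m, w) {
  f <- fractional_labeling(tc$time_min, pools, flux_params(exp(logj), m))
  sum(w * (tc$fraction - f)^2)
}

#' Fit the MEP pathway flux to an isoprene labeling time course
#'
#' Least-squares fit of the closed-form four-pool labeling curve to the
#' data, with the pool sizes fixed and the flux J free (positive). The
#' plateau m is fixed to [estimate_plateau()] by default; set `fit_m = TRUE`
#' to co-fit it. The fit is multi-started on a log grid around the
#' mean-transit-time initial guess J0 = (A+B+C+D)/t50, where t50 is the
#' first time the curve reaches m/2, to guard against the flat likelihood
#' tail at large J.
#'
#' @param tc A [label_timecourse()] with at least 5 points.
#' @param pools A [pool_sizes()] object (fixed during the fit).
#' @param fit_m If `TRUE`, co-fit the plateau m in (0, 1].
#' @param m Optional known plateau; overrides [estimate_plateau()] when
#'   `fit_m` is `FALSE` (e.g. when the asymptote is known from a longer
#'   run). Ignored when `fit_m` is `TRUE`.
#' @param weights Optional non-negative per-point weights (default
#'   unweighted).
#' @param k_last Trailing points used for the plateau estimate.
#' @param n_starts Number of multi-start points on the log-J grid.
#' @return An object of class `flux_fit`: a list with elements `flux_j`,
#'   `plateau_m`, `se_j`, `se_m` (`NA` when m is fixed), `rss`,
#'   `converged`, `fitted`, `residuals`, `fit_m`, `n`.
#' @examples
#' p <- pool_sizes(1, 2, 3, 4)
#' tc <- labeling_curve(seq(0, 20, length.out = 25), p, flux_params(2, 0.95))
#' fit_flux(tc, p)$flux_j
#' @export
fit_flux <- function(tc, pools, fit_m = FALSE, m = NULL, weights = NULL,
                     k_last = 3L, n_starts = 5L) {
  stopifnot(inherits(tc, "label_timecourse"))
  pools <- as_pool_sizes(pools)
  n <- nrow(tc)
  if (n < 5L) stop("fit_flux: need at least 5 points", call. = FALSE)
  if (all(tc$fraction < 0.01)) {
    stop("fit_flux: no label incorporation (all fractions < 0.01)",
         call. = FALSE)
  }
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(is.na(w) | w < 0)) {
    stop("fit_flux: weights must be non-negative, one per point",
         call. = FALSE)
  }

  m_hat <- if (!is.null(m) && !fit_m) as.numeric(m)
           else estimate_plateau(tc, k_last)
  if (m_hat <= 0) stop("fit_flux: plateau estimate is not positive",
                       call. = FALSE)
  m_hat <- min(m_hat, 1)

  # J0 from the mean hypoexponential lag: sum(P)/t50
  above <- which(tc$fraction >= m_hat / 2)
  t50 <- if (length(above) && tc$time_min[above[1]] > 0) {
    tc$time_min[above[1]]
  } else {
    max(tc$time_min) / 2
  }
  j0 <- sum(as.numeric(pools)) / t50
  starts <- log(j0) + log(10) * seq(-1, 1, length.out = max(1L, n_starts))

  best <- NULL
  for (s in starts) {
    fit <- if (fit_m) {
      stats::optim(c(s, stats::qlogis(min(max(m_hat, 1e-3), 1 - 1e-6))),
                   function(p) .flux_rss(p[1], tc, pools,
                                         stats::plogis(p[2]), w),
                   method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12))
    } else {
      stats::optim(s, function(p) .flux_rss(p, tc, pools, m_hat, w),
                   method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14))
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }

  j_hat <- exp(best$par[1])
  m_fit <- if (fit_m) stats::plogis(best$par[2]) else m_hat
  params <- flux_params(j_hat, m_fit)
  fitted <- fractional_labeling(tc$time_min, pools, params)
  resid <- tc$fraction - fitted
  rss <- sum(w * resid^2)

  # standard errors from the Gauss-Newton Jacobian at the optimum
  p_hat <- if (fit_m) c(j_hat, m_fit) else j_hat
  model_fun <- function(p) {
    fractional_labeling(tc$time_min, pools,
                        flux_params(p[1], if (fit_m) p[2] else m_hat))
  }
  J <- .num_jacobian(model_fun, p_hat)
  np <- length(p_hat)
  sigma2 <- rss / max(1, n - np)
  covm <- tryCatch(sigma2 * solve(crossprod(J * sqrt(w))),
                   error = function(e) matrix(NA_real_, np, np))
  se <- sqrt(pmax(diag(covm), 0))

  structure(list(
    flux_j = j_hat, plateau_m = m_fit,
    se_j = se[1], se_m = if (fit_m) se[2] else NA_real_,
    rss = rss, converged = best$convergence == 0,
    fitted = fitted, residuals = resid, fit_m = fit_m, n = n,
    pools = pools), class = "flux_fit")
}

.num_jacobian <- function(f, p, rel = 1e-6) {
  f0 <- f(p)
  J <- matrix(NA_real_, length(f0), length(p))
  for (k in seq_along(p)) {
    h <- rel * max(abs(p[k]), 1e-8)
    pk <- p; pk[k] <- p[k] + h
    J[, k] <- (f(pk) - f0) / h
  }
  J
}

#' @export
print.flux_fit <- function(x, ...) {
  cat(sprintf("MEP pathway flux fit (%d points)\n", x$n))
  cat(sprintf("  J = %.4g +/- %.3g nmol gFW^-1 min^-1\n", x$flux_j, x$se_j))
  cat(sprintf("  m = %.4g%s\n", x$plateau_m,
              if (x$fit_m) sprintf(" +/- %.3g (fitted)", x$se_m)
              else " (fixed from plateau)"))
  cat(sprintf("  RSS = %.4g, converged: %s\n", x$rss, x$converged))
  invisible(x)
}

#' Residual-resampling bootstrap for the fitted flux
#'
#' Refits the flux to `fitted + resampled residuals` time courses and
#' summarizes the bootstrap distribution of J with a percentile interval.
#'
#' @inheritParams fit_flux
#' @param n_boot Number of bootstrap replicates (>= 100).
#' @param seed Integer seed; the run is reproducible given (inputs, seed).
#' @param level Interval coverage (default 0.95).
#' @param ... Further arguments passed to [fit_flux()] (e.g. `m`).
#' @return A list with `flux_j` (point fit), `boot_mean`, `boot_sd`,
#'   `ci_lower`, `ci_upper`, `level`, `n_boot`, `j_boot` (replicates).
#' @export
bootstrap_flux <- function(tc, pools, n_boot = 200L, seed = 1L,
                           fit_m = FALSE, level = 0.95, k_last = 3L, ...) {
  n_boot <- as.integer(n_boot)
  if (n_boot < 100L) stop("bootstrap_flux: n_boot must be >= 100",
                          call. = FALSE)
  fit <- fit_flux(tc, pools, fit_m = fit_m, k_last = k_last, ...)
  j_boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      fr <- fit$fitted + sample(fit$residuals, length(fit$residuals),
                                replace = TRUE)
      tcb <- label_timecourse(tc$time_min, pmin(pmax(fr, 0), 1))
      fb <- tryCatch(fit_flux(tcb, pools, fit_m = fit_m, k_last = k_last,
                              n_starts = 3L, ...),
                     error = function(e) NULL)
      if (is.null(fb)) NA_real_ else fb$flux_j
    }, numeric(1))
  })
  j_boot <- j_boot[!is.na(j_boot)]
  alpha <- (1 - level) / 2
  qs <- stats::quantile(j_boot, c(alpha, 1 - alpha), names = FALSE)
  list(flux_j = fit$flux_j, boot_mean = mean(j_boot), boot_sd = stats::sd(j_boot),
       ci_lower = qs[1], ci_upper = qs[2], level = level,
       n_boot = length(j_boot), j_boot = j_boot)
}
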