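#' @section Labeling model:
#' After the switch to 13CO2 at t = 0, unlabeled material in each MEP
#' intermediate pool is washed out at rate J/P (flux over pool size). The
#' fractional labeling of isoprene is the response of a linear chain of four
#' well-mixed pools in series, DXP -> MEcDP -> HMBDP -> IDP+DMADP, scaled by
#' the plateau m. With distinct pools the solution is the hypoexponential
#' mixture f(t) = m * (1 - sum_i c_i exp(-(J/P_i) t)) with partial-fraction
#' coefficients c_i = P_i^3 / prod_{j != i} (P_i - P_j).
#' @name mepflux-label-model
NULL

# relative closeness below which partial fractions are numerically unsafe
.DEGENERACY_TOL <- 1e-9

pools_degenerate <- function(pools, tol = .DEGENERACY_TOL) {
  p <- as.numeric(pools)
  d <- abs(outer(p, p, "-")) / outer(p, p, pmax)
  any(d[upper.tri(d)] < tol)
}

#' Partial-fraction coefficients of the four-pool labeling chain
#'
#' Computes the coefficients c_i = P_i^3 / prod_{j != i}(P_i - P_j) of the
#' closed-form labeling curve. They sum to 1, which enforces f(0) = 0.
#'
#' @param pools A [pool_sizes()] object (or numeric vector of length 4).
#' @param tol Relative degeneracy tolerance: if any two pools satisfy
#'   |Pi - Pj| / max(Pi, Pj) < tol the partial-fraction form is numerically
#'   unstable and an error of class `mepflux_degenerate_pools` is raised;
#'   callers should then use [integrate_chain_ode()].
#' @return Named numeric vector `(c_A, c_B, c_C, c_D)`.
#' @examples
#' chain_coefficients(pool_sizes(1, 2, 3, 4))  # sums to 1
#' @export
chain_coefficients <- function(pools, tol = .DEGENERACY_TOL) {
  pools <- as_pool_sizes(pools)
  p <- as.numeric(pools)
  if (pools_degenerate(p, tol)) {
    stop(structure(
      class = c("mepflux_degenerate_pools", "error", "condition"),
      list(message = paste0(
        "chain_coefficients: two pool sizes are closer than the relative ",
        "tolerance ", format(tol), "; use integrate_chain_ode() instead"),
        call = sys.call(-1))))
  }
  cc <- vapply(1:4, function(i) p[i]^3 / prod(p[i] - p[-i]), numeric(1))
  names(cc) <- c("c_A", "c_B", "c_C", "c_D")
  cc
}

#' Closed-form fractional labeling of isoprene
#'
#' Evaluates f(t) = m * (1 - sum_i c_i exp(-(J/P_i) t)) for the four-pool
#' chain. When pools are degenerate (nearly equal), the call is routed
#' transparently to the adaptive ODE integrator, which handles repeated
#' rates without cancellation.
#'
#' @param t Time(s) in minutes, non-negative; vectorized.
#' @param pools A [pool_sizes()] object.
#' @param params A [flux_params()] object (flux J, plateau m).
#' @return Labeled fraction(s) in \[0, m\].
#' @examples
#' fractional_labeling(10, pool_sizes(1, 2, 3, 4), flux_params(1, 1))
#' @export
fractional_labeling <- function(t, pools, params) {
  pools <- as_pool_sizes(pools)
  stopifnot(inherits(params, "flux_params"))
  t <- as.numeric(t)
  if (any(t < 0)) stop("fractional_labeling: t must be >= 0", call. = FALSE)
  if (pools_degenerate(pools)) {
    ord <- order(t)
    tc <- integrate_chain_ode(sort(unique(t)), pools, params)
    return(tc$fraction[match(t, tc$time_min)])
  }
  cc <- chain_coefficients(pools)
  rates <- params$flux_j / as.numeric(pools)
  E <- exp(-outer(t, rates))            # n x 4
  f <- params$plateau_m * (1 - as.numeric(E %*% cc))
  # guard the tiny negative round-off at t near 0
  pmin(pmax(f, 0), params$plateau_m)
}

#' Labeling curve on a time grid
#'
#' Vectorized [fractional_labeling()] returning a [label_timecourse()].
#'
#' @inheritParams fractional_labeling
#' @param times Strictly increasing, non-negative time grid (minutes).
#' @return A [label_timecourse()].
#' @export
labeling_curve <- function(times, pools, params) {
  label_timecourse(times, fractional_labeling(times, pools, params))
}

#' Mean transit time of the labeling chain
#'
#' The mean of the hypoexponential lag, (A+B+C+D)/J, equal to the area
#' under 1 - f(t)/m. Used to initialize flux fits.
#'
#' @inheritParams fractional_labeling
#' @return Mean transit time in minutes.
#' @examples
#' mean_transit_time(pool_sizes(1, 2, 3, 4), flux_params(2))  # 5
#' @export
mean_transit_time <- function(pools, params) {
  pools <- as_pool_sizes(pools)
  stopifnot(inherits(params, "flux_params"))
  sum(as.numeric(pools)) / params$flux_j
}

#' Brute-force ODE solution of the labeling chain
#'
#' Integrates the chain dl1/dt = (J/A)(1 - l1), dl2/dt = (J/B)(l1 - l2),
#' dl3/dt = (J/C)(l2 - l3), dl4/dt = (J/D)(l3 - l4), f = m * l4 with an
#' adaptive embedded Runge-Kutta (Cash-Karp 4(5)) integrator. This is the
#' independent oracle for the closed form and the fallback for degenerate
#' (near-equal) pools, where partial fractions cancel catastrophically.
#'
#' @inheritParams labeling_curve
#' @param atol,rtol Absolute and relative local error tolerances.
#' @return A [label_timecourse()] evaluated at `times`.
#' @examples
#' integrate_chain_ode(c(0, 5, 10), pool_sizes(1, 2, 3, 4), flux_params(1, 1))
#' @export
integrate_chain_ode <- function(times, pools, params,
                                atol = 1e-9, rtol = 1e-9) {
  pools <- as_pool_sizes(pools)
  stopifnot(inherits(params, "flux_params"))
  times <- as.numeric(times)
  if (any(times < 0) || (length(times) > 1L && any(diff(times) <= 0))) {
    stop("integrate_chain_ode: times must be non-negative and increasing",
         call. = FALSE)
  }
  r <- params$flux_j / as.numeric(pools)
  deriv <- function(l) {
    c(r[1] * (1 - l[1]), r[2] * (l[1] - l[2]),
      r[3] * (l[2] - l[3]), r[4] * (l[3] - l[4]))
  }
  # Cash-Karp tableau
  b5 <- c(37 / 378, 0, 250 / 621, 125 / 594, 0, 512 / 1771)
  b4 <- c(2825 / 27648, 0, 18575 / 48384, 13525 / 55296, 277 / 14336, 1 / 4)
  a21 <- 1 / 5
  a31 <- 3 / 40;        a32 <- 9 / 40
  a41 <- 3 / 10;        a42 <- -9 / 10;    a43 <- 6 / 5
  a51 <- -11 / 54;      a52 <- 5 / 2;      a53 <- -70 / 27;  a54 <- 35 / 27
  a61 <- 1631 / 55296;  a62 <- 175 / 512;  a63 <- 575 / 13824
  a64 <- 44275 / 110592; a65 <- 253 / 4096

  out <- numeric(length(times))
  l <- c(0, 0, 0, 0)
  tcur <- 0
  h <- min(0.1 / max(r), if (max(times) > 0) max(times) / 10 else 1)
  max_steps <- 1e6L
  steps <- 0L
  for (k in seq_along(times)) {
    target <- times[k]
    while (tcur < target) {
      if ((steps <- steps + 1L) > max_steps) {
        stop("integrate_chain_ode: step control failed to reach tolerance",
             call. = FALSE)
      }
      hstep <- min(h, target - tcur)
      k1 <- deriv(l)
      k2 <- deriv(l + hstep * a21 * k1)
      k3 <- deriv(l + hstep * (a31 * k1 + a32 * k2))
      k4 <- deriv(l + hstep * (a41 * k1 + a42 * k2 + a43 * k3))
      k5 <- deriv(l + hstep * (a51 * k1 + a52 * k2 + a53 * k3 + a54 * k4))
      k6 <- deriv(l + hstep * (a61 * k1 + a62 * k2 + a63 * k3 +
                                 a64 * k4 + a65 * k5))
      y5 <- l + hstep * (b5[1] * k1 + b5[3] * k3 + b5[4] * k4 + b5[6] * k6)
      y4 <- l + hstep * (b4[1] * k1 + b4[3] * k3 + b4[4] * k4 +
                           b4[5] * k5 + b4[6] * k6)
      sc <- atol + rtol * pmax(abs(l), abs(y5))
      err <- sqrt(mean(((y5 - y4) / sc)^2))
      if (err <= 1) {
        tcur <- tcur + hstep
        l <- y5
      }
      fac <- if (err > 0) 0.9 * err^(-0.2) else 5
      h <- hstep * min(5, max(0.2, fac))
    }
    out[k] <- params$plateau_m * l[4]
  }
  label_timecourse(times, pmin(pmax(out, 0), 1))
}
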