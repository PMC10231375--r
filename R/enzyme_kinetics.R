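#' @section Enzyme kinetics:
#' HDR assays report the combined DMADP+IDP product over time at several
#' HMBDP concentrations. Each progress curve is fit with the Box-Lucas
#' exponential y = a (1 - exp(-b t)); its slope at the origin, v0 = a b, is
#' the initial velocity. The v0-vs-substrate relationship is then fit with
#' the Michaelis-Menten equation, either by nonlinear least squares
#' (default) or by the classical Lineweaver-Burk double-reciprocal
#' regression, which is provided for comparability despite its well-known
#' sensitivity to noise at low substrate.
#' @name mepflux-kinetics
NULL

#' Fit a Box-Lucas exponential progress curve
#'
#' Fits y = a (1 - exp(-b t)) by least squares and reports the initial
#' velocity v0 = a * b (the analytic slope at t = 0). Near-linear data
#' (small b, e.g. a short sampling window far below the asymptote) lie on a
#' ridge a*b = const; the product v0 remains well determined there even
#' when a and b individually are not.
#'
#' @param times Assay times (minutes), strictly increasing, >= 0.
#' @param product Combined DMADP+IDP concentration (uM), non-negative.
#' @param substrate_conc Optional HMBDP concentration (uM) for bookkeeping.
#' @return An object of class `box_lucas_fit`: list with `a` (uM), `b`
#'   (min^-1), `v0 = a*b` (uM min^-1), `rss`, `converged`,
#'   `substrate_conc`.
#' @examples
#' t <- seq(0.5, 10, by = 0.5)
#' fit_progress_curve(t, 10 * (1 - exp(-0.5 * t)))$v0  # 5
#' @export
fit_progress_curve <- function(times, product, substrate_conc = NA_real_) {
  times <- as.numeric(times); product <- as.numeric(product)
  if (length(times) != length(product) || length(times) < 4L) {
    stop("fit_progress_curve: need >= 4 (time, product) points",
         call. = FALSE)
  }
  if (any(times < 0) || any(diff(times) <= 0)) {
    stop("fit_progress_curve: times must be non-negative and increasing",
         call. = FALSE)
  }
  if (any(product < 0)) {
    stop("fit_progress_curve: product must be non-negative", call. = FALSE)
  }
  if (all(product == 0)) {
    stop("fit_progress_curve: all product values are zero", call. = FALSE)
  }

  tp <- times[times > 0]; pp <- product[times > 0]
  slope0 <- pp[1] / tp[1]                   # crude origin slope
  a0 <- max(product) * 1.05
  b0 <- max(slope0 / a0, 1e-6)
  # parametrize as (v0, b) with a = v0/b: the near-linear small-b regime
  # (y -> v0 * t) is then a smooth limit instead of an a*b ridge
  rssfun <- function(p) {
    v0 <- exp(p[1]); b <- exp(p[2])
    yhat <- if (b < 1e-10) v0 * times
            else (v0 / b) * (1 - exp(-b * times))
    sum((product - yhat)^2)
  }
  best <- NULL
  for (fb in c(1, 0.2, 5, 0.02)) {          # small multi-start over b
    fit <- stats::optim(c(log(a0 * b0), log(b0 * fb)), rssfun,
                        method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  b <- exp(best$par[2]); a <- exp(best$par[1]) / b
  structure(list(a = a, b = b, v0 = a * b, rss = best$value,
                 converged = best$convergence == 0,
                 substrate_conc = substrate_conc),
            class = "box_lucas_fit")
}

#' @export
print.box_lucas_fit <- function(x, ...) {
  cat(sprintf(
    "Box-Lucas fit: a = %.4g uM, b = %.4g min^-1, v0 = a*b = %.4g uM/min\n",
    x$a, x$b, x$v0))
  if (!is.na(x$substrate_conc)) {
    cat(sprintf("  substrate: %.4g uM HMBDP\n", x$substrate_conc))
  }
  invisible(x)
}

#' Construct a Michaelis-Menten kinetics record
#'
#' Direct constructor for entering literature values (e.g. printed Km and
#' kcat) or for the fit functions' return value.
#'
#' @param km Michaelis constant (uM), > 0.
#' @param vmax Maximal velocity (uM min^-1), > 0; optional if `kcat` given.
#' @param kcat Turnover number (min^-1); requires the enzyme molarity to
#'   derive from vmax, see [kcat_from_vmax()].
#' @param method Estimation method tag: `"nonlinear"`, `"lineweaver_burk"`
#'   or `"literature"`.
#' @param converged Logical convergence flag.
#' @return Object of class `mm_kinetics` with elements `km`, `vmax`,
#'   `kcat`, `efficiency` (kcat/km, uM^-1 min^-1, present iff kcat is).
#' @examples
#' mm_kinetics(km = 6.0, kcat = 62.0)
#' @export
mm_kinetics <- function(km, vmax = NA_real_, kcat = NA_real_,
                        method = "literature", converged = TRUE) {
  km <- as.numeric(km)
  if (is.na(km) || km <= 0) stop("km must be > 0", call. = FALSE)
  if (!is.na(vmax) && vmax <= 0) stop("vmax must be > 0", call. = FALSE)
  structure(list(km = km, vmax = as.numeric(vmax), kcat = as.numeric(kcat),
                 efficiency = if (is.na(kcat)) NA_real_ else kcat / km,
                 method = method, converged = converged),
            class = "mm_kinetics")
}

#' @export
print.mm_kinetics <- function(x, ...) {
  cat(sprintf("Michaelis-Menten kinetics (%s):\n", x$method))
  cat(sprintf("  Km = %.4g uM", x$km))
  if (!is.na(x$vmax)) cat(sprintf(", Vmax = %.4g uM/min", x$vmax))
  if (!is.na(x$kcat)) {
    cat(sprintf(", kcat = %.4g min^-1, kcat/Km = %.4g uM^-1 min^-1",
                x$kcat, x$efficiency))
  }
  cat("\n")
  invisible(x)
}

#' Nonlinear Michaelis-Menten fit of initial velocities
#'
#' Least-squares fit of v = Vmax S / (Km + S). This is the recommended
#' estimator; [fit_lineweaver_burk()] is provided for comparability.
#'
#' @param substrate Substrate concentrations (uM), >= 3 distinct positive
#'   levels.
#' @param v0 Initial velocities (uM min^-1).
#' @return An `mm_kinetics` object with method `"nonlinear"`.
#' @examples
#' s <- c(1, 2, 5, 10, 50)
#' fit_mm_nls(s, 10 * s / (5 + s))
#' @export
fit_mm_nls <- function(substrate, v0) {
  s <- as.numeric(substrate); v <- as.numeric(v0)
  .check_mm_input(s, v)
  vmax0 <- max(v) * 1.2
  km0 <- s[which.min(abs(v - vmax0 / 2))]
  if (km0 <= 0) km0 <- stats::median(s)
  fit <- tryCatch(
    stats::nls(v ~ vmax * s / (km + s),
               start = list(vmax = vmax0, km = km0),
               control = stats::nls.control(maxiter = 200, tol = 1e-10,
                                            minFactor = 1e-12)),
    error = function(e) NULL)
  converged <- TRUE
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    vmax0 <- cf[["vmax"]]; km0 <- cf[["km"]]
    converged <- fit$convInfo$isConv
  }
  # Levenberg-Marquardt polish with the analytic Jacobian: nls's
  # relative-offset criterion stalls short of machine precision on
  # (near-)zero-residual data
  vmax <- vmax0; km <- km0
  lambda <- 1e-8
  rss <- sum((v - vmax * s / (km + s))^2)
  for (it in 1:100) {
    r <- v - vmax * s / (km + s)
    Jm <- cbind(s / (km + s), -vmax * s / (km + s)^2)
    A <- crossprod(Jm) + lambda * diag(2)
    step <- tryCatch(solve(A, crossprod(Jm, r)), error = function(e) NULL)
    if (is.null(step)) break
    vn <- vmax + step[1]; kn <- km + step[2]
    if (vn <= 0 || kn <= 0) { lambda <- lambda * 10; next }
    rss_new <- sum((v - vn * s / (kn + s))^2)
    if (rss_new <= rss) {
      if (rss - rss_new < 1e-15 * (rss + 1e-30)) {
        vmax <- vn; km <- kn; break
      }
      vmax <- vn; km <- kn; rss <- rss_new
      lambda <- max(lambda / 10, 1e-12)
    } else {
      lambda <- lambda * 10
      if (lambda > 1e8) break
    }
  }
  mm_kinetics(km = km, vmax = vmax, method = "nonlinear",
              converged = converged)
}

#' Lineweaver-Burk (double-reciprocal) Michaelis-Menten fit
#'
#' Ordinary least squares of 1/v on 1/S; Km = slope/intercept and
#' Vmax = 1/intercept. Equivalent to [fit_mm_nls()] on noiseless data, but
#' biased under realistic noise because taking reciprocals inflates the
#' weight of the smallest velocities; prefer the nonlinear fit.
#'
#' @inheritParams fit_mm_nls
#' @return An `mm_kinetics` object with method `"lineweaver_burk"`; a
#'   non-positive intercept (non-physical negative Vmax) raises an error.
#' @export
fit_lineweaver_burk <- function(substrate, v0) {
  s <- as.numeric(substrate); v <- as.numeric(v0)
  .check_mm_input(s, v)
  if (any(v == 0)) {
    stop("fit_lineweaver_burk: zero velocity cannot be reciprocal-transformed",
         call. = FALSE)
  }
  fit <- stats::lm(I(1 / v) ~ I(1 / s))
  ic <- stats::coef(fit)[[1]]; sl <- stats::coef(fit)[[2]]
  if (ic <= 0) {
    stop("fit_lineweaver_burk: non-positive intercept (non-physical Vmax); ",
         "use fit_mm_nls()", call. = FALSE)
  }
  mm_kinetics(km = sl / ic, vmax = 1 / ic, method = "lineweaver_burk")
}

.check_mm_input <- function(s, v) {
  if (length(s) != length(v)) {
    stop("substrate and v0 must have equal length", call. = FALSE)
  }
  if (anyNA(s) || anyNA(v) || any(s <= 0) || any(v < 0)) {
    stop("substrate must be positive and v0 non-negative", call. = FALSE)
  }
  if (length(unique(s)) < 3L) {
    stop("need >= 3 distinct substrate levels", call. = FALSE)
  }
}

#' Turnover number from Vmax and enzyme concentration
#'
#' @param vmax Maximal velocity (uM min^-1), >= 0.
#' @param enzyme_molar Enzyme concentration in the assay (uM), > 0. The
#'   package does not infer molecular weights; compute molarity from mass,
#'   assay volume and molecular weight yourself.
#' @return kcat = vmax / enzyme_molar (min^-1).
#' @examples
#' kcat_from_vmax(1.0, 0.05)  # 20
#' @export
kcat_from_vmax <- function(vmax, enzyme_molar) {
  vmax <- as.numeric(vmax); enzyme_molar <- as.numeric(enzyme_molar)
  if (is.na(enzyme_molar) || enzyme_molar <= 0) {
    stop("enzyme_molar must be a positive concentration (uM)", call. = FALSE)
  }
  if (is.na(vmax) || vmax < 0) stop("vmax must be >= 0", call. = FALSE)
  vmax / enzyme_molar
}

#' Catalytic-efficiency fold change between two enzymes
#'
#' (kcat1/Km1) / (kcat2/Km2); e.g. the poplar HDR1 vs HDR2 comparison using
#' printed constants gives about a 7-fold difference.
#'
#' @param e1,e2 `mm_kinetics` objects with `kcat` set.
#' @return Dimensionless fold difference of kcat/Km.
#' @examples
#' efficiency_fold(mm_kinetics(km = 6.0, kcat = 62.0),
#'                 mm_kinetics(km = 21.4, kcat = 31.6))  # ~7
#' @export
efficiency_fold <- function(e1, e2) {
  stopifnot(inherits(e1, "mm_kinetics"), inherits(e2, "mm_kinetics"))
  if (is.na(e1$kcat) || is.na(e2$kcat)) {
    stop("efficiency_fold: both enzymes need kcat (see kcat_from_vmax)",
         call. = FALSE)
  }
  (e1$kcat / e1$km) / (e2$kcat / e2$km)
}

#' DMADP:IDP product ratio
#'
#' Normalizes the measured DMADP and IDP amounts to the conventional
#' "1 : x" form with x = IDP/DMADP. The exact float is kept; printing
#' rounds x to the nearest integer by default (`digits = 0`).
#'
#' @param dmadp DMADP amount, > 0.
#' @param idp IDP amount, >= 0 (same units as `dmadp`).
#' @return Object of class `product_ratio` with `dmadp`, `idp`, `x`
#'   (= idp/dmadp).
#' @examples
#' dmadp_idp_ratio(2, 42)  # 1:21
#' @export
dmadp_idp_ratio <- function(dmadp, idp) {
  dmadp <- as.numeric(dmadp); idp <- as.numeric(idp)
  if (is.na(dmadp) || dmadp <= 0) {
    stop("dmadp must be > 0 to normalize the ratio", call. = FALSE)
  }
  if (is.na(idp) || idp < 0) stop("idp must be >= 0", call. = FALSE)
  structure(list(dmadp = dmadp, idp = idp, x = idp / dmadp),
            class = "product_ratio")
}

#' @rdname dmadp_idp_ratio
#' @param x A `product_ratio`.
#' @param digits Decimals for the IDP side (0 = paper-style integer).
#' @param ... Unused.
#' @export
format.product_ratio <- function(x, digits = 0, ...) {
  sprintf("1:%s", formatC(round(x$x, digits), format = "fg"))
}

#' @export
print.product_ratio <- function(x, ...) {
  cat(sprintf("DMADP:IDP ratio %s (exact 1:%.4g)\n", format(x), x$x))
  invisible(x)
}
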