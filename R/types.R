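#' Plastidial pool sizes for the four-pool MEP labeling chain
#'
#' Container for the four plastidial pool sizes that govern the lag of the
#' isoprene labeling curve: DXP, MEcDP, HMBDP and the combined IDP+DMADP
#' pool, in that fixed order (A, B, C, D). All pools are in nmol per gram
#' fresh weight and must be strictly positive.
#'
#' @param dxp DXP pool size (nmol gFW^-1).
#' @param mecdp MEcDP pool size (nmol gFW^-1).
#' @param hmbdp HMBDP pool size (nmol gFW^-1).
#' @param idp_dmadp Combined IDP+DMADP pool size (nmol gFW^-1).
#' @return An object of class `pool_sizes`: a named numeric vector of
#'   length 4 with names `dxp`, `mecdp`, `hmbdp`, `idp_dmadp`.
#' @examples
#' pool_sizes(1, 2, 3, 4)
#' @export
pool_sizes <- function(dxp, mecdp, hmbdp, idp_dmadp) {
  p <- c(dxp = as.numeric(dxp), mecdp = as.numeric(mecdp),
         hmbdp = as.numeric(hmbdp), idp_dmadp = as.numeric(idp_dmadp))
  if (length(p) != 4L || anyNA(p)) {
    stop("pool_sizes: all four pools must be single non-missing numbers",
         call. = FALSE)
  }
  if (any(p <= 0)) {
    stop("pool_sizes: all pools must be strictly positive", call. = FALSE)
  }
  structure(p, class = "pool_sizes")
}

#' @export
print.pool_sizes <- function(x, ...) {
  cat("Plastidial pool sizes (nmol gFW^-1):\n")
  print(setNames(as.numeric(x), c("DXP (A)", "MEcDP (B)", "HMBDP (C)",
                                  "IDP+DMADP (D)")))
  invisible(x)
}

as_pool_sizes <- function(x) {
  if (inherits(x, "pool_sizes")) return(x)
  x <- as.numeric(x)
  if (length(x) != 4L) stop("expected four pool sizes", call. = FALSE)
  pool_sizes(x[1], x[2], x[3], x[4])
}

#' Pathway flux and labeling plateau
#'
#' @param flux_j Pathway flux J (nmol gFW^-1 min^-1), strictly positive.
#' @param plateau_m Maximal fractional labeling m reached at the end of the
#'   run, in (0, 1]. `m = 0` is allowed only internally (degenerate
#'   zero curve); user-facing constructors require m > 0.
#' @return An object of class `flux_params`.
#' @examples
#' flux_params(2, 0.95)
#' @export
flux_params <- function(flux_j, plateau_m = 1) {
  flux_j <- as.numeric(flux_j); plateau_m <- as.numeric(plateau_m)
  if (length(flux_j) != 1L || is.na(flux_j) || flux_j <= 0) {
    stop("flux_params: flux_j must be a single positive number", call. = FALSE)
  }
  if (length(plateau_m) != 1L || is.na(plateau_m) ||
      plateau_m < 0 || plateau_m > 1) {
    stop("flux_params: plateau_m must be in [0, 1]", call. = FALSE)
  }
  structure(list(flux_j = flux_j, plateau_m = plateau_m),
            class = "flux_params")
}

#' @export
print.flux_params <- function(x, ...) {
  cat(sprintf("Flux J = %g nmol gFW^-1 min^-1, plateau m = %g\n",
              x$flux_j, x$plateau_m))
  invisible(x)
}

#' Isoprene fractional-labeling time course
#'
#' @param times Sampling times in minutes; non-negative, strictly increasing.
#' @param fractions Labeled fraction f(t) at each time, each in \[0, 1\].
#' @param sd Optional per-point standard deviation of the fraction.
#' @return A data frame of class `label_timecourse` with columns `time_min`,
#'   `fraction` and optionally `sd`.
#' @examples
#' label_timecourse(0:5, c(0, .2, .4, .55, .65, .7))
#' @export
label_timecourse <- function(times, fractions, sd = NULL) {
  times <- as.numeric(times); fractions <- as.numeric(fractions)
  if (length(times) != length(fractions)) {
    stop("label_timecourse: times and fractions must have equal length",
         call. = FALSE)
  }
  if (anyNA(times) || anyNA(fractions)) {
    stop("label_timecourse: missing values are not allowed", call. = FALSE)
  }
  if (any(times < 0)) {
    stop("label_timecourse: times must be non-negative", call. = FALSE)
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("label_timecourse: times must be strictly increasing", call. = FALSE)
  }
  if (any(fractions < 0 | fractions > 1)) {
    stop("label_timecourse: fractions must lie in [0, 1]", call. = FALSE)
  }
  out <- data.frame(time_min = times, fraction = fractions)
  if (!is.null(sd)) {
    sd <- as.numeric(sd)
    if (length(sd) != length(times) || any(is.na(sd) | sd < 0)) {
      stop("label_timecourse: sd must be non-negative, one per point",
           call. = FALSE)
    }
    out$sd <- sd
  }
  class(out) <- c("label_timecourse", "data.frame")
  out
}

#' @export
print.label_timecourse <- function(x, ...) {
  cat(sprintf("Isoprene labeling time course: %d points, t in [%g, %g] min\n",
              nrow(x), min(x$time_min), max(x$time_min)))
  print(as.data.frame(utils::head(x, 6L)))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}
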