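#' Plastidial fraction of a metabolite pool
#'
#' Isoprene is assumed to originate solely from plastidial sources, so its
#' final labeling fraction marks the fully plastidial reference. The share
#' of a metabolite's total pool located in the plastid is estimated as the
#' ratio of its final labeling fraction to that of isoprene. Ratios above 1
#' (possible under measurement noise) are clamped to 1 with a warning.
#'
#' @param metabolite_final_fraction Final labeling fraction of the
#'   metabolite, in \[0, 1\]. Vectorized.
#' @param isoprene_final_fraction Final labeling fraction (plateau) of
#'   isoprene, in (0, 1].
#' @return Plastidial fraction(s) in \[0, 1\].
#' @examples
#' plastidial_fraction(0.4, 0.8)  # 0.5
#' @export
plastidial_fraction <- function(metabolite_final_fraction,
                                isoprene_final_fraction) {
  m <- as.numeric(metabolite_final_fraction)
  iso <- as.numeric(isoprene_final_fraction)
  if (length(iso) != 1L || is.na(iso) || iso < 0 || iso > 1) {
    stop("isoprene_final_fraction must be a single value in [0, 1]",
         call. = FALSE)
  }
  if (iso == 0) {
    stop("isoprene_final_fraction is 0: no plastidial reference",
         call. = FALSE)
  }
  if (anyNA(m) || any(m < 0 | m > 1)) {
    stop("metabolite_final_fraction must lie in [0, 1]", call. = FALSE)
  }
  ratio <- m / iso
  if (any(ratio > 1)) {
    warning(sprintf(
      "%d plastidial fraction(s) exceeded 1 (max %.4f); clamped to 1",
      sum(ratio > 1), max(ratio)), call. = FALSE)
    ratio <- pmin(ratio, 1)
  }
  ratio
}

#' Plastidial pool of a metabolite
#'
#' Total pool times the plastidial fraction from [plastidial_fraction()].
#'
#' @param total_pool Total (whole-tissue) pool, nmol gFW^-1, >= 0.
#' @param metabolite_final_fraction,isoprene_final_fraction As in
#'   [plastidial_fraction()].
#' @return Plastidial pool estimate, nmol gFW^-1.
#' @examples
#' plastidial_pool(10, 0.4, 0.8)  # 5
#' @export
plastidial_pool <- function(total_pool, metabolite_final_fraction,
                            isoprene_final_fraction) {
  total_pool <- as.numeric(total_pool)
  if (anyNA(total_pool) || any(total_pool < 0)) {
    stop("total_pool must be >= 0", call. = FALSE)
  }
  total_pool * plastidial_fraction(metabolite_final_fraction,
                                   isoprene_final_fraction)
}

#' Canonical metabolite names of the labeling chain, in (A, B, C, D) order
#' @keywords internal
POOL_METABOLITES <- c("DXP", "MEcDP", "HMBDP", "IDP+DMADP")

#' Assemble pool sizes from a metabolite pool table
#'
#' Takes a table with one row per chain metabolite (columns `metabolite`,
#' `total_pool_nmol_per_gfw`, `final_fraction`) and the isoprene plateau,
#' computes plastidial pools and returns them in the fixed (A, B, C, D) =
#' (DXP, MEcDP, HMBDP, IDP+DMADP) ordering. A row named `isoprene` may
#' carry the reference plateau in its `final_fraction` column (its pool is
#' ignored) when `isoprene_final_fraction` is not given.
#'
#' @param records Data frame with columns `metabolite`,
#'   `total_pool_nmol_per_gfw`, `final_fraction`; exactly one row per
#'   metabolite in `POOL_METABOLITES`, optionally plus an `isoprene` row.
#' @param isoprene_final_fraction Isoprene plateau in (0, 1]; optional if an
#'   `isoprene` row is present.
#' @return A [pool_sizes()] object.
#' @export
build_pool_sizes <- function(records, isoprene_final_fraction = NULL) {
  req <- c("metabolite", "total_pool_nmol_per_gfw", "final_fraction")
  if (!is.data.frame(records) || !all(req %in% names(records))) {
    stop("records must be a data frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  nm <- as.character(records$metabolite)
  iso_row <- tolower(nm) == "isoprene"
  if (is.null(isoprene_final_fraction)) {
    if (!any(iso_row)) {
      stop("no isoprene reference: supply isoprene_final_fraction or an ",
           "'isoprene' row", call. = FALSE)
    }
    isoprene_final_fraction <- records$final_fraction[iso_row][1]
  }
  records <- records[!iso_row, , drop = FALSE]
  nm <- as.character(records$metabolite)
  missing <- setdiff(POOL_METABOLITES, nm)
  if (length(missing)) {
    stop("missing metabolite(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dup <- nm[duplicated(nm)]
  if (length(dup)) {
    stop("duplicate metabolite(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(nm, POOL_METABOLITES)
  if (length(extra)) {
    stop("unknown metabolite(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  idx <- match(POOL_METABOLITES, nm)
  pools <- plastidial_pool(records$total_pool_nmol_per_gfw[idx],
                           records$final_fraction[idx],
                           isoprene_final_fraction)
  if (any(pools <= 0)) {
    stop("plastidial pool(s) of ",
         paste(POOL_METABOLITES[pools <= 0], collapse = ", "),
         " are zero; pools must be positive to enter the flux model",
         call. = FALSE)
  }
  pool_sizes(pools[1], pools[2], pools[3], pools[4])
}
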