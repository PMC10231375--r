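#' Read an isoprene labeling time course from CSV
#'
#' One CSV dialect only: comma-separated, dot decimal, mandatory header
#' `time_min,fraction[,sd]`. Rows are sorted by time; duplicate times are
#' rejected rather than averaged.
#'
#' @param path Path to the CSV file.
#' @return A [label_timecourse()].
#' @export
read_timecourse <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("time_min", "fraction")
  if (!all(req %in% names(d))) {
    stop("timecourse CSV must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(d$time_min)) {
    stop("duplicate time values in ", path, call. = FALSE)
  }
  d <- d[order(d$time_min), , drop = FALSE]
  label_timecourse(d$time_min, d$fraction,
                   sd = if ("sd" %in% names(d)) d$sd else NULL)
}

#' Read an enzyme-assay table from CSV
#'
#' Schema `substrate_uM,time_min,product_uM[,dmadp_uM,idp_uM]`. When the
#' split columns are present their sum must equal the combined product
#' within 1e-6 relative. Returns one progress curve per substrate level.
#'
#' @param path Path to the CSV file.
#' @return A list with `curves` (list of data frames `time_min,product_uM`
#'   plus attribute `substrate_uM`, one per distinct substrate level, in
#'   increasing substrate order) and `data` (the full validated table).
#' @export
read_assay <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("substrate_uM", "time_min", "product_uM")
  if (!all(req %in% names(d))) {
    stop("assay CSV must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  has_split <- all(c("dmadp_uM", "idp_uM") %in% names(d))
  if (has_split) {
    s <- d$dmadp_uM + d$idp_uM
    rel <- abs(s - d$product_uM) / pmax(abs(d$product_uM), 1e-12)
    bad <- d$product_uM > 0 & rel > 1e-6
    if (any(bad)) {
      stop(sum(bad), " row(s) where dmadp_uM + idp_uM != product_uM",
           call. = FALSE)
    }
  }
  levels <- sort(unique(d$substrate_uM))
  curves <- lapply(levels, function(s0) {
    sub <- d[d$substrate_uM == s0, , drop = FALSE]
    sub <- sub[order(sub$time_min), , drop = FALSE]
    out <- data.frame(time_min = sub$time_min, product_uM = sub$product_uM)
    attr(out, "substrate_uM") <- s0
    out
  })
  list(curves = curves, data = d)
}

#' Read a metabolite pool table from CSV
#'
#' Schema `metabolite,total_pool_nmol_per_gfw,final_fraction`; an
#' `isoprene` row may carry the reference plateau (empty pool allowed).
#'
#' @param path Path to the CSV file.
#' @return The validated data frame.
#' @export
read_pool_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("metabolite", "total_pool_nmol_per_gfw", "final_fraction")
  if (!all(req %in% names(d))) {
    stop("pool CSV must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  d
}

#' Read a terpenoid product profile from CSV
#'
#' Schema `class,moles`.
#'
#' @param path Path to the CSV file.
#' @return Named numeric vector of moles per class.
#' @export
read_profile <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("class", "moles") %in% names(d))) {
    stop("profile CSV must have columns class, moles", call. = FALSE)
  }
  stats::setNames(as.numeric(d$moles), as.character(d$class))
}

.result_record <- function(result) {
  ver <- as.character(utils::packageVersion("mepflux"))
  if (inherits(result, "flux_fit")) {
    list(kind = "flux_fit", package_version = ver,
         flux_j = result$flux_j, plateau_m = result$plateau_m,
         se_j = result$se_j, se_m = result$se_m, rss = result$rss,
         converged = result$converged, n = result$n,
         m_fitted = result$fit_m)
  } else if (inherits(result, "mm_kinetics")) {
    list(kind = "mm_kinetics", package_version = ver,
         km = result$km, vmax = result$vmax, kcat = result$kcat,
         efficiency = result$efficiency, method = result$method,
         converged = result$converged)
  } else if (inherits(result, "supply_demand_balance")) {
    list(kind = "supply_demand_balance", package_version = ver,
         supply_dmadp = result$supply[["dmadp"]],
         supply_idp = result$supply[["idp"]],
         demand_dmadp = result$demand[["dmadp"]],
         demand_idp = result$demand[["idp"]],
         rate = result$rate, limiting = result$limiting,
         leftover_dmadp = result$leftover[["dmadp"]],
         leftover_idp = result$leftover[["idp"]])
  } else if (is.list(result)) {
    c(list(kind = "list", package_version = ver), result)
  } else {
    stop("write_results: unsupported result type", call. = FALSE)
  }
}

#' Write a result object to CSV or JSON
#'
#' Serializes fit and balance results with provenance (package version);
#' numbers are written at 6 significant digits in CSV and full precision
#' in JSON.
#'
#' @param result A `flux_fit`, `mm_kinetics`, `supply_demand_balance` or
#'   plain named list.
#' @param path Output file path.
#' @param format `"json"` or `"csv"` (default from the file extension).
#' @return Invisibly, the record written.
#' @export
write_results <- function(result, path,
                          format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  rec <- .result_record(result)
  if (format == "json") {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  } else {
    flat <- lapply(rec, function(v) {
      if (is.numeric(v)) signif(v, 6) else v
    })
    utils::write.csv(as.data.frame(flat), path, row.names = FALSE,
                     na = "")
  }
  invisible(rec)
}
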