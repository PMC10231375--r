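#' @section Synthetic data:
#' The study's raw inputs (on-line PTR-MS isoprene labeling traces and
#' LC-MS/MS enzyme-assay tables) are not deposited, so seeded generators
#' emulate their statistical structure: sum-of-exponential labeling curves
#' with additive truncated Gaussian noise, Michaelis-Menten progress curves
#' with substrate depletion and proportional (constant-CV) noise, and pool
#' tables that invert the plastidial-fraction estimator. All generators are
#' pure functions of (configuration, seed).
#' @name mepflux-synthetic
NULL

#' Simulate an isoprene labeling time course
#'
#' Closed-form four-pool labeling curve plus additive Gaussian noise,
#' truncated to \[0, 1\] (PTR-MS fractional-labeling estimates are
#' ratio-of-counts with roughly symmetric error at moderate fractions).
#'
#' @param pools A [pool_sizes()] object.
#' @param flux_j Pathway flux J (nmol gFW^-1 min^-1).
#' @param plateau_m Maximal fractional labeling m.
#' @param times Sampling grid (minutes), default 25 points over 0-20 min.
#' @param noise_sd Additive Gaussian SD on the fraction (default 0.02).
#' @param seed Integer seed.
#' @return A [label_timecourse()].
#' @examples
#' simulate_labeling(pool_sizes(1, 2, 3, 4), flux_j = 2, plateau_m = 0.95,
#'                   noise_sd = 0.02, seed = 1)
#' @export
simulate_labeling <- function(pools, flux_j = 2, plateau_m = 0.95,
                              times = seq(0, 20, length.out = 25),
                              noise_sd = 0.02, seed = 1L) {
  pools <- as_pool_sizes(pools)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  f <- fractional_labeling(times, pools, flux_params(flux_j, plateau_m))
  if (noise_sd > 0) {
    f <- with_seed(seed, f + stats::rnorm(length(f), 0, noise_sd))
    f <- pmin(pmax(f, 0), 1)
  }
  label_timecourse(times, f)
}

#' Simulate HDR progress-curve assays
#'
#' For each substrate level S0, integrates dP/dt = Vmax (S0-P)/(Km+S0-P)
#' by small fixed Euler steps (dt = min sampling interval / 100), samples
#' the product at `times`, applies proportional noise (constant CV) and
#' splits the product into DMADP and IDP at the fixed enzyme ratio 1:r.
#'
#' @param km,vmax Michaelis-Menten parameters (uM, uM min^-1).
#' @param substrate HMBDP start concentrations, one progress curve each.
#' @param times Sampling times (minutes), strictly increasing, > 0 allowed
#'   to include 0.
#' @param cv Proportional noise coefficient of variation (default 0.05).
#' @param ratio_idp IDP per DMADP in the product split (r in 1:r).
#' @param seed Integer seed.
#' @return A data frame with columns `substrate_uM`, `time_min`,
#'   `product_uM`, `dmadp_uM`, `idp_uM`; attribute `true` holds the
#'   generating parameters.
#' @export
simulate_assay <- function(km = 5, vmax = 10,
                           substrate = c(1, 2, 5, 10, 50),
                           times = seq(0.5, 5, by = 0.5),
                           cv = 0.05, ratio_idp = 6, seed = 1L) {
  stopifnot(km > 0, vmax > 0, all(substrate > 0), cv >= 0, ratio_idp >= 0)
  times <- as.numeric(times)
  if (any(times < 0) || any(diff(times) <= 0)) {
    stop("times must be non-negative and strictly increasing", call. = FALSE)
  }
  d <- diff(c(0, times))
  dt <- min(d[d > 0]) / 100
  sim_one <- function(s0) {
    p <- 0; tcur <- 0; out <- numeric(length(times))
    for (k in seq_along(times)) {
      while (tcur < times[k] - 1e-12) {
        step <- min(dt, times[k] - tcur)
        rate <- vmax * (s0 - p) / (km + (s0 - p))
        p <- min(p + step * rate, s0)
        tcur <- tcur + step
      }
      out[k] <- p
    }
    out
  }
  clean <- lapply(substrate, sim_one)
  prod <- unlist(clean)
  if (cv > 0) {
    prod <- with_seed(seed, prod * (1 + stats::rnorm(length(prod), 0, cv)))
    prod <- pmax(prod, 0)
  }
  out <- data.frame(
    substrate_uM = rep(substrate, each = length(times)),
    time_min = rep(times, times = length(substrate)),
    product_uM = prod,
    dmadp_uM = prod / (1 + ratio_idp),
    idp_uM = prod * ratio_idp / (1 + ratio_idp))
  attr(out, "true") <- list(km = km, vmax = vmax, cv = cv,
                            ratio_idp = ratio_idp, seed = seed)
  out
}

#' Simulate a metabolite pool table
#'
#' Inverts the plastidial-pool estimator: given true plastidial pools and
#' plastidial fractions, writes the total pools and final labeling
#' fractions a mass-spec measurement would report, so that
#' [build_pool_sizes()] recovers the true pools exactly in the noiseless
#' case.
#'
#' @param true_pools A [pool_sizes()] object of true plastidial pools.
#' @param isoprene_plateau Isoprene final labeling fraction, in (0, 1].
#' @param plastidial_fracs Four plastidial fractions in (0, 1\], ordered as
#'   (DXP, MEcDP, HMBDP, IDP+DMADP).
#' @param noise_sd Additive Gaussian SD on the reported final fractions,
#'   truncated to \[0, 1\] (default 0, noiseless).
#' @param seed Integer seed.
#' @return Data frame with columns `metabolite`, `total_pool_nmol_per_gfw`,
#'   `final_fraction`, including an `isoprene` reference row.
#' @export
simulate_pool_table <- function(true_pools, isoprene_plateau = 0.95,
                                plastidial_fracs = c(1, 1, 1, 1),
                                noise_sd = 0, seed = 1L) {
  true_pools <- as_pool_sizes(true_pools)
  stopifnot(length(plastidial_fracs) == 4L, all(plastidial_fracs > 0),
            all(plastidial_fracs <= 1),
            isoprene_plateau > 0, isoprene_plateau <= 1, noise_sd >= 0)
  total <- as.numeric(true_pools) / plastidial_fracs
  frac <- plastidial_fracs * isoprene_plateau
  if (noise_sd > 0) {
    frac <- with_seed(seed, frac + stats::rnorm(4, 0, noise_sd))
    frac <- pmin(pmax(frac, 0), 1)
  }
  data.frame(
    metabolite = c(POOL_METABOLITES, "isoprene"),
    total_pool_nmol_per_gfw = c(total, NA_real_),
    final_fraction = c(frac, isoprene_plateau))
}

#' Write a complete synthetic fixture set
#'
#' Writes labeling, assay, pool-table and product-profile CSVs plus a JSON
#' manifest recording seeds and true parameters. Identical configuration
#' and seed give byte-identical files.
#'
#' @param outdir Output directory (created if needed).
#' @param config Optional list overriding any of: `pools` (numeric 4),
#'   `flux_j`, `plateau_m`, `label_times`, `label_noise_sd`, `km`, `vmax`,
#'   `substrate`, `assay_times`, `cv`, `ratio_idp`, `isoprene_plateau`,
#'   `plastidial_fracs`, `pool_noise_sd`, `profile` (named moles).
#' @param seed Integer master seed.
#' @return Invisibly, the manifest list (with file paths).
#' @export
write_fixture_set <- function(outdir, config = list(), seed = 1L) {
  cfg <- utils::modifyList(list(
    pools = c(1, 2, 3, 4), flux_j = 2, plateau_m = 0.95,
    label_times = seq(0, 20, length.out = 25), label_noise_sd = 0.02,
    km = 5, vmax = 10, substrate = c(1, 2, 5, 10, 50),
    assay_times = seq(0.5, 5, by = 0.5), cv = 0.05, ratio_idp = 6,
    isoprene_plateau = 0.95, plastidial_fracs = c(0.8, 0.7, 0.9, 0.6),
    pool_noise_sd = 0,
    profile = c(GGDP = 1, GDP = 0.2)), config)
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(outdir)) {
      stop("cannot create output directory ", outdir, call. = FALSE)
    }
  }
  pools <- as_pool_sizes(cfg$pools)
  tc <- simulate_labeling(pools, cfg$flux_j, cfg$plateau_m,
                          cfg$label_times, cfg$label_noise_sd, seed)
  assay <- simulate_assay(cfg$km, cfg$vmax, cfg$substrate, cfg$assay_times,
                          cfg$cv, cfg$ratio_idp, seed + 1L)
  pool_tab <- simulate_pool_table(pools, cfg$isoprene_plateau,
                                  cfg$plastidial_fracs,
                                  cfg$pool_noise_sd, seed + 2L)
  prof <- data.frame(class = names(cfg$profile),
                     moles = as.numeric(cfg$profile))
  files <- file.path(outdir, c("labeling.csv", "assay.csv", "pools.csv",
                               "profile.csv", "manifest.json"))
  names(files) <- c("labeling", "assay", "pools", "profile", "manifest")
  utils::write.csv(as.data.frame(tc), files["labeling"], row.names = FALSE)
  utils::write.csv(assay, files["assay"], row.names = FALSE)
  utils::write.csv(pool_tab, files["pools"], row.names = FALSE)
  utils::write.csv(prof, files["profile"], row.names = FALSE)
  manifest <- list(seed = seed, config = cfg,
                   files = as.list(files[1:4]),
                   package_version = as.character(
                     utils::packageVersion("mepflux")))
  jsonlite::write_json(manifest, files["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
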