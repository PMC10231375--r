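#' @section Precursor stoichiometry:
#' Every prenyl diphosphate of n C5 units is condensed from exactly 1 mole
#' of DMADP (the starter) and n - 1 moles of IDP (the extenders): isoprene
#' and hemiterpenes come from DMADP alone, GDP (C10) takes 1 IDP, FDP (C15)
#' takes 2, GGDP (C20) takes 3. Tetraterpenes (C40, carotenoids) condense
#' two GGDP and are entered as 2x GGDP. Comparing a product profile's
#' aggregate demand with the DMADP:IDP supply ratio of an HDR enzyme is a
#' limiting-reagent calculation.
#' @name mepflux-stoichiometry
NULL

.PRENYL_UNITS <- c(
  "isoprene" = 1, "DMADP" = 1, "C5" = 1, "hemiterpene" = 1,
  "GDP" = 2, "C10" = 2, "monoterpene" = 2,
  "FDP" = 3, "C15" = 3, "sesquiterpene" = 3,
  "GGDP" = 4, "C20" = 4, "diterpene" = 4)

#' Prenyl diphosphate class
#'
#' @param name Class name: one of `isoprene`/`DMADP`/`C5`, `GDP`/`C10`,
#'   `FDP`/`C15`, `GGDP`/`C20` (synonyms `hemiterpene`, `monoterpene`,
#'   `sesquiterpene`, `diterpene`), a generic `C5n` string such as `"C25"`
#'   (n C5 units, 5n carbons), or `NULL` when `n_units` is given directly.
#' @param n_units Number of C5 units (>= 1); overrides `name` lookup.
#' @return Object of class `prenyl_class` with `name` and `n_units`.
#' @examples
#' prenyl_class("GGDP")
#' prenyl_class("C25")         # sesterterpene precursor, n = 5
#' prenyl_class(n_units = 6)
#' @export
prenyl_class <- function(name = NULL, n_units = NULL) {
  if (is.null(n_units)) {
    if (is.null(name)) stop("give a class name or n_units", call. = FALSE)
    key <- as.character(name)
    if (key %in% names(.PRENYL_UNITS)) {
      n_units <- .PRENYL_UNITS[[key]]
    } else if (grepl("^C[0-9]+$", key)) {
      carbons <- as.integer(sub("^C", "", key))
      if (carbons %% 5 != 0 || carbons < 5) {
        stop("invalid prenyl class '", key,
             "': carbon count must be a positive multiple of 5",
             call. = FALSE)
      }
      n_units <- carbons %/% 5L
    } else {
      stop("invalid prenyl class '", key, "'", call. = FALSE)
    }
  }
  n_units <- as.integer(n_units)
  if (is.na(n_units) || n_units < 1L) {
    stop("n_units must be an integer >= 1", call. = FALSE)
  }
  structure(list(name = if (is.null(name)) sprintf("C%d", 5L * n_units)
                 else as.character(name),
                 n_units = n_units),
            class = "prenyl_class")
}

#' DMADP and IDP demand of one mole of a prenyl class
#'
#' Chain elongation starts from 1 DMADP and adds one IDP per additional C5
#' unit, so the demand is (1, n_units - 1).
#'
#' @param cls A [prenyl_class()] or a class name accepted by it.
#' @return Named numeric `c(dmadp = 1, idp = n_units - 1)`.
#' @examples
#' unit_demand("GGDP")  # 1 DMADP, 3 IDP
#' @export
unit_demand <- function(cls) {
  if (!inherits(cls, "prenyl_class")) cls <- prenyl_class(cls)
  c(dmadp = 1, idp = cls$n_units - 1)
}

#' Aggregate DMADP/IDP demand of a product profile
#'
#' @param profile Named numeric vector or two-column data frame
#'   (`class`, `moles`) of moles per prenyl class. Class `"C40"` (synonym
#'   `"tetraterpene"`) is expanded as 2 moles GGDP per mole, since C40
#'   products condense two C20 precursors.
#' @return Object of class `demand_profile`: list with `per_class` (data
#'   frame class/moles/dmadp/idp), `dmadp_moles`, `idp_moles` and `ratio`
#'   (idp/dmadp, `NaN` for an empty profile).
#' @examples
#' profile_demand(c(GGDP = 1))            # 1 DMADP, 3 IDP
#' profile_demand(c(GDP = 2, FDP = 1))    # 3 DMADP, 4 IDP
#' @export
profile_demand <- function(profile) {
  if (is.data.frame(profile)) {
    stopifnot(all(c("class", "moles") %in% names(profile)))
    cls <- as.character(profile$class); moles <- as.numeric(profile$moles)
  } else {
    cls <- names(profile); moles <- as.numeric(profile)
    if (length(profile) && is.null(cls)) {
      stop("profile vector must be named by class", call. = FALSE)
    }
  }
  if (anyNA(moles) || any(moles < 0)) {
    stop("profile moles must be non-negative", call. = FALSE)
  }
  # C40 tetraterpenes condense two GGDP
  c40 <- cls %in% c("C40", "tetraterpene")
  if (any(c40)) {
    moles[c40] <- 2 * moles[c40]
    cls[c40] <- "GGDP"
  }
  per <- if (length(cls)) {
    dem <- vapply(cls, function(k) unit_demand(prenyl_class(k)), numeric(2))
    data.frame(class = cls, moles = moles,
               dmadp = moles * dem["dmadp", ],
               idp = moles * dem["idp", ], row.names = NULL)
  } else {
    data.frame(class = character(), moles = numeric(),
               dmadp = numeric(), idp = numeric())
  }
  dm <- sum(per$dmadp); id <- sum(per$idp)
  structure(list(per_class = per, dmadp_moles = dm, idp_moles = id,
                 ratio = id / dm),
            class = "demand_profile")
}

#' @export
print.demand_profile <- function(x, ...) {
  cat("Precursor demand profile:\n")
  if (nrow(x$per_class)) print(x$per_class)
  cat(sprintf("  total DMADP %.4g, IDP %.4g (IDP/DMADP = %.4g)\n",
              x$dmadp_moles, x$idp_moles, x$ratio))
  invisible(x)
}

#' Supply-versus-demand balance for a DMADP/IDP split
#'
#' Per unit of total C5 flux, a fraction `supply_dmadp_frac` arrives as
#' DMADP and the rest as IDP (an HDR product ratio 1:r corresponds to a
#' fraction 1/(1+r)). The maximum rate of forming the profile is the
#' limiting-reagent minimum of supply/demand over the two species; the
#' non-limiting species accumulates as leftover. An optional isomerase
#' (IDI) step converts a fraction of the leftover species before the final
#' balance, since IDI interconverts IDP and DMADP in vivo.
#'
#' @param supply_dmadp_frac DMADP fraction of the C5 supply, in (0, 1).
#' @param profile A [profile_demand()] result (or input acceptable to it).
#' @param idi_fraction Fraction of the initially-leftover species converted
#'   to the other by IDI before the reported balance (default 0, off).
#' @return Object of class `supply_demand_balance`: list with
#'   `supply` (dmadp, idp per unit flux), `demand` (per mole of profile),
#'   `rate` (moles of full profile formed per unit C5 flux),
#'   `consumed` and `leftover` (per species), `limiting`
#'   (`"DMADP"`, `"IDP"` or `"balanced"`).
#' @examples
#' supply_vs_demand(0.25, c(GGDP = 1))  # exactly balanced 1:3
#' supply_vs_demand(0.5,  c(GGDP = 1))  # IDP-limited, DMADP piles up
#' @export
supply_vs_demand <- function(supply_dmadp_frac, profile, idi_fraction = 0) {
  f <- as.numeric(supply_dmadp_frac)
  if (is.na(f) || f <= 0 || f >= 1) {
    stop("supply_dmadp_frac must be strictly between 0 and 1", call. = FALSE)
  }
  if (!inherits(profile, "demand_profile")) profile <- profile_demand(profile)
  dd <- profile$dmadp_moles; di <- profile$idp_moles
  if (dd <= 0 && di <= 0) {
    stop("profile has zero demand for both species", call. = FALSE)
  }
  if (idi_fraction < 0 || idi_fraction > 1) {
    stop("idi_fraction must be in [0, 1]", call. = FALSE)
  }
  supply <- c(dmadp = f, idp = 1 - f)

  balance <- function(supply) {
    per <- c(if (dd > 0) supply[["dmadp"]] / dd else Inf,
             if (di > 0) supply[["idp"]] / di else Inf)
    lim <- which.min(per)
    rate <- per[lim]
    consumed <- c(dmadp = rate * dd, idp = rate * di)
    consumed[lim] <- supply[[lim]]   # limiting species fully consumed
    leftover <- supply - consumed
    leftover[lim] <- 0               # exact zero, conservation holds
    list(rate = rate, consumed = consumed, leftover = leftover)
  }

  b <- balance(supply)
  if (idi_fraction > 0 && any(b$leftover > 0)) {
    shift <- idi_fraction * b$leftover
    supply <- supply - shift + rev(shift)
    names(supply) <- c("dmadp", "idp")
    b <- balance(supply)
  }
  limiting <- if (all(b$leftover == 0)) "balanced"
              else if (b$leftover[["dmadp"]] > 0) "IDP" else "DMADP"
  structure(list(supply = supply, demand = c(dmadp = dd, idp = di),
                 rate = b$rate, consumed = b$consumed,
                 leftover = b$leftover, limiting = limiting,
                 idi_fraction = idi_fraction),
            class = "supply_demand_balance")
}

#' @export
print.supply_demand_balance <- function(x, ...) {
  cat("C5 supply vs demand (per unit total C5 flux):\n")
  cat(sprintf("  supply  DMADP %.4g, IDP %.4g\n",
              x$supply[["dmadp"]], x$supply[["idp"]]))
  cat(sprintf("  demand  DMADP %.4g, IDP %.4g per mole of profile\n",
              x$demand[["dmadp"]], x$demand[["idp"]]))
  cat(sprintf("  max profile formation rate %.4g; limiting: %s\n",
              x$rate, x$limiting))
  cat(sprintf("  leftover DMADP %.4g, IDP %.4g\n",
              x$leftover[["dmadp"]], x$leftover[["idp"]]))
  invisible(x)
}
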