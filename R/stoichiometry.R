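# Stoichiometric metabolic-hydrogen ([2H]) balance of rumen fermentation
# end products. Coefficients are moles of [2H] produced (+) or utilized (-)
# per mole of end product formed; glucose-based fermentation stoichiometry.

#' Gas constant, J mol^-1 K^-1
#' @keywords internal
.R_GAS <- 8.3145

#' Stoichiometric [2H] coefficients of fermentation end products
#'
#' Returns the signed moles of metabolic hydrogen ([2H]) produced (positive)
#' or utilized (negative) per mole of each fermentation end product.
#' Caproate can form by condensation of two propionyl-CoA, which incorporates
#' 4 mol [2H]/mol (`"propanyl_coa"`, pathway 1), or of two acetyl-CoA, which
#' releases 2 mol [2H]/mol (`"acetyl_coa"`, pathway 2).
#'
#' @param pathway caproate formation route, `"propanyl_coa"` or `"acetyl_coa"`.
#' @param include_iso add isobutyrate and isovalerate with the coefficients of
#'   their straight-chain forms. The default balance uses n-forms only.
#' @param extra named numeric vector of additional products (e.g. formate,
#'   heptanoate) to append; values must be finite.
#' @return named numeric vector of signed [2H] coefficients, including
#'   `methane` (-4).
#' @examples
#' h2_stoich_coefficients("propanyl_coa")["caproate"]  # -4
#' h2_stoich_coefficients("acetyl_coa")["caproate"]    # +2
#' @export
h2_stoich_coefficients <- function(pathway = c("propanyl_coa", "acetyl_coa"),
                                   include_iso = FALSE, extra = NULL) {
  pathway <- match.arg(pathway)
  coefs <- c(acetate = 2, propionate = -1, butyrate = 2, valerate = -1,
             caproate = if (pathway == "propanyl_coa") -4 else 2,
             methane = -4)
  if (include_iso)
    coefs <- c(coefs, isobutyrate = 2, isovalerate = -1)
  if (!is.null(extra)) {
    if (is.null(names(extra)) || any(!nzchar(names(extra))) ||
        any(!is.finite(extra)))
      stop("'extra' must be a fully named vector of finite coefficients")
    coefs <- c(coefs, extra)
  }
  coefs
}

#' Caproate pathway labels
#' @return character vector of the two recognised caproate pathway tags.
#' @export
caproate_pathways <- function() c("propanyl_coa", "acetyl_coa")

#' Convert a gas volume to millimoles via the Ideal Gas Law
#'
#' n = PV / RT with P in kPa, V in mL and T in kelvin, which yields
#' millimoles directly (kPa * mL = 1e-3 J).
#'
#' @param volume gas volume, mL/d (non-negative).
#' @param temperature absolute temperature, K (positive).
#' @param pressure pressure, kPa (positive). Default one standard atmosphere.
#' @return amount of gas, mmol/d.
#' @examples
#' ch4_volume_to_mmol(22414, 273.15, 101.325)  # ~1000 mmol
#' @export
ch4_volume_to_mmol <- function(volume, temperature = 312.65,
                               pressure = 101.325) {
  if (any(!is.finite(volume)) || any(volume < 0))
    stop("'volume' must be finite and >= 0")
  if (any(!is.finite(temperature)) || any(temperature <= 0))
    stop("'temperature' must be finite and > 0 (kelvin)")
  if (any(!is.finite(pressure)) || any(pressure <= 0))
    stop("'pressure' must be finite and > 0 (kPa)")
  pressure * volume / (.R_GAS * temperature)
}

#' Construct a per-fermenter-day fermentation profile
#'
#' Holds daily production of the straight-chain short-chain fatty acids
#' (mmol/d) and methane. Methane may be given as a volume (`ch4_volume`,
#' mL/d, converted with the Ideal Gas Law at `temperature`/`pressure`) or
#' directly in mmol/d (`ch4_mmol`); exactly one must be supplied unless both
#' are zero/absent.
#'
#' @param acetate,propionate,butyrate,valerate,caproate daily production,
#'   mmol/d (non-negative scalars).
#' @param ch4_volume methane volume, mL/d, or `NULL`.
#' @param ch4_mmol methane amount, mmol/d, or `NULL`.
#' @param temperature,pressure gas conditions used for the volume conversion;
#'   defaults are the 39.5 degC incubation temperature (312.65 K) and one
#'   atmosphere (101.325 kPa).
#' @param ... further named products (mmol/d) that have a coefficient in the
#'   stoichiometric table in use (e.g. `isobutyrate`).
#' @return an object of class `fermentation_profile` (named list).
#' @export
fermentation_profile <- function(acetate = 0, propionate = 0, butyrate = 0,
                                 valerate = 0, caproate = 0,
                                 ch4_volume = NULL, ch4_mmol = NULL,
                                 temperature = 312.65, pressure = 101.325,
                                 ...) {
  amounts <- c(acetate = acetate, propionate = propionate,
               butyrate = butyrate, valerate = valerate,
               caproate = caproate, unlist(list(...)))
  if (any(!is.finite(amounts)) || any(amounts < 0))
    stop("all product amounts must be finite and >= 0 (mmol/d)")
  if (!is.null(ch4_volume) && !is.null(ch4_mmol))
    stop("supply 'ch4_volume' or 'ch4_mmol', not both")
  methane <- if (!is.null(ch4_mmol)) {
    if (!is.finite(ch4_mmol) || ch4_mmol < 0)
      stop("'ch4_mmol' must be finite and >= 0")
    ch4_mmol
  } else if (!is.null(ch4_volume)) {
    ch4_volume_to_mmol(ch4_volume, temperature, pressure)
  } else 0
  structure(list(amounts = c(amounts, methane = methane),
                 ch4_volume = ch4_volume,
                 temperature = temperature, pressure = pressure),
            class = "fermentation_profile")
}

.as_profile <- function(profile) {
  if (!inherits(profile, "fermentation_profile"))
    stop("'profile' must be a fermentation_profile")
  profile
}

#' Per-product [2H] components of a fermentation profile
#'
#' Multiplies each product's daily production (mmol/d) by its signed [2H]
#' coefficient. Positive components are [2H] sources, negative components
#' [2H] sinks.
#'
#' @param profile a [fermentation_profile()].
#' @param pathway caproate pathway tag, see [caproate_pathways()].
#' @param coefficients stoichiometric table; defaults to
#'   [h2_stoich_coefficients()] for `pathway`.
#' @return named numeric vector, signed mmol [2H]/d per product.
#' @export
h2_components <- function(profile, pathway = c("propanyl_coa", "acetyl_coa"),
                          coefficients = NULL) {
  pathway <- match.arg(pathway)
  profile <- .as_profile(profile)
  if (is.null(coefficients))
    coefficients <- h2_stoich_coefficients(pathway)
  amounts <- profile$amounts
  missing <- setdiff(names(amounts), names(coefficients))
  # products present in the profile at zero level need no coefficient
  missing <- missing[amounts[missing] > 0]
  if (length(missing))
    stop("no stoichiometric coefficient for product(s): ",
         paste(missing, collapse = ", "))
  shared <- intersect(names(amounts), names(coefficients))
  coefficients[shared] * amounts[shared]
}

#' Total [2H] production of a profile
#'
#' Sum of the positive [2H] components: acetate and butyrate always, plus
#' caproate under the acetyl-CoA pathway.
#'
#' @inheritParams h2_components
#' @return mmol [2H]/d.
#' @export
h2_production <- function(profile, pathway = c("propanyl_coa", "acetyl_coa"),
                          coefficients = NULL) {
  comp <- h2_components(profile, pathway, coefficients)
  sum(comp[comp > 0])
}

#' Total [2H] utilization of a profile
#'
#' Sum of the magnitudes of the negative [2H] components: propionate,
#' valerate and methane always, plus caproate under the propionyl-CoA
#' condensation pathway.
#'
#' @inheritParams h2_components
#' @return mmol [2H]/d.
#' @export
h2_utilization <- function(profile, pathway = c("propanyl_coa", "acetyl_coa"),
                           coefficients = NULL) {
  comp <- h2_components(profile, pathway, coefficients)
  sum(abs(comp[comp < 0]))
}

#' Metabolic hydrogen balance of a fermentation profile
#'
#' Computes, for both caproate pathway scenarios, total [2H] production and
#' utilization, the gain (production - utilization) and the percent recovery
#' (100 x utilization / production). Recovery is `NA` when production is
#' zero.
#'
#' @param profile a [fermentation_profile()].
#' @param coefficients optional named list with elements `propanyl_coa` and
#'   `acetyl_coa` giving the stoichiometric table per pathway; defaults to
#'   [h2_stoich_coefficients()].
#' @return an object of class `h2_balance`: a list with one element per
#'   pathway, each holding `production`, `utilization`, `gain`, `recovery`
#'   and the signed `components` vector.
#' @examples
#' p <- fermentation_profile(acetate = 25.15, propionate = 16.4,
#'                           butyrate = 10.65, valerate = 3.23,
#'                           caproate = 1.875, ch4_mmol = 3.45)
#' h2_balance(p)
#' @export
h2_balance <- function(profile, coefficients = NULL) {
  profile <- .as_profile(profile)
  out <- lapply(caproate_pathways(), function(pw) {
    tab <- if (is.null(coefficients)) NULL else coefficients[[pw]]
    comp <- h2_components(profile, pw, tab)
    prod <- sum(comp[comp > 0])
    util <- sum(abs(comp[comp < 0]))
    list(pathway = pw, production = prod, utilization = util,
         gain = prod - util,
         recovery = if (prod > 0) 100 * util / prod else NA_real_,
         components = comp)
  })
  names(out) <- caproate_pathways()
  structure(out, class = "h2_balance")
}

#' @export
print.h2_balance <- function(x, digits = 2, ...) {
  cat("Metabolic hydrogen [2H] balance (mmol/d)\n")
  for (b in x) {
    cat(sprintf("  caproate via %s:\n", b$pathway))
    cat(sprintf("    production %s  utilization %s  gain %s  recovery%% %s\n",
                format(round(b$production, digits)),
                format(round(b$utilization, digits)),
                format(round(b$gain, digits)),
                if (is.na(b$recovery)) "NA"
                else format(round(b$recovery, digits))))
  }
  invisible(x)
}

#' @export
as.data.frame.h2_balance <- function(x, ...) {
  do.call(rbind, lapply(x, function(b)
    data.frame(pathway = b$pathway, production = b$production,
               utilization = b$utilization, gain = b$gain,
               recovery = b$recovery, row.names = NULL)))
}

#' Tabulate the [2H] balance for a fermentation data frame
#'
#' Vectorised front end to [h2_balance()]: one input row per fermenter-day
#' with SCFA production columns in mmol/d and methane as `ch4_ml` (mL/d) or
#' `ch4_mmol` (mmol/d).
#'
#' @param data data frame with columns `acetate`, `propionate`, `butyrate`,
#'   `valerate`, `caproate` and `ch4_ml` and/or `ch4_mmol`. All other columns
#'   are carried through as identifiers.
#' @param temperature,pressure gas conditions for the methane volume
#'   conversion; either scalars or per-row vectors. A `temperature` column in
#'   `data` (kelvin), if present, takes precedence.
#' @param include_iso include `isobutyrate`/`isovalerate` columns in the
#'   balance with straight-chain coefficients.
#' @return `data` with appended columns, per pathway suffix `_p1`
#'   (propionyl-CoA) and `_p2` (acetyl-CoA): `h2_production`,
#'   `h2_utilization`, `h2_gain`, `h2_recovery`, and the per-product signed
#'   components `h2_<product>`.
#' @export
h2_balance_table <- function(data, temperature = 312.65, pressure = 101.325,
                             include_iso = FALSE) {
  needed <- c("acetate", "propionate", "butyrate", "valerate", "caproate")
  if (!all(needed %in% names(data)))
    stop("missing fermentation columns: ",
         paste(setdiff(needed, names(data)), collapse = ", "))
  if (!("ch4_ml" %in% names(data)) && !("ch4_mmol" %in% names(data)))
    stop("need a 'ch4_ml' or 'ch4_mmol' column")
  if ("temperature" %in% names(data)) temperature <- data$temperature
  temperature <- rep_len(temperature, nrow(data))
  pressure <- rep_len(pressure, nrow(data))
  iso <- if (include_iso) intersect(c("isobutyrate", "isovalerate"),
                                    names(data)) else character()
  res <- lapply(seq_len(nrow(data)), function(i) {
    extra <- as.list(data[i, iso, drop = FALSE])
    prof <- do.call(fermentation_profile, c(
      list(acetate = data$acetate[i], propionate = data$propionate[i],
           butyrate = data$butyrate[i], valerate = data$valerate[i],
           caproate = data$caproate[i],
           ch4_volume = if ("ch4_mmol" %in% names(data)) NULL
                        else data$ch4_ml[i],
           ch4_mmol = if ("ch4_mmol" %in% names(data)) data$ch4_mmol[i]
                      else NULL,
           temperature = temperature[i], pressure = pressure[i]),
      extra))
    bal <- h2_balance(prof,
      coefficients = if (include_iso) list(
        propanyl_coa = h2_stoich_coefficients("propanyl_coa", TRUE),
        acetyl_coa = h2_stoich_coefficients("acetyl_coa", TRUE)) else NULL)
    unlist(lapply(seq_along(bal), function(k) {
      b <- bal[[k]]
      v <- c(h2_production = b$production, h2_utilization = b$utilization,
             h2_gain = b$gain, h2_recovery = b$recovery,
             stats::setNames(b$components,
                             paste0("h2_", names(b$components))))
      stats::setNames(v, paste0(names(v), c("_p1", "_p2")[k]))
    }))
  })
  cbind(data, as.data.frame(do.call(rbind, res)))
}
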