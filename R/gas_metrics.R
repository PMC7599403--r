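# Fermentation gas metrics: total gas, gas fractions, apparent nutrient
# disappearance, methane yield per gram degraded nutrient, and the methane
# conversion rate (CH4 energy as % of gross-energy intake).

#' Total fermentation gas
#'
#' Total gas = CH4 + CO2 + O2 (mL/d).
#'
#' @param ch4,co2,o2 component volumes, mL/d (non-negative, vectorised).
#' @return total gas volume, mL/d.
#' @export
total_fermentation_gas <- function(ch4, co2, o2 = 0) {
  v <- cbind(ch4, co2, o2)
  if (any(!is.finite(v)) || any(v < 0))
    stop("gas volumes must be finite and >= 0")
  ch4 + co2 + o2
}

#' Gas component fraction of total fermentation gas
#'
#' @inheritParams total_fermentation_gas
#' @param component one of `"ch4"`, `"co2"`, `"o2"`.
#' @return percent of total gas; `NA` where the total is zero.
#' @export
gas_fraction <- function(ch4, co2, o2 = 0,
                         component = c("ch4", "co2", "o2")) {
  component <- match.arg(component)
  total <- total_fermentation_gas(ch4, co2, o2)
  part <- switch(component, ch4 = ch4, co2 = co2, o2 = rep_len(o2,
    length(total)))
  ifelse(total > 0, 100 * part / total, NA_real_)
}

#' Apparent nutrient disappearance
#'
#' Grams of dry matter (DM) and organic matter (OM) lost from the feed
#' during incubation: degraded = in - out.
#'
#' @param dm_in,dm_out,om_in,om_out nutrient masses, g/d; `out` must not
#'   exceed `in` (a violation usually signals a unit mix-up).
#' @return data frame with columns `dm_degraded` and `om_degraded` (g/d).
#' @export
apparent_disappearance <- function(dm_in, dm_out, om_in, om_out) {
  v <- cbind(dm_in, dm_out, om_in, om_out)
  if (any(!is.finite(v)) || any(v < 0))
    stop("nutrient masses must be finite and >= 0")
  if (any(dm_out > dm_in) || any(om_out > om_in))
    stop("nutrient outflow exceeds inflow; check units (g/d)")
  data.frame(dm_degraded = dm_in - dm_out, om_degraded = om_in - om_out)
}

#' Methane yield per gram of degraded nutrient
#'
#' @param ch4 methane production, mL/d.
#' @param degraded apparently degraded nutrient mass, g/d.
#' @return mL CH4 per g degraded; `NA` where `degraded` is not positive.
#' @export
normalize_ch4 <- function(ch4, degraded) {
  if (any(!is.finite(ch4)) || any(ch4 < 0))
    stop("'ch4' must be finite and >= 0")
  ifelse(is.finite(degraded) & degraded > 0, ch4 / degraded, NA_real_)
}

#' Methane conversion rate (% of gross-energy intake)
#'
#' MCR = 100 x (CH4 volume in L/d x energy density) / GE intake. The default
#' energy density is the standard CH4 combustion value of 39.54 kJ/L.
#'
#' @param ch4 methane production, mL/d.
#' @param ge_intake gross-energy intake, kJ/d (positive).
#' @param ch4_energy_density methane energy density, kJ/L.
#' @return percent of GE intake.
#' @export
methane_conversion_rate <- function(ch4, ge_intake,
                                    ch4_energy_density = 39.54) {
  if (any(!is.finite(ge_intake)) || any(ge_intake <= 0))
    stop("'ge_intake' must be finite and > 0 (kJ/d)")
  if (any(!is.finite(ch4_energy_density)) || any(ch4_energy_density <= 0))
    stop("'ch4_energy_density' must be finite and > 0 (kJ/L)")
  if (any(!is.finite(ch4)) || any(ch4 < 0))
    stop("'ch4' must be finite and >= 0")
  100 * (ch4 / 1000 * ch4_energy_density) / ge_intake
}

#' All gas metrics for a fermentation data frame
#'
#' Convenience wrapper computing total gas, CH4/CO2 percentages, DM/OM
#' disappearance, CH4 yields per g degraded and the methane conversion rate
#' for each row.
#'
#' @param data data frame with columns `ch4_ml`, `co2_ml`, optionally
#'   `o2_ml` (absent implies 0 with a warning), `dm_in`, `dm_out`, `om_in`,
#'   `om_out` and `ge_intake` (kJ/d).
#' @param ch4_energy_density methane energy density, kJ/L.
#' @return `data` with appended metric columns.
#' @export
gas_metrics_table <- function(data, ch4_energy_density = 39.54) {
  needed <- c("ch4_ml", "co2_ml", "dm_in", "dm_out", "om_in", "om_out",
              "ge_intake")
  if (!all(needed %in% names(data)))
    stop("missing columns: ", paste(setdiff(needed, names(data)),
                                    collapse = ", "))
  o2 <- if ("o2_ml" %in% names(data)) data$o2_ml else {
    warning("no 'o2_ml' column; assuming O2 = 0 in total gas")
    0
  }
  dis <- apparent_disappearance(data$dm_in, data$dm_out,
                                data$om_in, data$om_out)
  total <- total_fermentation_gas(data$ch4_ml, data$co2_ml, o2)
  cbind(data,
        total_gas = total,
        ch4_pct = gas_fraction(data$ch4_ml, data$co2_ml, o2, "ch4"),
        co2_pct = gas_fraction(data$ch4_ml, data$co2_ml, o2, "co2"),
        dis,
        ch4_per_g_dm = normalize_ch4(data$ch4_ml, dis$dm_degraded),
        ch4_per_g_om = normalize_ch4(data$ch4_ml, dis$om_degraded),
        mcr = methane_conversion_rate(data$ch4_ml, data$ge_intake,
                                      ch4_energy_density))
}
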