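# Carbon fluxes from culture measurements: relative growth rate, respiration,
# metabolic quotient and carbon-use efficiency.

#' Physical constants for carbon-flux calculations
#'
#' Bundles the constants needed to convert a closed-loop CO2 concentration
#' rise and mycelial dry masses into carbon fluxes. Defaults describe the
#' standard measurement setup: a 274 cm3 sampling loop at 1 atm and 20 C,
#' read over 2.5 minutes, with mycelium assumed to contain 0.43 g carbon per
#' g dry mass.
#'
#' @param carbon_fraction Mycelial carbon content, g C per g dry mass.
#'   Must lie in (0, 1].
#' @param molar_mass_C Molar mass of carbon, g/mol.
#' @param gas_constant Universal gas constant, J/(mol K).
#' @param temperature Loop air temperature, K.
#' @param pressure Loop air pressure, Pa.
#' @param loop_volume Sampling-loop volume, cm3.
#' @param measurement_duration CO2 accumulation time, minutes.
#'
#' @return An object of class `physio_constants` (a named list).
#' @examples
#' physio_constants()
#' physio_constants(temperature = 298.15) # 25 C loop
#' @export
physio_constants <- function(carbon_fraction = 0.43,
                             molar_mass_C = 12.011,
                             gas_constant = 8.314462,
                             temperature = 293.15,
                             pressure = 101325,
                             loop_volume = 274,
                             measurement_duration = 2.5) {
  k <- list(carbon_fraction = carbon_fraction,
            molar_mass_C = molar_mass_C,
            gas_constant = gas_constant,
            temperature = temperature,
            pressure = pressure,
            loop_volume = loop_volume,
            measurement_duration = measurement_duration)
  for (nm in names(k)) {
    v <- k[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("'", nm, "' must be a single strictly positive number", call. = FALSE)
    }
  }
  if (carbon_fraction > 1) {
    stop("'carbon_fraction' must lie in (0, 1]", call. = FALSE)
  }
  structure(k, class = "physio_constants")
}

#' @export
print.physio_constants <- function(x, ...) {
  cat("Physiological constants:\n")
  cat(sprintf("  carbon fraction      %.3f g C / g dry mass\n", x$carbon_fraction))
  cat(sprintf("  molar mass C         %.3f g/mol\n", x$molar_mass_C))
  cat(sprintf("  loop: %g cm3 at %g Pa, %g K, read over %g min\n",
              x$loop_volume, x$pressure, x$temperature, x$measurement_duration))
  invisible(x)
}

.check_positive <- function(x, field) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop("'", field, "' must be strictly positive and finite", call. = FALSE)
  }
  invisible(x)
}

.check_nonnegative <- function(x, field) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop("'", field, "' must be non-negative and finite", call. = FALSE)
  }
  invisible(x)
}

#' Relative growth rate under exponential growth
#'
#' The specific growth rate mu (day^-1) implied by the biomass ratio between
#' harvest and inoculation, `mu = ln(Bt/B0) / t`, assuming exponential growth
#' over the culture period.
#'
#' @param B0 Inoculum dry mass, mg. Strictly positive.
#' @param Bt Dry mass at harvest, mg. Strictly positive.
#' @param t Culture duration, days. Strictly positive.
#'
#' @return Relative growth rate, day^-1. Vectorized; negative when `Bt < B0`.
#' @examples
#' relative_growth_rate(B0 = 2, Bt = 16, t = 10) # ln(8)/10
#' @export
relative_growth_rate <- function(B0, Bt, t) {
  .check_positive(B0, "B0")
  .check_positive(Bt, "Bt")
  .check_positive(t, "t")
  log(Bt / B0) / t
}

# moles of gas in the sampling loop (ideal gas law, V converted cm3 -> m3)
.loop_moles <- function(constants) {
  constants$pressure * constants$loop_volume * 1e-6 /
    (constants$gas_constant * constants$temperature)
}

#' Convert a CO2 concentration rise to a respiration rate
#'
#' Applies the ideal gas law to the sampling loop: a rise of `delta_ppm` over
#' the measurement window corresponds to `delta_ppm * 1e-6 * PV/RT` mol CO2,
#' which is scaled to mmol carbon per day.
#'
#' @param delta_ppm CO2 concentration increase over the measurement window,
#'   ppm. Non-negative; vectorized.
#' @param constants A [physio_constants()] object.
#'
#' @return Respiration rate, mmol C per day.
#' @examples
#' co2_to_respiration(100) # approx 0.656 mmol C/day with the default loop
#' @export
co2_to_respiration <- function(delta_ppm, constants = physio_constants()) {
  .check_nonnegative(delta_ppm, "delta_ppm")
  stopifnot(inherits(constants, "physio_constants"))
  delta_ppm * 1e-6 * .loop_moles(constants) *
    (1440 / constants$measurement_duration) * 1000
}

#' Carbon content of dry mycelium
#'
#' @param dry_mass Dry mass, mg. Non-negative; vectorized.
#' @param constants A [physio_constants()] object.
#'
#' @return Biomass carbon, mmol C (`dry_mass * carbon_fraction / molar_mass_C`).
#' @examples
#' biomass_carbon(10) # 4.3 mg C = 0.358 mmol C
#' @export
biomass_carbon <- function(dry_mass, constants = physio_constants()) {
  .check_nonnegative(dry_mass, "dry_mass")
  stopifnot(inherits(constants, "physio_constants"))
  dry_mass * constants$carbon_fraction / constants$molar_mass_C
}

#' Metabolic quotient
#'
#' Respiration rate per unit biomass carbon at harvest, qCO2 (day^-1).
#'
#' @param respiration Respiration rate, mmol C/day. Non-negative.
#' @param biomass_c Biomass carbon at harvest, mmol C. Strictly positive.
#'
#' @return qCO2, day^-1.
#' @examples
#' metabolic_quotient(0.6561, 0.35801)
#' @export
metabolic_quotient <- function(respiration, biomass_c) {
  .check_nonnegative(respiration, "respiration")
  .check_positive(biomass_c, "biomass_c")
  respiration / biomass_c
}

#' Carbon-use efficiency
#'
#' The share of metabolized carbon allocated to growth rather than respired:
#' `CUE = mu / (mu + qCO2)`. Lies in (0, 1) when both rates are positive.
#'
#' @param mu Relative growth rate, day^-1.
#' @param qco2 Metabolic quotient, day^-1. Non-negative.
#'
#' @return Dimensionless CUE.
#' @examples
#' carbon_use_efficiency(0.3, 0.1) # 0.75
#' @export
carbon_use_efficiency <- function(mu, qco2) {
  if (!is.numeric(mu) || any(!is.finite(mu))) {
    stop("'mu' must be numeric and finite", call. = FALSE)
  }
  .check_nonnegative(qco2, "qco2")
  if (any(mu + qco2 == 0)) {
    stop("'mu' + 'qco2' must be non-zero", call. = FALSE)
  }
  mu / (mu + qco2)
}

#' Derive carbon fluxes for a batch of culture samples
#'
#' Converts per-sample phenotype measurements into a flux table holding
#' relative growth rate, respiration, biomass carbon, metabolic quotient and
#' CUE. Problem records are flagged rather than aborting the batch:
#' `NEGATIVE_GROWTH` when `mu <= 0`, `ZERO_BIOMASS` when the harvested mass is
#' zero (mu and qCO2 undefined), and `INVALID_RECORD` when an input violates
#' its domain (non-positive B0 or t, negative delta CO2). Flagged samples are
#' excluded from downstream marker fitting by [usable_samples()] but stay in
#' the table for transparency.
#'
#' @param phenotypes Data frame with columns `sample_id`, `B0_mg`, `Bt_mg`,
#'   `t_days`, `delta_co2_ppm` (see [read_phenotypes()]).
#' @param constants A [physio_constants()] object.
#'
#' @return A data frame of class `flux_table` with columns `sample_id`,
#'   `mu_per_day`, `respiration_mmolC_per_day`, `biomass_mmolC`,
#'   `qco2_per_day`, `cue` and `qc_flags` (semicolon-separated, empty when
#'   clean).
#' @examples
#' ph <- data.frame(sample_id = c("a", "b"), B0_mg = c(2, 5),
#'                  Bt_mg = c(16, 4), t_days = c(10, 7),
#'                  delta_co2_ppm = c(100, 80))
#' compute_fluxes(ph)
#' @export
compute_fluxes <- function(phenotypes, constants = physio_constants()) {
  required <- c("sample_id", "B0_mg", "Bt_mg", "t_days", "delta_co2_ppm")
  missing_cols <- setdiff(required, names(phenotypes))
  if (length(missing_cols)) {
    stop("phenotype table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(phenotypes) == 0L) stop("phenotype table is empty", call. = FALSE)
  if (anyDuplicated(phenotypes$sample_id)) {
    stop("duplicated sample_id in phenotype table", call. = FALSE)
  }

  n <- nrow(phenotypes)
  B0 <- phenotypes$B0_mg
  Bt <- phenotypes$Bt_mg
  t <- phenotypes$t_days
  dppm <- phenotypes$delta_co2_ppm

  invalid <- !is.finite(B0) | B0 <= 0 | !is.finite(t) | t <= 0 |
    !is.finite(Bt) | Bt < 0 | !is.finite(dppm) | dppm < 0
  zero_biomass <- !invalid & Bt == 0

  mu <- resp <- bc <- qco2 <- cue <- rep(NA_real_, n)
  ok <- !invalid & !zero_biomass
  mu[ok] <- log(Bt[ok] / B0[ok]) / t[ok]
  resp[!invalid] <- co2_to_respiration(dppm[!invalid], constants)
  bc[!invalid] <- biomass_carbon(Bt[!invalid], constants)
  qco2[ok] <- resp[ok] / bc[ok]
  denom_ok <- ok & (mu + qco2) != 0
  cue[denom_ok] <- mu[denom_ok] / (mu[denom_ok] + qco2[denom_ok])

  flags <- character(n)
  add_flag <- function(flags, which, flag) {
    ifelse(which, ifelse(flags == "", flag, paste(flags, flag, sep = ";")), flags)
  }
  flags <- add_flag(flags, invalid, "INVALID_RECORD")
  flags <- add_flag(flags, zero_biomass, "ZERO_BIOMASS")
  flags <- add_flag(flags, ok & mu <= 0, "NEGATIVE_GROWTH")

  out <- data.frame(sample_id = phenotypes$sample_id,
                    mu_per_day = mu,
                    respiration_mmolC_per_day = resp,
                    biomass_mmolC = bc,
                    qco2_per_day = qco2,
                    cue = cue,
                    qc_flags = flags,
                    stringsAsFactors = FALSE)
  class(out) <- c("flux_table", "data.frame")
  out
}

#' Samples usable for marker fitting
#'
#' @param fluxes A `flux_table` from [compute_fluxes()].
#' @return Character vector of sample ids with an empty QC flag set.
#' @export
usable_samples <- function(fluxes) {
  stopifnot(inherits(fluxes, "flux_table"))
  fluxes$sample_id[fluxes$qc_flags == ""]
}
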