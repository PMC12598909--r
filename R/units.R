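#' @keywords internal
#' @importFrom randomForest randomForest importance
#' @importFrom minpack.lm nlsLM nls.lm.control
#' @importFrom lmerTest lmer
#' @importFrom lme4 lmerControl isSingular
#' @importFrom car Anova
#' @importFrom stats predict coef anova lm
"_PACKAGE"

# Universal gas constant, J mol-1 K-1
.R_GAS <- 8.314462618

# Molar masses, g mol-1
.MOLAR_MASS <- c(co2 = 44.01, ch4 = 16.04, n2o = 44.01)

# Ambient mole fractions used as trace baselines, ppm
.AMBIENT_PPM <- c(co2 = 420, ch4 = 2.0, n2o = 0.34)

.GASES <- c("co2", "ch4", "n2o")

#' Normalise a gas identifier
#'
#' Accepts common spellings ("CO2", "co2", "CO_2") and returns the canonical
#' lower-case id used throughout the package.
#'
#' @param gas character scalar.
#' @return one of `"co2"`, `"ch4"`, `"n2o"`.
#' @export
gas_id <- function(gas) {
  g <- tolower(gsub("[^a-z0-9]", "", tolower(gas)))
  if (!g %in% .GASES) stop("unknown gas id: ", gas)
  g
}

#' Convert a concentration slope to a surface flux
#'
#' Chamber headspace mole-fraction change is converted to an areal mass flux
#' assuming ideal-gas molar density at the measurement temperature and
#' pressure:
#' flux = slope \[ppm s-1\] x 1e-6 x P/(R T) \[mol m-3\] x M \[g mol-1\]
#'        x 1e3 \[mg g-1\] x V/A \[m\] x 3600 \[s h-1\].
#'
#' @param slope_ppm_s concentration change, ppm s-1.
#' @param gas gas id.
#' @param height_m effective headspace height V/A, m.
#' @param tair_k air temperature, K.
#' @param pressure_pa air pressure, Pa.
#' @return flux in mg gas m-2 h-1, emission positive.
#' @export
slope_to_flux <- function(slope_ppm_s, gas, height_m, tair_k,
                          pressure_pa = 101325) {
  if (any(tair_k <= 0) || any(pressure_pa <= 0)) {
    stop("temperature and pressure must be positive")
  }
  m <- .MOLAR_MASS[[gas_id(gas)]]
  molar_density <- pressure_pa / (.R_GAS * tair_k) # mol m-3
  slope_ppm_s * 1e-6 * molar_density * m * 1e3 * height_m * 3600
}

#' Convert a surface flux to the concentration slope it produces
#'
#' Exact inverse of [slope_to_flux()]; used by the trace generator.
#'
#' @inheritParams slope_to_flux
#' @param flux_mg_m2_h flux in mg gas m-2 h-1.
#' @return slope in ppm s-1.
#' @export
flux_to_slope <- function(flux_mg_m2_h, gas, height_m, tair_k,
                          pressure_pa = 101325) {
  flux_mg_m2_h / slope_to_flux(1, gas, height_m, tair_k, pressure_pa)
}
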