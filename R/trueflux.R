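#' Ground-truth flux surfaces of the synthetic campaign
#'
#' Evaluates the generator's true flux (mg gas m-2 h-1, emission positive)
#' at one or more driver rows.
#'
#' CO2: net exchange = -(alpha Rg GPPmax)/(alpha Rg + GPPmax) + Rd, with
#' GPPmax and Rd modulated by WTL (exponential suppression toward wet), Rd by
#' a Q10 response to 5-cm soil temperature and GPPmax by a post-harvest
#' regrowth factor. CH4: scale x exp(WTL / efold) x Q10 term - negligible
#' below about -0.6 m. N2O: baseline plus a post-fertilization exponential
#' pulse, amplified when WTL lies in the optimum interval; the low dosage
#' halves the pulse.
#'
#' @param gas gas id.
#' @param drivers one or more rows of a [gen_drivers()] table (needs `Rg`,
#'   `Ts5`, `WTL`, `days_since_harvest`, `days_since_fertilization`).
#' @param params a [true_flux_params()].
#' @param dose fertilization dosage, `"high"` or `"low"` (N2O pulse only).
#' @return numeric vector of fluxes, mg gas m-2 h-1.
#' @export
true_flux <- function(gas, drivers, params = true_flux_params(),
                      dose = "high") {
  gas <- gas_id(gas)
  dose <- match.arg(dose, c("high", "low"))
  q10t <- params$q10^((drivers$Ts5 - 10) / 10)
  if (gas == "co2") {
    fg <- exp(params$wtl_suppression_gpp * (drivers$WTL - params$wtl_ref))
    fr <- exp(params$wtl_suppression_rd * (drivers$WTL - params$wtl_ref))
    regrow <- 1 - params$harvest_drop *
      exp(-drivers$days_since_harvest / params$harvest_recovery_d)
    g <- params$gppmax_base * fg * regrow
    rd <- params$rd_ref * q10t * fr
    a_rg <- params$alpha_base * drivers$Rg
    uptake <- ifelse(a_rg + g > 0, a_rg * g / (a_rg + g), 0)
    -uptake + rd
  } else if (gas == "ch4") {
    params$ch4_scale * exp(drivers$WTL / params$ch4_wtl_efold) * q10t
  } else {
    opt <- params$n2o_wtl_optimum
    width <- (opt[2] - opt[1]) / 1.5
    wfac <- 1 + 2 * exp(-0.5 * ((drivers$WTL - mean(opt)) / width)^2)
    dose_f <- if (dose == "high") 1 else 0.5
    pulse <- ifelse(
      drivers$days_since_fertilization < 365,
      params$n2o_pulse_peak * dose_f *
        exp(-drivers$days_since_fertilization / params$n2o_pulse_decay_d),
      0)
    params$n2o_baseline + pulse * wfac
  }
}
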