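#' Campaign configuration
#'
#' Describes the measurement campaign emulated by the synthetic generator:
#' five plots along a water-table gradient, each split into a high- and a
#' low-fertilization subplot with three chambers apiece (30 chambers), every
#' chamber closed once per 8-h cycle from May through October at 69.5 deg N.
#'
#' @param n_plots number of plots along the water-table gradient.
#' @param n_chambers_per_subplot replicate chambers per fertilization subplot.
#' @param season_start,season_end season date range (Date or coercible).
#' @param measurement_cycle_h hours between successive closures of one chamber.
#' @param closure_min usable closure length, minutes (16-min measurement minus
#'   two 3-min flushes).
#' @param latitude_deg site latitude, degrees north.
#' @param fertilization_dates,harvest_dates management dates inside the season.
#' @param seed integer seed governing drivers and other "field truth"
#'   randomness (chamber heterogeneity, biomass).
#' @return object of class `campaign_config`.
#' @export
campaign_config <- function(n_plots = 5,
                            n_chambers_per_subplot = 3,
                            season_start = "2022-05-01",
                            season_end = "2022-10-31",
                            measurement_cycle_h = 8,
                            closure_min = 10,
                            latitude_deg = 69.5,
                            fertilization_dates = c("2022-05-12", "2022-08-09"),
                            harvest_dates = "2022-08-09",
                            seed = 1L) {
  season_start <- as.Date(season_start)
  season_end <- as.Date(season_end)
  fertilization_dates <- as.Date(fertilization_dates)
  harvest_dates <- as.Date(harvest_dates)
  stopifnot(n_plots >= 1, n_chambers_per_subplot >= 1,
            closure_min > 0, measurement_cycle_h > 0,
            season_end > season_start)
  ev <- c(fertilization_dates, harvest_dates)
  if (length(ev) && (any(ev < season_start) || any(ev > season_end))) {
    stop("all management dates must fall inside the season")
  }
  structure(list(
    n_plots = as.integer(n_plots),
    n_chambers_per_subplot = as.integer(n_chambers_per_subplot),
    season_start = season_start, season_end = season_end,
    measurement_cycle_h = measurement_cycle_h,
    closure_min = closure_min,
    latitude_deg = latitude_deg,
    fertilization_dates = fertilization_dates,
    harvest_dates = harvest_dates,
    seed = as.integer(seed)
  ), class = "campaign_config")
}

#' Chamber geometry
#'
#' Transparent 60 x 60 x 60 cm chambers: 0.36 m2 footprint, 0.216 m3 volume.
#' The flux conversion only uses the ratio V/A (the headspace height).
#'
#' @param footprint_area m2.
#' @param headspace_height m.
#' @return object of class `chamber_geometry` with a derived `volume` field.
#' @export
chamber_geometry <- function(footprint_area = 0.36, headspace_height = 0.6) {
  stopifnot(footprint_area > 0, headspace_height > 0)
  structure(list(
    footprint_area = footprint_area,
    headspace_height = headspace_height,
    volume = footprint_area * headspace_height
  ), class = "chamber_geometry")
}

#' True-flux surface parameters for the synthetic generator
#'
#' Defines the "field truth" flux surfaces the generator samples. CO2 follows
#' a Michaelis-Menten light response whose GPPmax and Rd are suppressed
#' multiplicatively toward wetter water tables (exp(s (WTL - wtl_ref))), with
#' GPPmax declining faster than Rd in absolute terms while Rd/GPPmax shrinks,
#' so the light compensation point falls toward the wettest plots. CH4 grows
#' exponentially with WTL; N2O is a small baseline plus post-fertilization
#' exponential pulses amplified in an intermediate WTL window.
#'
#' @param gppmax_base maximum gross primary production at `wtl_ref`,
#'   mg CO2 m-2 h-1.
#' @param alpha_base light-use efficiency, mg CO2 m-2 h-1 per W m-2.
#' @param rd_ref dark respiration at 10 C and `wtl_ref`, mg CO2 m-2 h-1.
#' @param q10 temperature sensitivity of respiration/methanogenesis.
#' @param wtl_suppression_gpp,wtl_suppression_rd exponential WTL-suppression
#'   rates, per metre (negative: wetter water table suppresses).
#' @param wtl_ref WTL (m) at which the suppression factors equal 1.
#' @param ch4_scale CH4 flux scale, mg CH4 m-2 h-1.
#' @param ch4_wtl_efold e-folding depth of the CH4-WTL response, m.
#' @param n2o_baseline background N2O flux, mg N2O m-2 h-1.
#' @param n2o_pulse_peak peak of the post-fertilization N2O pulse (high
#'   dosage), mg N2O m-2 h-1.
#' @param n2o_pulse_decay_d pulse decay constant, days.
#' @param n2o_wtl_optimum WTL interval (m) in which N2O pulses are amplified.
#' @param harvest_drop fractional GPP reduction immediately after a harvest.
#' @param harvest_recovery_d regrowth time constant, days.
#' @return object of class `true_flux_params`.
#' @export
true_flux_params <- function(gppmax_base = 2600,
                             alpha_base = 2.0,
                             rd_ref = 750,
                             q10 = 2.2,
                             wtl_suppression_gpp = -0.55,
                             wtl_suppression_rd = -1.35,
                             wtl_ref = -1.5,
                             ch4_scale = 3,
                             ch4_wtl_efold = 0.15,
                             n2o_baseline = 0.02,
                             n2o_pulse_peak = 0.8,
                             n2o_pulse_decay_d = 7,
                             n2o_wtl_optimum = c(-0.4, -0.3),
                             harvest_drop = 0.6,
                             harvest_recovery_d = 14) {
  stopifnot(q10 > 1, n2o_pulse_decay_d > 0, ch4_wtl_efold > 0,
            gppmax_base > 0, rd_ref > 0, alpha_base > 0,
            length(n2o_wtl_optimum) == 2,
            n2o_wtl_optimum[1] < n2o_wtl_optimum[2])
  # GPPmax must decline faster with WTL than Rd (absolute slope, over the
  # campaign's WTL range) while Rd/GPPmax shrinks toward wet, so the light
  # compensation point decreases with the water table.
  for (w in c(-1.6, -0.1)) {
    dg <- gppmax_base * abs(wtl_suppression_gpp) *
      exp(wtl_suppression_gpp * (w - wtl_ref))
    dr <- rd_ref * abs(wtl_suppression_rd) *
      exp(wtl_suppression_rd * (w - wtl_ref))
    if (dg <= dr) {
      stop("wtl suppression slopes must make GPPmax decline faster than Rd")
    }
  }
  if (wtl_suppression_rd >= wtl_suppression_gpp) {
    stop("Rd/GPPmax must shrink toward wet (wtl_suppression_rd < ",
         "wtl_suppression_gpp)")
  }
  structure(as.list(environment())[c(
    "gppmax_base", "alpha_base", "rd_ref", "q10",
    "wtl_suppression_gpp", "wtl_suppression_rd", "wtl_ref",
    "ch4_scale", "ch4_wtl_efold",
    "n2o_baseline", "n2o_pulse_peak", "n2o_pulse_decay_d", "n2o_wtl_optimum",
    "harvest_drop", "harvest_recovery_d")],
    class = "true_flux_params")
}

#' Trace noise model
#'
#' Additive AR(1) Gaussian noise on the ppm series plus an optional
#' stabilization artefact: an extra slope `curvature x true slope` that
#' decays with time constant `curvature_tau_s`, bending the early part of
#' the trace (the behaviour that motivates the dynamic fit window).
#'
#' @param sd_ppm marginal noise SD, ppm.
#' @param ar1 lag-1 autocorrelation in (0, 1).
#' @param curvature dimensionless multiplier of the initial extra slope;
#'   0 disables the artefact.
#' @param curvature_tau_s decay time constant of the artefact, seconds.
#' @return object of class `trace_noise`.
#' @export
trace_noise <- function(sd_ppm = 0.5, ar1 = 0.8, curvature = 2,
                        curvature_tau_s = 60) {
  if (sd_ppm < 0) stop("noise sd must be non-negative")
  stopifnot(ar1 >= 0, ar1 < 1, curvature_tau_s > 0)
  structure(list(sd_ppm = sd_ppm, ar1 = ar1, curvature = curvature,
                 curvature_tau_s = curvature_tau_s),
            class = "trace_noise")
}

#' Per-gas trace noise defaults for the campaign generator
#'
#' Analyzer-scale marginal noise: 0.5 ppm for CO2 and 0.0015 ppm for CH4 and
#' N2O, AR(1) 0.8, stabilization artefact enabled.
#'
#' @param co2,ch4,n2o `trace_noise` objects.
#' @return named list of `trace_noise` objects.
#' @export
campaign_noise <- function(co2 = trace_noise(sd_ppm = 0.5),
                           ch4 = trace_noise(sd_ppm = 0.0015),
                           n2o = trace_noise(sd_ppm = 0.0015)) {
  list(co2 = co2, ch4 = ch4, n2o = n2o)
}
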