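#' Compute a flux from a fitted window
#'
#' Converts the fitted concentration slope to an areal mass flux (see
#' [slope_to_flux()] for the unit chain). The intercept (absolute ppm level)
#' does not enter: the flux is invariant to a constant ppm offset.
#'
#' @param trace a `conc_trace` (carries the gas and met conditions unless
#'   overridden).
#' @param window a `fit_window` from [select_window()].
#' @param geom a [chamber_geometry()].
#' @param met list with `Tair_K`, `pressure_Pa`; defaults to the trace's.
#' @param gas gas id; defaults to the trace's.
#' @return flux in mg gas m-2 h-1, emission positive.
#' @export
compute_flux <- function(trace, window, geom = chamber_geometry(),
                         met = NULL, gas = NULL) {
  if (is.null(met)) met <- trace$met
  if (is.null(gas)) gas <- trace$gas
  slope_to_flux(window$slope, gas, geom$headspace_height,
                met$Tair_K, met$pressure_Pa)
}

#' Assign quality-control flags to flux records
#'
#' Flag 0: fit R-squared above `r2_min`. Flag 1: poorer fit but a flux below
#' the gas-specific small-flux magnitude (near the analyzer detection limit,
#' where noisy traces are expected; such fluxes barely affect budgets but
#' matter for statistics). Flag 2: everything else. Thresholds are absolute
#' magnitudes for all gases.
#'
#' @param records data.frame with `gas`, `flux`, `r2` columns.
#' @param r2_min R-squared threshold for flag 0 (strict >).
#' @param small_flux named vector of small-flux magnitudes, mg gas m-2 h-1.
#' @return `records` with a `qc_flag` column (integer 0/1/2).
#' @export
assign_qc <- function(records, r2_min = 0.8,
                      small_flux = c(co2 = 100, ch4 = 0.1, n2o = 0.2)) {
  stopifnot(all(c("gas", "flux", "r2") %in% names(records)))
  thr <- small_flux[as.character(records$gas)]
  flag <- ifelse(records$r2 > r2_min, 0L,
                 ifelse(abs(records$flux) < thr, 1L, 2L))
  records$qc_flag <- flag
  records
}

#' Drop flag-2 records
#'
#' Keeps flags 0 and 1 for further analysis and reports the per-gas removal
#' fractions as the `"removed_fraction"` attribute.
#'
#' @param records data.frame with `gas` and `qc_flag`.
#' @return filtered data.frame.
#' @export
filter_records <- function(records) {
  stopifnot("qc_flag" %in% names(records))
  removed <- tapply(records$qc_flag == 2L, records$gas, mean)
  kept <- records[records$qc_flag != 2L, , drop = FALSE]
  attr(kept, "removed_fraction") <- removed
  kept
}

#' Process a batch of campaign traces into quality-flagged flux records
#'
#' Runs the dynamic-window fit and the flux conversion over every closure of
#' a (synthetic or equivalently formatted) campaign, then assigns QC flags.
#'
#' @param campaign a [gen_campaign()] result, or a list with `traces` (long
#'   data.frame: `measurement_id`, `gas`, `t_s`, `ppm`) and `measurements`
#'   (one row per closure with `measurement_id`, `chamber_id`, `plot`,
#'   `fertilization`, `timestamp`, `Tair`).
#' @param geom a [chamber_geometry()].
#' @param pressure_pa air pressure, Pa.
#' @param min_window_s,step_s dynamic-window settings, see [select_window()].
#' @return data.frame of flux records with fit-window fields and `qc_flag`.
#' @export
process_traces <- function(campaign, geom = chamber_geometry(),
                           pressure_pa = 101325,
                           min_window_s = 240, step_s = 10) {
  traces <- campaign$traces
  meas <- campaign$measurements
  out <- vector("list", length(.GASES))
  names(out) <- .GASES
  for (g in .GASES) {
    tr <- traces[traces$gas == g, , drop = FALSE]
    if (!nrow(tr)) next
    ids <- unique(tr$measurement_id)
    nt <- sum(tr$measurement_id == ids[1])
    ppm <- matrix(tr$ppm, nrow = nt) # generator emits fixed-length closures
    w <- .window_search(ppm, min_window_s, step_s)
    m <- meas[match(ids, meas$measurement_id), , drop = FALSE]
    flux <- slope_to_flux(w$slope, g, geom$headspace_height,
                          m$Tair + 273.15, pressure_pa)
    out[[g]] <- data.frame(
      measurement_id = ids, gas = g, flux = flux,
      start_s = w$start_s, end_s = w$end_s, n = w$n,
      slope = w$slope, r2 = w$r2,
      chamber_id = m$chamber_id, plot = m$plot,
      fertilization = m$fertilization, timestamp = m$timestamp
    )
  }
  assign_qc(do.call(rbind, out))
}
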