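#' GWP100 factors
#'
#' Mass-based 100-year global warming potentials: 27 t CO2-eq per t CH4 and
#' 273 per t N2O.
#'
#' @param ch4,n2o multipliers.
#' @return named list.
#' @export
gwp_factors <- function(ch4 = 27, n2o = 273) {
  stopifnot(ch4 > 0, n2o > 0)
  list(ch4 = ch4, n2o = n2o)
}

#' Off-season extrapolation rules
#'
#' Outside the May-October measurement season (November-April, 6 months)
#' the CO2 flux is assumed constant at `co2_rate` g C m-2 month-1 and the
#' off-season CH4 flux is taken as `ch4_offseason_fraction` of the annual
#' total. No off-season rule exists for N2O; its annual total equals the
#' seasonal total (conservative).
#'
#' @param co2_rate g C m-2 month-1.
#' @param ch4_offseason_fraction fraction of the annual CH4 total in (0,1).
#' @param months_offseason number of off-season months.
#' @return named list.
#' @export
offseason_rules <- function(co2_rate = 1.5, ch4_offseason_fraction = 0.15,
                            months_offseason = 6) {
  stopifnot(ch4_offseason_fraction > 0, ch4_offseason_fraction < 1)
  list(co2_rate = co2_rate,
       ch4_offseason_fraction = ch4_offseason_fraction,
       months_offseason = months_offseason)
}

#' Integrate hourly fluxes to seasonal totals
#'
#' Sums complete hourly series per chamber over the season window and
#' converts mg m-2 (summed mg m-2 h-1 over hours) to t ha-1 with the factor
#' 1e-5. Any missing hour is a hard error: gap-fill first. Per-tree sums,
#' if supplied, are converted alongside.
#'
#' @param hourly data.frame (`chamber_id`, `time`, `flux`), e.g. from
#'   [predict_hourly()].
#' @param window_start,window_end season bounds (dates).
#' @param tree_sums optional chambers x trees matrix of summed hourly
#'   fluxes (mg m-2 h-1) as produced by [predict_hourly()].
#' @return list: `chamber_totals` (named vector, t gas ha-1) and
#'   `tree_totals` (matrix, t gas ha-1, or NULL).
#' @export
integrate_seasonal <- function(hourly, window_start = NULL,
                               window_end = NULL, tree_sums = NULL) {
  if (!is.null(window_start)) {
    hourly <- hourly[as.Date(hourly$time) >= as.Date(window_start) &
                       as.Date(hourly$time) <= as.Date(window_end), ,
                     drop = FALSE]
  }
  if (anyNA(hourly$flux)) {
    bad <- hourly$time[is.na(hourly$flux)]
    stop("residual gaps at: ", paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) sprintf(" (+%d more)", length(bad) - 5))
  }
  n_hours <- table(hourly$chamber_id)
  if (length(unique(n_hours)) > 1) {
    warning("chambers cover unequal numbers of hours")
  }
  tot <- tapply(hourly$flux, hourly$chamber_id, sum) * 1e-5
  totals <- stats::setNames(as.numeric(tot), names(tot))
  tree_totals <- if (!is.null(tree_sums)) tree_sums * 1e-5 else NULL
  list(chamber_totals = totals, tree_totals = tree_totals)
}

#' Convert per-gas totals to CO2 equivalents
#'
#' CO2-eq = CO2 + 27 CH4 + 273 N2O (same mass units in and out); linear, so
#' it commutes with sums and means.
#'
#' @param co2,ch4,n2o totals, t gas ha-1 (vectors recycle).
#' @param gwp a [gwp_factors()].
#' @return CO2-eq totals, t CO2-eq ha-1.
#' @export
to_co2eq <- function(co2, ch4, n2o, gwp = gwp_factors()) {
  co2 + gwp$ch4 * ch4 + gwp$n2o * n2o
}

#' Extrapolate seasonal totals to annual totals
#'
#' Annual CO2 adds the off-season months at the assumed constant rate
#' (converted from g C m-2 to t CO2 ha-1 via 44.01/12.011 and 1 g m-2 =
#' 0.01 t ha-1); annual CH4 solves seasonal = (1 - fraction) x annual; N2O
#' carries over unchanged.
#'
#' @param seasonal seasonal total, t gas ha-1.
#' @param gas gas id.
#' @param rules an [offseason_rules()].
#' @return annual total, t gas ha-1.
#' @export
annualize <- function(seasonal, gas, rules = offseason_rules()) {
  gas <- gas_id(gas)
  switch(gas,
    co2 = seasonal +
      rules$months_offseason * rules$co2_rate * (44.01 / 12.011) * 1e-2,
    ch4 = seasonal / (1 - rules$ch4_offseason_fraction),
    n2o = seasonal)
}

#' Net ecosystem carbon balance
#'
#' C loss = CO2 x 12.011/44.01 + CH4 x 12.011/16.04 + c_fraction x harvested
#' dry biomass; positive = carbon lost from the ecosystem. N2O carries no
#' carbon and is excluded.
#'
#' @param co2_t,ch4_t seasonal (or annual) gas totals, t gas ha-1.
#' @param biomass_t harvested dry biomass, t ha-1.
#' @param c_fraction carbon fraction of dry biomass.
#' @return net C balance, t C ha-1.
#' @export
net_c_balance <- function(co2_t, ch4_t = 0, biomass_t = 0,
                          c_fraction = 0.43) {
  stopifnot(all(biomass_t >= 0))
  co2_t * 12.011 / 44.01 + ch4_t * 12.011 / 16.04 + c_fraction * biomass_t
}

#' Photoperiod counterfactual: no radiation between 20:00 and 04:00
#'
#' Re-predicts the hourly CO2 series with global radiation forced to zero in
#' the stated local-time window and integrates both series; the difference
#' (counterfactual minus factual, per chamber) quantifies how much the long
#' daylight reduces net emissions. Both sides use model predictions
#' throughout so the contrast is purely the radiation forcing.
#'
#' @param fit a CO2 `ghg_rf`.
#' @param drivers a [gen_drivers()] table.
#' @param chambers chamber table.
#' @param dark_from,dark_to window bounds, local hours (wraps midnight).
#' @param n_plots number of plots.
#' @return list: `delta` per chamber (t CO2 ha-1 season-1, expected >= 0),
#'   `factual`, `counterfactual` chamber totals.
#' @export
photoperiod_counterfactual <- function(fit, drivers, chambers,
                                       dark_from = 20, dark_to = 4,
                                       n_plots = 5) {
  dark <- drivers$hour >= dark_from | drivers$hour < dark_to
  cf_drivers <- drivers
  cf_drivers$Rg[dark] <- 0
  fact <- predict_hourly(fit, drivers, chambers, n_plots = n_plots)
  cf <- predict_hourly(fit, cf_drivers, chambers, n_plots = n_plots)
  ft <- integrate_seasonal(fact$hourly)$chamber_totals
  ct <- integrate_seasonal(cf$hourly)$chamber_totals
  list(delta = ct - ft, factual = ft, counterfactual = ct)
}

#' Hot-moment contribution to a budget
#'
#' Hot moments are records whose flux exceeds mean + k SD of the flux
#' distribution; their summed contribution is reported as a fraction of the
#' total. Undefined (NA, flagged) when the total is not positive. A
#' degenerate SD of zero yields no hot moments and a fraction of zero.
#'
#' @param flux vector of flux records (equal time weights).
#' @param k SD multiplier.
#' @return list: `fraction`, `n_hot`, `threshold`, `defined`.
#' @export
hot_moment_fraction <- function(flux, k = 4) {
  if (length(flux) < 2) stop("need at least 2 records")
  thr <- mean(flux) + k * stats::sd(flux)
  hot <- flux > thr
  total <- sum(flux)
  if (total <= 0) {
    return(list(fraction = NA_real_, n_hot = sum(hot), threshold = thr,
                defined = FALSE))
  }
  list(fraction = sum(flux[hot]) / total, n_hot = sum(hot),
       threshold = thr, defined = TRUE)
}

#' Partition budget uncertainty into replicate and bootstrap components
#'
#' Replicate variance is the variance across the chamber totals of one
#' subplot; bootstrap variance is the mean (over chambers) of each
#' chamber's variance across per-tree totals.
#'
#' @param chamber_totals numeric vector of per-chamber seasonal totals.
#' @param tree_totals chambers x trees matrix of per-tree totals.
#' @return list: `replicate_var`, `bootstrap_var` (same squared units).
#' @export
uncertainty_partition <- function(chamber_totals, tree_totals) {
  rep_var <- if (length(chamber_totals) >= 2) stats::var(chamber_totals)
             else NA_real_
  boot_var <- mean(apply(tree_totals, 1, stats::var))
  list(replicate_var = rep_var, bootstrap_var = boot_var)
}

#' Subplot budget table across gases
#'
#' Aggregates per-chamber seasonal totals to subplot level (mean of the
#' replicate chambers), adds CO2-equivalents, annual totals, net C balance
#' with harvest removal, and the replicate/bootstrap variance partition.
#'
#' @param totals named list (per gas) of [integrate_seasonal()] results.
#' @param chambers chamber table (`chamber_id`, `plot`, `fertilization`,
#'   `subplot`).
#' @param biomass biomass table (`chamber_id`, `dry_biomass_t_ha`), summed
#'   per chamber over harvests.
#' @param gwp a [gwp_factors()].
#' @param rules an [offseason_rules()].
#' @param c_fraction carbon fraction of dry biomass.
#' @return data.frame, one row per subplot.
#' @export
subplot_budgets <- function(totals, chambers, biomass = NULL,
                            gwp = gwp_factors(), rules = offseason_rules(),
                            c_fraction = 0.43) {
  subplots <- unique(chambers[, c("subplot", "plot", "fertilization")])
  rows <- vector("list", nrow(subplots))
  for (i in seq_len(nrow(subplots))) {
    ch <- chambers$chamber_id[chambers$subplot == subplots$subplot[i]]
    per_gas <- sapply(.GASES, function(g) {
      mean(totals[[g]]$chamber_totals[as.character(ch)])
    })
    vars <- lapply(.GASES, function(g) {
      idx <- match(as.character(ch), names(totals[[g]]$chamber_totals))
      uncertainty_partition(
        totals[[g]]$chamber_totals[idx],
        totals[[g]]$tree_totals[idx, , drop = FALSE])
    })
    names(vars) <- .GASES
    bio <- 0
    if (!is.null(biomass)) {
      b <- biomass[biomass$chamber_id %in% ch, , drop = FALSE]
      bio <- sum(b$dry_biomass_t_ha) / length(ch)
    }
    rows[[i]] <- data.frame(
      subplot = subplots$subplot[i], plot = subplots$plot[i],
      fertilization = subplots$fertilization[i],
      co2_t_ha = per_gas[["co2"]], ch4_t_ha = per_gas[["ch4"]],
      n2o_t_ha = per_gas[["n2o"]],
      co2eq_t_ha = to_co2eq(per_gas[["co2"]], per_gas[["ch4"]],
                            per_gas[["n2o"]], gwp),
      co2_annual_t_ha = annualize(per_gas[["co2"]], "co2", rules),
      ch4_annual_t_ha = annualize(per_gas[["ch4"]], "ch4", rules),
      n2o_annual_t_ha = annualize(per_gas[["n2o"]], "n2o", rules),
      biomass_t_ha = bio,
      net_c_t_ha = net_c_balance(per_gas[["co2"]], per_gas[["ch4"]],
                                 bio, c_fraction),
      co2_replicate_var = vars$co2$replicate_var,
      co2_bootstrap_var = vars$co2$bootstrap_var,
      ch4_replicate_var = vars$ch4$replicate_var,
      ch4_bootstrap_var = vars$ch4$bootstrap_var,
      n2o_replicate_var = vars$n2o$replicate_var,
      n2o_bootstrap_var = vars$n2o$bootstrap_var
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
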