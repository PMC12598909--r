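# the 13 model predictors, in reporting order
.PREDICTORS <- c("plot_id", "fertilization", "Rg", "WTL", "WS", "VPD",
                 "DOY", "PPT", "Ts5", "Ts50", "Tair",
                 "days_since_harvest", "days_since_fertilization")

# hourly driver/feature rows for a set of chambers (one block per chamber)
.chamber_feature_rows <- function(drivers, chambers, n_plots) {
  out <- vector("list", nrow(chambers))
  for (i in seq_len(nrow(chambers))) {
    d <- drivers[drivers$plot == chambers$plot[i], , drop = FALSE]
    f <- data.frame(
      chamber_id = chambers$chamber_id[i], time = d$time,
      plot_id = factor(chambers$plot[i], levels = seq_len(n_plots)),
      fertilization = factor(chambers$fertilization[i],
                             levels = c("high", "low")),
      Rg = d$Rg, WTL = d$WTL, WS = d$WS, VPD = d$VPD, DOY = d$doy,
      PPT = d$PPT, Ts5 = d$Ts5, Ts50 = d$Ts50, Tair = d$Tair,
      days_since_harvest = d$days_since_harvest,
      days_since_fertilization = d$days_since_fertilization
    )
    out[[i]] <- f
  }
  do.call(rbind, out)
}

#' Build the model feature matrix for one gas
#'
#' Joins retained flux records to the hourly driver table of each record's
#' plot at the record's timestamp, yielding one row per record with the 13
#' predictors (plot id, fertilization, global radiation, WTL, wind speed,
#' VPD, day of year, precipitation, soil temperature at 5 and 50 cm, air
#' temperature, days since harvest and days since fertilization) plus the
#' flux target. Event clocks come from the driver table, which uses the most
#' recent preceding event and a 365-day sentinel before a season's first
#' event. Records whose driver hour is missing are dropped with a message.
#'
#' @param records flux records of one gas (post [filter_records()]).
#' @param drivers a [gen_drivers()] table.
#' @param n_plots number of plots (factor levels of `plot_id`).
#' @return data.frame: `flux`, the 13 predictors, `chamber_id`,
#'   `measurement_id`, `timestamp`.
#' @export
build_features <- function(records, drivers, n_plots = 5) {
  stopifnot(length(unique(records$gas)) <= 1)
  key_r <- paste(records$plot, records$timestamp)
  key_d <- paste(drivers$plot, drivers$time)
  i <- match(key_r, key_d)
  if (anyNA(i)) {
    message(sum(is.na(i)), " record(s) without a driver hour dropped")
    records <- records[!is.na(i), , drop = FALSE]
    i <- i[!is.na(i)]
  }
  d <- drivers[i, , drop = FALSE]
  data.frame(
    flux = records$flux,
    plot_id = factor(records$plot, levels = seq_len(n_plots)),
    fertilization = factor(records$fertilization, levels = c("high", "low")),
    Rg = d$Rg, WTL = d$WTL, WS = d$WS, VPD = d$VPD, DOY = d$doy,
    PPT = d$PPT, Ts5 = d$Ts5, Ts50 = d$Ts50, Tair = d$Tair,
    days_since_harvest = d$days_since_harvest,
    days_since_fertilization = d$days_since_fertilization,
    chamber_id = records$chamber_id,
    measurement_id = records$measurement_id,
    timestamp = records$timestamp
  )
}
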