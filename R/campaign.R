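#' Generate a complete synthetic chamber campaign with known ground truth
#'
#' Emulates the field campaign end to end: hourly drivers ([gen_drivers()]),
#' a chamber table (plots x {high, low} fertilization x replicate chambers,
#' with mild lognormal chamber-to-chamber heterogeneity), hourly true fluxes
#' per chamber and gas, a closure schedule (each chamber once per
#' measurement cycle, chambers staggered across the cycle), noisy 1-Hz
#' closure traces for every scheduled and retained closure, and harvested
#' dry biomass per chamber with a multiplicative fertilization effect.
#'
#' Seeding is split so the field truth and the measurement realisation can
#' be varied independently: `config$seed` fixes drivers, chamber
#' heterogeneity and biomass; `seed` fixes the observation schedule
#' subsampling and the trace noise.
#'
#' @param config a [campaign_config()].
#' @param params a [true_flux_params()].
#' @param geom a [chamber_geometry()].
#' @param noise per-gas noise list from [campaign_noise()].
#' @param seed integer seed for schedule subsampling and trace noise.
#' @param obs_fraction fraction of scheduled closures actually measured
#'   (the rest are data gaps to be gap-filled).
#' @param gaps optional list of `c(start, end)` date pairs; closures inside
#'   any pair are removed (power/instrument outages).
#' @param make_traces set `FALSE` to skip 1-Hz trace synthesis and keep only
#'   schedule + truth (cheap, for tests that start from fluxes).
#' @param chamber_sd lognormal SD of per-chamber flux multipliers. The
#'   default truth surfaces are identical for the chambers of a subplot
#'   (replicate chambers sample the same surface); set a positive value to
#'   inject known chamber-level heterogeneity, e.g. for studying the
#'   replicate variance component.
#' @return list with `drivers`, `chambers`, `measurements` (one row per
#'   retained closure, incl. true fluxes), `traces` (long 1-Hz data.frame),
#'   `truth` (hourly true flux per chamber and gas), `biomass`, `events`,
#'   and the input objects.
#' @export
gen_campaign <- function(config = campaign_config(),
                         params = true_flux_params(),
                         geom = chamber_geometry(),
                         noise = campaign_noise(),
                         seed = 1L,
                         obs_fraction = 0.2,
                         gaps = NULL,
                         make_traces = TRUE,
                         chamber_sd = 0) {
  stopifnot(obs_fraction > 0, obs_fraction <= 1)
  drivers <- gen_drivers(config)

  n_sub <- config$n_plots * 2
  chambers <- data.frame(
    chamber_id = seq_len(n_sub * config$n_chambers_per_subplot),
    plot = rep(seq_len(config$n_plots), each = 2 * config$n_chambers_per_subplot),
    fertilization = rep(rep(c("high", "low"),
                            each = config$n_chambers_per_subplot),
                        times = config$n_plots)
  )
  chambers$subplot <- paste0("P", chambers$plot, "_", chambers$fertilization)

  # field-truth randomness rides on config$seed
  set.seed(config$seed + 1L)
  n_ch <- nrow(chambers)
  mult <- matrix(stats::rlnorm(n_ch * 3, 0, chamber_sd), n_ch, 3,
                 dimnames = list(NULL, .GASES))

  truth <- vector("list", n_ch)
  for (i in seq_len(n_ch)) {
    d <- drivers[drivers$plot == chambers$plot[i], , drop = FALSE]
    truth[[i]] <- data.frame(
      chamber_id = chambers$chamber_id[i], time = d$time,
      co2 = true_flux("co2", d, params, chambers$fertilization[i]) * mult[i, "co2"],
      ch4 = true_flux("ch4", d, params, chambers$fertilization[i]) * mult[i, "ch4"],
      n2o = true_flux("n2o", d, params, chambers$fertilization[i]) * mult[i, "n2o"]
    )
  }
  truth <- do.call(rbind, truth)

  # biomass: lognormal around plot means, fixed fertilization effect
  n_harv <- length(config$harvest_dates)
  plot_mean <- 2.5 * seq(0.9, 1.1, length.out = config$n_plots)
  bio <- expand.grid(chamber_id = chambers$chamber_id,
                     harvest_date = config$harvest_dates)
  bio <- merge(bio, chambers, by = "chamber_id")
  bio$dry_biomass_t_ha <- plot_mean[bio$plot] / n_harv *
    ifelse(bio$fertilization == "high", 1.35, 1) *
    stats::rlnorm(nrow(bio), 0, 0.15)

  # closure schedule: chambers staggered across the measurement cycle
  set.seed(seed)
  offset <- (chambers$chamber_id - 1) %% config$measurement_cycle_h
  sched <- vector("list", n_ch)
  for (i in seq_len(n_ch)) {
    d <- drivers[drivers$plot == chambers$plot[i] &
                   drivers$hour %% config$measurement_cycle_h == offset[i], ,
                 drop = FALSE]
    sched[[i]] <- data.frame(chamber_id = chambers$chamber_id[i],
                             time = d$time, date = d$date, Tair = d$Tair)
  }
  sched <- do.call(rbind, sched)
  if (!is.null(gaps)) {
    for (gp in gaps) {
      gp <- as.Date(gp)
      sched <- sched[!(sched$date >= gp[1] & sched$date <= gp[2]), ,
                     drop = FALSE]
    }
  }
  keep <- stats::runif(nrow(sched)) < obs_fraction
  sched <- sched[keep, , drop = FALSE]
  sched <- sched[order(sched$time, sched$chamber_id), , drop = FALSE]
  sched$measurement_id <- seq_len(nrow(sched))

  meas <- merge(sched, chambers, by = "chamber_id")
  meas <- meas[order(meas$measurement_id), , drop = FALSE]
  tkey <- paste(meas$chamber_id, meas$time)
  ti <- match(tkey, paste(truth$chamber_id, truth$time))
  meas$true_co2 <- truth$co2[ti]
  meas$true_ch4 <- truth$ch4[ti]
  meas$true_n2o <- truth$n2o[ti]
  names(meas)[names(meas) == "time"] <- "timestamp"
  rownames(meas) <- NULL

  traces <- NULL
  if (make_traces && nrow(meas)) {
    nt <- round(config$closure_min * 60)
    per_gas <- vector("list", 3)
    for (k in seq_along(.GASES)) {
      g <- .GASES[k]
      ppm <- .gen_trace_matrix(meas[[paste0("true_", g)]], g, geom,
                               meas$Tair + 273.15, 101325,
                               config$closure_min, noise[[g]])
      per_gas[[k]] <- data.frame(
        measurement_id = rep(meas$measurement_id, each = nt),
        gas = g,
        t_s = rep(seq_len(nt) - 1L, times = nrow(meas)),
        ppm = as.numeric(ppm)
      )
    }
    traces <- do.call(rbind, per_gas)
  }

  list(config = config, params = params, geom = geom, noise = noise,
       drivers = drivers, chambers = chambers, measurements = meas,
       traces = traces, truth = truth, biomass = bio,
       events = list(fertilization = config$fertilization_dates,
                     harvest = config$harvest_dates))
}

#' Write a synthetic campaign to plain-text CSV files
#'
#' Writes `drivers.csv`, `measurements.csv`, `truth.csv`, `biomass.csv` and
#' (if present) `traces.csv` into `dir`.
#'
#' @param campaign a [gen_campaign()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_campaign_csv <- function(campaign, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(campaign$drivers, file.path(dir, "drivers.csv"),
                   row.names = FALSE)
  utils::write.csv(campaign$measurements, file.path(dir, "measurements.csv"),
                   row.names = FALSE)
  utils::write.csv(campaign$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  utils::write.csv(campaign$biomass, file.path(dir, "biomass.csv"),
                   row.names = FALSE)
  if (!is.null(campaign$traces)) {
    utils::write.csv(campaign$traces, file.path(dir, "traces.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
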