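#' Solar elevation angle
#'
#' Simple declination/hour-angle geometry; adequate for clear-sky radiation
#' shapes including polar day above the Arctic circle.
#'
#' @param doy day of year (1-366).
#' @param hour local solar hour (0-23, fractional allowed).
#' @param latitude_deg degrees north.
#' @return elevation in degrees (negative below the horizon).
#' @export
solar_elevation <- function(doy, hour, latitude_deg) {
  decl <- 23.44 * pi / 180 * sin(2 * pi * (284 + doy) / 365)
  lat <- latitude_deg * pi / 180
  h <- (hour - 12) / 12 * pi
  sin_e <- sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(h)
  asin(pmin(1, pmax(-1, sin_e))) * 180 / pi
}

# first-order low-pass y[t] = (1-k) y[t-1] + k x[t]
.damp <- function(x, k, init = x[1]) {
  as.numeric(stats::filter(k * x, 1 - k, method = "recursive",
                           init = init))
}

# days since the most recent preceding event; sentinel before the first one
.event_clock <- function(dates, events, sentinel = 365) {
  if (!length(events)) return(rep(sentinel, length(dates)))
  ev <- sort(as.numeric(as.Date(events)))
  d <- as.numeric(as.Date(dates))
  idx <- findInterval(d, ev)
  out <- rep(sentinel, length(d))
  has <- idx > 0
  out[has] <- d[has] - ev[idx[has]]
  out
}

#' Generate hourly environmental drivers for a synthetic campaign
#'
#' Produces an hourly table per plot covering the season. Global radiation is
#' a deterministic clear-sky curve scaled to peak near 300 W m-2 at the site
#' latitude (continuous daylight near the solstice at 69.5 deg N); air
#' temperature is a seasonal bump peaking in late July (~15 C summer mean,
#' subzero by late October) with a diurnal cycle and AR(1) weather noise;
#' soil temperatures at 5 and 50 cm are damped, lagged transforms of air
#' temperature; the water table per plot follows a plot-specific summer
#' drawdown spanning about -1.6 m (driest) to -0.2 m (wettest). Event clocks
#' (days since fertilization/harvest) are included. Deterministic for a given
#' `config$seed`.
#'
#' @param config a [campaign_config()].
#' @return data.frame keyed by (`time`, `plot`) with columns `Rg`, `Tair`,
#'   `Ts5`, `Ts50`, `WTL`, `WS`, `VPD`, `PPT`, `days_since_fertilization`,
#'   `days_since_harvest` plus calendar helpers `date`, `doy`, `hour`.
#' @export
gen_drivers <- function(config) {
  stopifnot(inherits(config, "campaign_config"))
  set.seed(config$seed)
  t0 <- as.POSIXct(paste(config$season_start, "00:00:00"), tz = "UTC")
  t1 <- as.POSIXct(paste(config$season_end, "23:00:00"), tz = "UTC")
  time <- seq(t0, t1, by = "hour")
  n <- length(time)
  lt <- as.POSIXlt(time)
  doy <- lt$yday + 1
  hour <- lt$hour
  fdoy <- doy + hour / 24

  elev <- solar_elevation(doy, hour, config$latitude_deg)
  rg <- 430 * pmax(sin(elev * pi / 180), 0)

  tair <- -3 + 21 * exp(-0.5 * ((fdoy - 200) / 50)^2) +
    3 * sin(2 * pi * (hour - 9) / 24) +
    as.numeric(stats::filter(stats::rnorm(n, sd = 0.45), 0.97,
                             method = "recursive"))
  ts5 <- .damp(tair, 1 / 72)          # ~3 day memory
  ts50 <- .damp(tair, 1 / 480)        # ~20 day memory

  ws <- pmax(0.2, 3 + as.numeric(stats::filter(stats::rnorm(n, sd = 0.5),
                                               0.9, method = "recursive")))
  rh <- pmin(0.99, pmax(0.3, 0.75 + as.numeric(
    stats::filter(stats::rnorm(n, sd = 0.03), 0.9, method = "recursive"))))
  esat <- 0.6108 * exp(17.27 * tair / (tair + 237.3)) # kPa
  vpd <- pmax(0, esat * (1 - rh))
  ppt <- ifelse(stats::runif(n) < 0.04, stats::rexp(n, rate = 1 / 1.5), 0)

  spring <- seq(-0.6, -0.2, length.out = config$n_plots)
  amp <- seq(1.0, 0.45, length.out = config$n_plots)
  drawdown <- exp(-0.5 * ((fdoy - 185) / 40)^2)

  dsf <- .event_clock(as.Date(time), config$fertilization_dates)
  dsh <- .event_clock(as.Date(time), config$harvest_dates)

  out <- vector("list", config$n_plots)
  for (p in seq_len(config$n_plots)) {
    wtl_noise <- 0.03 * as.numeric(stats::filter(
      stats::rnorm(n, sd = 0.05), 0.995, method = "recursive"))
    wtl <- pmin(-0.05, spring[p] - amp[p] * drawdown + wtl_noise)
    out[[p]] <- data.frame(
      time = time, date = as.Date(time), doy = doy, hour = hour,
      plot = p, Rg = rg, Tair = tair, Ts5 = ts5, Ts50 = ts50,
      WTL = wtl, WS = ws, VPD = vpd, PPT = ppt,
      days_since_fertilization = dsf, days_since_harvest = dsh
    )
  }
  do.call(rbind, out)
}
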