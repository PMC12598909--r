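test_that("polar-day radiation never reaches zero at 69.5 N solstice", {
  cfg <- campaign_config(season_start = "2022-06-15",
                         season_end = "2022-06-25",
                         fertilization_dates = "2022-06-16",
                         harvest_dates = "2022-06-20", seed = 1)
  d <- gen_drivers(cfg)
  j <- d[d$plot == 1 & format(d$time, "%m-%d") == "06-21", ]
  expect_equal(nrow(j), 24)
  expect_true(all(j$Rg > 0))
})

test_that("equatorial day length is about 12 hours", {
  cfg <- campaign_config(season_start = "2022-05-01",
                         season_end = "2022-05-10", latitude_deg = 0,
                         fertilization_dates = "2022-05-02",
                         harvest_dates = "2022-05-05", seed = 1)
  d <- gen_drivers(cfg)
  dark_per_day <- tapply(d$Rg[d$plot == 1] == 0, d$date[d$plot == 1], sum)
  expect_true(all(dark_per_day >= 10 & dark_per_day <= 14))
})

test_that("drivers are deterministic given the seed and span the WTL range", {
  cfg <- campaign_config(seed = 5)
  d1 <- gen_drivers(cfg)
  d2 <- gen_drivers(cfg)
  expect_identical(d1, d2)
  expect_lt(min(d1$WTL), -1.4)            # driest plot approaches -1.6 m
  expect_gt(max(d1$WTL), -0.3)            # wettest plot approaches -0.2 m
  expect_true(all(d1$WTL < 0))
  expect_true(all(d1$days_since_fertilization >= 0))
})

test_that("true CO2 flux at zero light is the respiration term", {
  p <- true_flux_params()
  row <- data.frame(Rg = 0, Ts5 = 10, WTL = p$wtl_ref,
                    days_since_harvest = 365, days_since_fertilization = 365)
  f <- true_flux("co2", row, p)
  expect_gt(f, 0)
  expect_equal(f, p$rd_ref, tolerance = 1e-10) # Q10 and WTL factors = 1
})

test_that("CH4 is negligible at deep water tables", {
  p <- true_flux_params(ch4_wtl_efold = 0.15)
  row <- data.frame(Rg = 0, Ts5 = 10, WTL = -1.2,
                    days_since_harvest = 365, days_since_fertilization = 365)
  # exp(-1.2/0.15) = exp(-8) ~ 3.4e-4
  expect_lt(true_flux("ch4", row, p), 0.01 * p$ch4_scale)
})

test_that("N2O pulse decays by 1/e per decay constant", {
  p <- true_flux_params()
  row <- function(dsf) data.frame(Rg = 0, Ts5 = 10, WTL = -1.0,
                                  days_since_harvest = 365,
                                  days_since_fertilization = dsf)
  at0 <- true_flux("n2o", row(0), p) - p$n2o_baseline
  at_tau <- true_flux("n2o", row(p$n2o_pulse_decay_d), p) - p$n2o_baseline
  expect_equal(at_tau / at0, exp(-1), tolerance = 1e-10)
  # low dosage halves the pulse
  expect_equal((true_flux("n2o", row(0), p, dose = "low") - p$n2o_baseline) /
                 at0, 0.5, tolerance = 1e-10)
})

test_that("flux surfaces are monotone in WTL in the expected directions", {
  p <- true_flux_params()
  grid <- data.frame(Rg = 150, Ts5 = 10, WTL = seq(-1.6, -0.1, by = 0.05),
                     days_since_harvest = 365,
                     days_since_fertilization = 365)
  co2 <- true_flux("co2", grid, p)
  ch4 <- true_flux("ch4", grid, p)
  expect_true(all(diff(co2) <= 1e-9))  # net CO2 emission falls toward wet
  expect_true(all(diff(ch4) >= -1e-9)) # CH4 rises toward wet
})

test_that("trace generator inverts the flux conversion exactly", {
  geom <- chamber_geometry()
  met <- list(Tair_K = 283.15, pressure_Pa = 101325)
  quiet <- trace_noise(sd_ppm = 0, curvature = 0)
  tr0 <- gen_trace(0, "co2", geom, met, noise = quiet)
  expect_equal(diff(range(tr0$ppm)), 0)
  # hand-inverted unit chain for 1000 mg CO2 m-2 h-1 at 283.15 K
  tr <- gen_trace(1000, "co2", geom, met, noise = quiet)
  expected_slope <- 1000 /
    (3600 * 0.6 * 1000 * 44.01 * 101325 / (8.314462618 * 283.15) * 1e-6)
  expect_equal(tr$true_slope, expected_slope, tolerance = 1e-9)
  w <- select_window(tr)
  expect_equal(compute_flux(tr, w, geom), 1000, tolerance = 1e-9)
})

test_that("negative noise sd is rejected", {
  expect_error(trace_noise(sd_ppm = -1), "non-negative")
})

test_that("campaign schedules 3 closures per chamber per day for 30 chambers", {
  camp <- small_campaign(obs_fraction = 1, make_traces = FALSE)
  m <- camp$measurements
  expect_equal(nrow(camp$chambers), 30)
  per <- table(m$chamber_id, as.Date(m$timestamp))
  expect_true(all(per == 3)) # 24 h / 8 h cycle
})

test_that("gap specifications remove all closures in the window", {
  camp <- small_campaign(obs_fraction = 1, make_traces = FALSE,
                         gaps = list(c("2022-06-03", "2022-06-04")))
  d <- as.Date(camp$measurements$timestamp)
  expect_false(any(d >= as.Date("2022-06-03") & d <= as.Date("2022-06-04")))
  expect_gt(nrow(camp$measurements), 0)
})

test_that("truth is tied to the config seed, trace noise to the campaign seed", {
  c1 <- small_campaign(seed = 1)
  c2 <- small_campaign(seed = 2)
  expect_identical(c1$truth, c2$truth)
  expect_false(identical(c1$traces$ppm, c2$traces$ppm))
  c1b <- small_campaign(seed = 1)
  expect_identical(c1$traces, c1b$traces) # full determinism per seed pair
})

test_that("event dates outside the season are rejected", {
  expect_error(campaign_config(fertilization_dates = "2023-02-01"),
               "inside the season")
})
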