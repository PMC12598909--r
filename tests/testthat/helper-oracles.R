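# Independent oracles used across test files.

# exhaustive dynamic-window search via lm() per candidate window
brute_force_window <- function(trace, min_window_s = 240, step_s = 10) {
  nt <- length(trace$ppm)
  best <- NULL
  for (s in seq(0, nt - min_window_s, by = step_s)) {
    i <- (s + 1):nt
    f <- stats::lm(trace$ppm[i] ~ trace$t_s[i])
    r2 <- summary(f)$r.squared
    if (is.null(best) || r2 > best$r2 + 1e-12) {
      best <- list(start_s = s, r2 = r2, slope = unname(stats::coef(f)[2]))
    }
  }
  best
}

# hyperbolic light-response curve, magnitude parameterization
lr_curve <- function(rg, a, g, rd) {
  ifelse(a * rg + g > 0, -(a * rg * g) / (a * rg + g), 0) + rd
}

# root-find the light compensation point directly from the curve
brute_force_lcp <- function(a, g, rd, upper = 1e7) {
  stats::uniroot(function(x) lr_curve(x, a, g, rd), c(0, upper),
                 tol = 1e-12)$root
}

# small fast campaign for structural tests: 6 days, full observation
small_campaign <- function(seed = 1L, obs_fraction = 1, gaps = NULL,
                           make_traces = TRUE, chamber_sd = 0,
                           noise = campaign_noise()) {
  cfg <- campaign_config(season_start = "2022-06-01",
                         season_end = "2022-06-06",
                         fertilization_dates = "2022-06-02",
                         harvest_dates = c("2022-06-03", "2022-06-05"),
                         seed = 11L)
  gen_campaign(cfg, seed = seed, obs_fraction = obs_fraction, gaps = gaps,
               make_traces = make_traces, chamber_sd = chamber_sd,
               noise = noise)
}

# synthetic feature matrix with a known smooth response, for RF unit tests
toy_features <- function(n = 400, n_chambers = 12, seed = 1L) {
  set.seed(seed)
  f <- data.frame(
    plot_id = factor(sample(1:5, n, TRUE), levels = 1:5),
    fertilization = factor(sample(c("high", "low"), n, TRUE),
                           levels = c("high", "low")),
    Rg = runif(n, 0, 300), WTL = runif(n, -1.6, -0.2),
    WS = runif(n, 0, 8), VPD = runif(n, 0, 2),
    DOY = sample(121:304, n, TRUE), PPT = rexp(n, 1),
    Ts5 = runif(n, 2, 16), Ts50 = runif(n, 4, 12),
    Tair = runif(n, 0, 22),
    days_since_harvest = sample(0:80, n, TRUE),
    days_since_fertilization = sample(0:80, n, TRUE),
    chamber_id = sample(seq_len(n_chambers), n, TRUE),
    measurement_id = seq_len(n)
  )
  f$flux <- 500 - 2 * f$Rg + 300 * f$WTL + 20 * f$Ts5 + rnorm(n, 0, 20)
  f$timestamp <- as.POSIXct("2022-06-01", tz = "UTC") + f$DOY * 3600
  f
}
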