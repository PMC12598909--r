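test_that("the seasonal integration constant survives dimensional analysis", {
  # 1 mg m-2 h-1 for 1 h = 1 mg m-2 = 10 g ha-1 = 1e-5 t ha-1
  h <- data.frame(chamber_id = 1,
                  time = as.POSIXct("2022-05-01", tz = "UTC"),
                  flux = 1)
  expect_equal(unname(integrate_seasonal(h)$chamber_totals), 1e-5)
  # constant 100 mg CO2 m-2 h-1 over the 4416-hour season: 4.416 t ha-1
  times <- seq(as.POSIXct("2022-05-01 00:00", tz = "UTC"),
               as.POSIXct("2022-10-31 23:00", tz = "UTC"), by = "hour")
  expect_equal(length(times), 4416)
  h2 <- data.frame(chamber_id = 1, time = times, flux = 100)
  expect_equal(unname(integrate_seasonal(h2)$chamber_totals), 4.416)
  expect_equal(unname(integrate_seasonal(
    transform(h2, flux = 0))$chamber_totals), 0)
  expect_lt(unname(integrate_seasonal(
    transform(h2, flux = -50))$chamber_totals), 0)
  expect_error(integrate_seasonal(transform(h2, flux = NA)), "gaps")
})

test_that("GWP100 conversion uses 27 and 273 and is linear", {
  expect_equal(to_co2eq(0, 1, 0), 27)
  expect_equal(to_co2eq(0, 0, 1), 273)
  expect_equal(to_co2eq(5, 0, 0), 5)
  a <- c(1.2, 0.3, 0.01)
  b <- c(-0.5, 0.1, 0.02)
  expect_equal(to_co2eq(a[1] + b[1], a[2] + b[2], a[3] + b[3]),
               to_co2eq(a[1], a[2], a[3]) + to_co2eq(b[1], b[2], b[3]))
})

test_that("annual extrapolation applies the off-season rules exactly", {
  # 6 months x 1.5 g C m-2 month-1 = 9 g C m-2 = 0.33 t CO2 ha-1
  expect_equal(annualize(0, "co2"), 6 * 1.5 * (44.01 / 12.011) * 1e-2)
  expect_equal(annualize(0, "co2"), 0.33, tolerance = 0.005)
  # off-season CH4 is 15% of the annual total
  expect_equal(annualize(0.85, "ch4"), 1)
  expect_equal(annualize(0, "ch4"), 0)
  expect_equal(annualize(0.4, "n2o"), 0.4) # no off-season rule for N2O
})

test_that("net carbon balance combines stoichiometry and the 43% biomass rule", {
  expect_equal(net_c_balance(0, 0, 10), 4.3)
  expect_equal(net_c_balance(-44.01, 0, 0), -12.011)
  expect_equal(net_c_balance(0, 16.04, 0), 12.011)
})

test_that("hot-moment fractions match brute-force enumeration", {
  expect_equal(hot_moment_fraction(rep(5, 50))$fraction, 0)
  x <- c(rep(0, 99), 1000)
  hm <- hot_moment_fraction(x)
  thr <- mean(x) + 4 * sd(x)
  expect_equal(hm$threshold, thr)
  expect_equal(hm$fraction, sum(x[x > thr]) / sum(x))
  expect_equal(hm$n_hot, 1)
  # negative-total budgets leave the fraction undefined but flagged
  hm2 <- hot_moment_fraction(c(-5, -4, -6, 1))
  expect_false(hm2$defined)
  expect_true(is.na(hm2$fraction))
  # random sets: enumeration oracle
  set.seed(8)
  for (i in 1:20) {
    y <- rexp(200, 1 / 10) * sample(c(1, 50), 200, TRUE, prob = c(.97, .03))
    hm3 <- hot_moment_fraction(y)
    hot <- y[y > mean(y) + 4 * sd(y)]
    expect_equal(hm3$fraction, sum(hot) / sum(y))
  }
})

test_that("variance partition separates replicate and bootstrap components", {
  up <- uncertainty_partition(rep(3, 3),
                              matrix(rnorm(3 * 100, 3, 0.5), 3, 100))
  expect_equal(up$replicate_var, 0)
  expect_gt(up$bootstrap_var, 0)
  up2 <- uncertainty_partition(c(1, 2, 3), matrix(7, 3, 100))
  expect_gt(up2$replicate_var, 0)
  expect_equal(up2$bootstrap_var, 0)
  expect_true(is.na(uncertainty_partition(1, matrix(1, 1, 5))$replicate_var))
})

test_that("injected variance components are recovered on average", {
  set.seed(11)
  s_rep <- 0.4; s_boot <- 0.15
  rep_vars <- boot_vars <- numeric(300)
  for (i in 1:300) {
    mu <- 10
    ch <- rnorm(3, mu, s_rep)
    trees <- matrix(rnorm(3 * 200, rep(ch, 200), s_boot), 3, 200)
    up <- uncertainty_partition(ch, trees)
    rep_vars[i] <- up$replicate_var
    boot_vars[i] <- up$bootstrap_var
  }
  expect_equal(mean(rep_vars), s_rep^2, tolerance = 0.2)
  expect_equal(mean(boot_vars), s_boot^2, tolerance = 0.2)
})

test_that("an already-dark photoperiod window leaves the budget unchanged", {
  f <- toy_features(200)
  fit <- tune_and_fit(f, rf_config(ntree = 30, maxnodes_grid = 32,
                                   mtry_grid = 4, n_folds = 4), seed = 1)
  camp <- small_campaign(obs_fraction = 1, make_traces = FALSE)
  drivers <- camp$drivers
  drivers$Rg[drivers$hour >= 20 | drivers$hour < 4] <- 0
  cf <- photoperiod_counterfactual(fit, drivers, camp$chambers[1:2, ])
  expect_equal(unname(cf$delta), c(0, 0))
})

test_that("subplot budgets aggregate chambers and honour GWP identities", {
  camp <- small_campaign(obs_fraction = 1, make_traces = FALSE)
  ch <- camp$chambers
  mk <- function(v) list(
    chamber_totals = stats::setNames(v, ch$chamber_id),
    tree_totals = matrix(rep(v, 10), nrow(ch), 10,
                         dimnames = list(ch$chamber_id, NULL)))
  totals <- list(co2 = mk(rep(2, nrow(ch))), ch4 = mk(rep(0.01, nrow(ch))),
                 n2o = mk(rep(0.001, nrow(ch))))
  b <- subplot_budgets(totals, ch, camp$biomass)
  expect_equal(nrow(b), 10)
  expect_equal(b$co2eq_t_ha, b$co2_t_ha + 27 * b$ch4_t_ha + 273 * b$n2o_t_ha)
  expect_equal(b$net_c_t_ha,
               b$co2_t_ha * 12.011 / 44.01 + b$ch4_t_ha * 12.011 / 16.04 +
                 0.43 * b$biomass_t_ha)
  expect_true(all(b$biomass_t_ha > 0))
  # fertilization effect present in generated biomass
  expect_gt(mean(b$biomass_t_ha[b$fertilization == "high"]),
            mean(b$biomass_t_ha[b$fertilization == "low"]))
})
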