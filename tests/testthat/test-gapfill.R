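test_that("feature rows join drivers and event clocks correctly", {
  camp <- small_campaign(obs_fraction = 1, make_traces = FALSE)
  m <- camp$measurements
  rec <- data.frame(measurement_id = m$measurement_id, gas = "co2",
                    flux = m$true_co2, chamber_id = m$chamber_id,
                    plot = m$plot, fertilization = m$fertilization,
                    timestamp = m$timestamp)
  f <- build_features(rec, camp$drivers)
  expect_equal(nrow(f), nrow(rec)) # gap-free fixture: one row per record
  expect_true(all(.lengths <- c("plot_id", "fertilization", "Rg", "WTL",
    "WS", "VPD", "DOY", "PPT", "Ts5", "Ts50", "Tair",
    "days_since_harvest", "days_since_fertilization") %in% names(f)))
  # fertilization was 2022-06-02; a record on 06-05 is 3 days after
  i <- which(as.Date(f$timestamp) == as.Date("2022-06-05"))[1]
  expect_equal(f$days_since_fertilization[i], 3)
  # before the first harvest (2022-06-04) the sentinel applies
  j <- which(as.Date(f$timestamp) == as.Date("2022-06-01"))[1]
  expect_equal(f$days_since_harvest[j], 365)
  # records without a driver hour are dropped with a message
  rec2 <- rec[1:5, ]
  rec2$timestamp[1] <- rec2$timestamp[1] + 86400 * 400
  expect_message(f2 <- build_features(rec2, camp$drivers), "dropped")
  expect_equal(nrow(f2), 4)
})

test_that("training preparation oversamples extremes and applies the CH4 cutoff", {
  f <- toy_features(100)
  cfg <- rf_config()
  prep <- prepare_training(f, "co2", cfg)
  expect_equal(prep$n_oversampled, 5) # 5 of 100 beyond the 95th percentile
  expect_equal(nrow(prep$training), 105)
  # unchanged when nothing is extreme and CH4 never exceeds the cutoff
  fc <- f
  fc$flux <- rep(c(1, 2), 50)
  prep2 <- prepare_training(fc, "ch4", cfg)
  expect_equal(nrow(prep2$training), 100)
  expect_equal(nrow(prep2$excluded), 0)
  # 7 extreme CH4 rows: excluded from training, retained on the side
  fh <- f
  fh$flux <- abs(fh$flux) / max(abs(fh$flux)) # all below 10
  fh$flux[1:7] <- 50
  prep3 <- prepare_training(fh, "ch4", cfg)
  expect_equal(nrow(prep3$excluded), 7)
  expect_true(all(prep3$training$flux <= 10))
})

test_that("cross-validation folds partition chambers", {
  folds <- make_chamber_folds(rep(1:30, each = 4), n_folds = 10, seed = 2)
  expect_equal(length(folds), 30)
  expect_equal(as.integer(table(folds)), rep(3L, 10)) # 10 folds of 3 chambers
  expect_warning(f2 <- make_chamber_folds(1:4, n_folds = 10), "reducing")
  expect_equal(max(f2), 4)
})

test_that("a one-cell grid is selected and fitted", {
  f <- toy_features(300)
  cfg <- rf_config(ntree = 50, maxnodes_grid = 64, mtry_grid = 4,
                   n_folds = 4)
  fit <- tune_and_fit(f, cfg, seed = 1)
  expect_equal(fit$best, list(maxnodes = 64, mtry = 4))
  expect_equal(nrow(fit$cv), 1)
  expect_gt(fit$cv_r2, 0.5) # smooth toy response is learnable
})

test_that("shuffled targets yield near-zero cross-validated R2", {
  f <- toy_features(300, seed = 3)
  set.seed(9)
  f$flux <- sample(f$flux)
  cfg <- rf_config(ntree = 50, maxnodes_grid = 64, mtry_grid = 4,
                   n_folds = 4)
  fit <- tune_and_fit(f, cfg, seed = 1)
  expect_lt(fit$cv_r2, 0.1) # permutation null
})

test_that("observed hours take precedence and tree spread behaves", {
  camp <- small_campaign(obs_fraction = 1, make_traces = FALSE)
  f <- toy_features(300)
  cfg <- rf_config(ntree = 30, maxnodes_grid = 32, mtry_grid = 4,
                   n_folds = 4)
  fit <- tune_and_fit(f, cfg, seed = 1)
  obs <- data.frame(chamber_id = 1,
                    timestamp = camp$drivers$time[5],
                    flux = 1234)
  ph <- predict_hourly(fit, camp$drivers, camp$chambers[1:2, ],
                       observations = obs, n_plots = 5)
  h <- ph$hourly
  i <- h$chamber_id == 1 & h$time == obs$timestamp
  expect_equal(h$flux[i], 1234)
  expect_false(h$filled[i])
  expect_equal(h$sd_tree[i], 0) # observation overrides every tree
  expect_true(all(h$filled[!i]))
  expect_equal(dim(ph$tree_sums), c(2, 30))

  # constant-target ensemble: every tree predicts the constant, zero spread
  fc <- f
  fc$flux <- 42
  fitc <- tune_and_fit(fc, cfg, seed = 1)
  phc <- predict_hourly(fitc, camp$drivers, camp$chambers[1, ], n_plots = 5)
  expect_true(all(abs(phc$hourly$flux - 42) < 1e-9))
  expect_true(all(phc$hourly$sd_tree < 1e-9))
})

test_that("single-point partial dependence equals the clamped mean prediction", {
  f <- toy_features(200)
  cfg <- rf_config(ntree = 30, maxnodes_grid = 32, mtry_grid = 4,
                   n_folds = 4)
  fit <- tune_and_fit(f, cfg, seed = 1)
  pd <- partial_dependence(fit, f, wtl = -0.5, ts5 = 10, n_sample = 50,
                           seed = 7)
  set.seed(7)
  idx <- sample(nrow(f), 50)
  nd <- f[idx, fit$predictors]
  nd$WTL <- -0.5
  nd$Ts5 <- 10
  expect_equal(pd$pred, mean(predict(fit$model, nd)), tolerance = 1e-10)
  expect_false(pd$extrapolated)
  pd2 <- partial_dependence(fit, f, wtl = -5, ts5 = 10)
  expect_true(pd2$extrapolated)
})

test_that("importance percentages are non-negative and sum to 100", {
  f <- toy_features(300)
  fit <- tune_and_fit(f, rf_config(ntree = 50, maxnodes_grid = 64,
                                   mtry_grid = 4, n_folds = 4), seed = 1)
  vi <- variable_importance(fit)
  expect_equal(sum(vi), 100, tolerance = 1e-9)
  expect_true(all(vi >= 0))
  expect_equal(names(vi)[1], "Rg") # Rg dominates the toy response
})
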