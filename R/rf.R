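#' Random-forest model configuration
#'
#' Defaults follow the flux-model setup: 600 trees, maxnodes grid 100-1800
#' in steps of 100, mtry grid 1-12, 10-fold cross-validation grouped by
#' chamber id, oversampling of targets beyond the 95th percentile, and a
#' 10 mg CH4 m-2 h-1 training exclusion for methane.
#'
#' @param ntree trees per forest.
#' @param maxnodes_grid candidate maximum numbers of terminal nodes.
#' @param mtry_grid candidate numbers of predictors per split.
#' @param n_folds cross-validation folds (chambers grouped, never split).
#' @param oversample_percentile percentile of |flux| beyond which training
#'   rows are duplicated once.
#' @param ch4_training_cutoff CH4 training exclusion threshold,
#'   mg CH4 m-2 h-1.
#' @return object of class `rf_config`.
#' @export
rf_config <- function(ntree = 600,
                      maxnodes_grid = seq(100, 1800, by = 100),
                      mtry_grid = 1:12,
                      n_folds = 10,
                      oversample_percentile = 95,
                      ch4_training_cutoff = 10) {
  stopifnot(length(maxnodes_grid) > 0, length(mtry_grid) > 0,
            ntree > 0, n_folds >= 2)
  structure(list(ntree = ntree, maxnodes_grid = maxnodes_grid,
                 mtry_grid = mtry_grid, n_folds = n_folds,
                 oversample_percentile = oversample_percentile,
                 ch4_training_cutoff = ch4_training_cutoff),
            class = "rf_config")
}

#' Prepare the training set for one gas
#'
#' For CH4, rows above the training cutoff are removed from training (they
#' remain available for budgets; returned in `$excluded`). Rows whose |flux|
#' exceeds the gas's `oversample_percentile` of |flux| are duplicated once
#' to counter the forest's bias against extremes.
#'
#' @param features a [build_features()] matrix.
#' @param gas gas id.
#' @param cfg an [rf_config()].
#' @return list: `training` (possibly with duplicated rows), `excluded`
#'   (CH4-cutoff rows), `n_oversampled`.
#' @export
prepare_training <- function(features, gas, cfg = rf_config()) {
  gas <- gas_id(gas)
  excluded <- features[0, , drop = FALSE]
  if (gas == "ch4") {
    hi <- features$flux > cfg$ch4_training_cutoff
    excluded <- features[hi, , drop = FALSE]
    features <- features[!hi, , drop = FALSE]
  }
  q <- stats::quantile(abs(features$flux), cfg$oversample_percentile / 100,
                       names = FALSE)
  extreme <- abs(features$flux) > q
  training <- rbind(features, features[extreme, , drop = FALSE])
  list(training = training, excluded = excluded,
       n_oversampled = sum(extreme))
}

#' Assign chambers to cross-validation folds
#'
#' Chambers are shuffled with the given seed and dealt round-robin into
#' folds, so no chamber ever spans folds. With fewer chambers than requested
#' folds the fold count is reduced with a warning.
#'
#' @param chamber_ids vector of chamber ids (with repeats allowed).
#' @param n_folds requested fold count.
#' @param seed integer seed for the shuffle.
#' @return named integer vector: fold per unique chamber id.
#' @export
make_chamber_folds <- function(chamber_ids, n_folds = 10, seed = 1L) {
  ch <- sort(unique(chamber_ids))
  if (length(ch) < n_folds) {
    warning("fewer chamber groups than folds; reducing folds to ",
            length(ch))
    n_folds <- length(ch)
  }
  set.seed(seed)
  shuffled <- sample(ch)
  folds <- rep(seq_len(n_folds), length.out = length(ch))
  stats::setNames(folds[order(match(ch, shuffled))], ch)
}

#' Tune and fit a random-forest flux model
#'
#' Grid search over (maxnodes, mtry) with chamber-grouped k-fold
#' cross-validation at fixed `ntree`; predictions are pooled across folds
#' and the grid cell with the lowest pooled RMSE is selected and refit on
#' all training data (with permutation importance enabled).
#'
#' @param training a `prepare_training()$training` data.frame.
#' @param cfg an [rf_config()].
#' @param seed integer seed (fold assignment and forest randomness).
#' @return object of class `ghg_rf`: `model` (randomForest), `cv` (grid
#'   table with pooled RMSE and R2), `best`, `folds`, `cv_rmse`, `cv_r2`,
#'   `xlevels`, `predictors`.
#' @export
tune_and_fit <- function(training, cfg = rf_config(), seed = 1L) {
  folds <- make_chamber_folds(training$chamber_id, cfg$n_folds, seed)
  fold_of <- folds[as.character(training$chamber_id)]
  x <- training[, .PREDICTORS]
  y <- training$flux
  grid <- expand.grid(maxnodes = cfg$maxnodes_grid,
                      mtry = pmin(cfg$mtry_grid, ncol(x)))
  grid <- grid[!duplicated(grid), , drop = FALSE]
  grid$rmse <- NA_real_
  grid$r2 <- NA_real_
  sst <- sum((y - mean(y))^2)
  for (i in seq_len(nrow(grid))) {
    pred <- numeric(length(y))
    for (f in unique(fold_of)) {
      tr <- fold_of != f
      set.seed(seed + i)
      m <- randomForest::randomForest(
        x = x[tr, , drop = FALSE], y = y[tr],
        ntree = cfg$ntree, mtry = grid$mtry[i], maxnodes = grid$maxnodes[i])
      pred[!tr] <- stats::predict(m, x[!tr, , drop = FALSE])
    }
    grid$rmse[i] <- sqrt(mean((pred - y)^2))
    grid$r2[i] <- 1 - sum((pred - y)^2) / sst
  }
  best <- which.min(grid$rmse)
  set.seed(seed)
  final <- randomForest::randomForest(
    x = x, y = y, ntree = cfg$ntree, mtry = grid$mtry[best],
    maxnodes = grid$maxnodes[best], importance = TRUE)
  structure(list(
    model = final, cv = grid,
    best = list(maxnodes = grid$maxnodes[best], mtry = grid$mtry[best]),
    folds = folds, cv_rmse = grid$rmse[best], cv_r2 = grid$r2[best],
    predictors = .PREDICTORS,
    ranges = list(WTL = range(x$WTL), Ts5 = range(x$Ts5))
  ), class = "ghg_rf")
}

#' Hourly flux predictions per chamber with per-tree spread
#'
#' Predicts every hour of the driver table for every chamber. Hours with an
#' observation keep the observation (`filled = FALSE`); all other hours are
#' model-filled. Per-tree predictions are not stored hour by hour; instead
#' each tree's seasonal running total per chamber is accumulated (a
#' consistent tree index across hours), which is what the bootstrap budget
#' uncertainty needs, along with the hourly ensemble SD.
#'
#' @param fit a `ghg_rf` from [tune_and_fit()].
#' @param drivers a [gen_drivers()] table covering the prediction window.
#' @param chambers chamber table (`chamber_id`, `plot`, `fertilization`).
#' @param observations optional data.frame (`chamber_id`, `timestamp`,
#'   `flux`) taking precedence over model predictions.
#' @param n_plots number of plots (factor levels).
#' @return list: `hourly` data.frame (`chamber_id`, `plot`, `fertilization`,
#'   `time`, `flux`, `filled`, `sd_tree`) and `tree_sums` matrix
#'   (chambers x trees, summed mg m-2 h-1 with observations overriding all
#'   trees on observed hours).
#' @export
predict_hourly <- function(fit, drivers, chambers, observations = NULL,
                           n_plots = 5) {
  ntree <- fit$model$ntree
  hourly <- vector("list", nrow(chambers))
  tree_sums <- matrix(0, nrow(chambers), ntree,
                      dimnames = list(chambers$chamber_id, NULL))
  for (i in seq_len(nrow(chambers))) {
    nd <- .chamber_feature_rows(drivers, chambers[i, , drop = FALSE],
                                n_plots)
    pr <- stats::predict(fit$model, nd[, fit$predictors],
                         predict.all = TRUE)
    trees <- pr$individual # hours x ntree
    mu <- pr$aggregate
    filled <- rep(TRUE, nrow(nd))
    if (!is.null(observations)) {
      ob <- observations[observations$chamber_id == chambers$chamber_id[i], ,
                         drop = FALSE]
      j <- match(ob$timestamp, nd$time)
      ok <- !is.na(j)
      if (any(ok)) {
        mu[j[ok]] <- ob$flux[ok]
        trees[j[ok], ] <- ob$flux[ok]
        filled[j[ok]] <- FALSE
      }
    }
    tree_sums[i, ] <- colSums(trees)
    hourly[[i]] <- data.frame(
      chamber_id = chambers$chamber_id[i], plot = chambers$plot[i],
      fertilization = chambers$fertilization[i], time = nd$time,
      flux = mu, filled = filled, sd_tree = apply(trees, 1, stats::sd)
    )
  }
  list(hourly = do.call(rbind, hourly), tree_sums = tree_sums)
}

#' Partial-dependence surface over water table and soil temperature
#'
#' Standard partial dependence: for every (WTL, Ts5) grid cell the two
#' variables are clamped in a sample of the training rows and predictions
#' are averaged over the empirical distribution of the remaining 11
#' predictors. Cells outside the training range of either variable are
#' flagged `extrapolated`.
#'
#' @param fit a `ghg_rf`.
#' @param data training feature rows to average over.
#' @param wtl,ts5 grid vectors (m; deg C).
#' @param n_sample rows sampled from `data` (all rows if fewer).
#' @param seed sampling seed.
#' @return data.frame: `WTL`, `Ts5`, `pred`, `extrapolated`.
#' @export
partial_dependence <- function(fit, data, wtl = seq(-1.5, -0.1, by = 0.1),
                               ts5 = seq(2, 16, by = 2),
                               n_sample = 200, seed = 1L) {
  set.seed(seed)
  idx <- if (nrow(data) > n_sample) sample(nrow(data), n_sample)
         else seq_len(nrow(data))
  base <- data[idx, fit$predictors]
  grid <- expand.grid(WTL = wtl, Ts5 = ts5)
  nd <- base[rep(seq_len(nrow(base)), times = nrow(grid)), ]
  nd$WTL <- rep(grid$WTL, each = nrow(base))
  nd$Ts5 <- rep(grid$Ts5, each = nrow(base))
  p <- stats::predict(fit$model, nd)
  grid$pred <- as.numeric(tapply(p, rep(seq_len(nrow(grid)),
                                        each = nrow(base)), mean))
  grid$extrapolated <- grid$WTL < fit$ranges$WTL[1] |
    grid$WTL > fit$ranges$WTL[2] |
    grid$Ts5 < fit$ranges$Ts5[1] | grid$Ts5 > fit$ranges$Ts5[2]
  grid
}

#' Permutation variable importance as percentages
#'
#' Mean-decrease-in-accuracy importance of the fitted forest, truncated at
#' zero and normalised to sum to 100.
#'
#' @param fit a `ghg_rf`.
#' @return named numeric vector (percent per predictor, decreasing).
#' @export
variable_importance <- function(fit) {
  imp <- randomForest::importance(fit$model, type = 1)[, 1]
  imp <- pmax(imp, 0)
  sort(100 * imp / sum(imp), decreasing = TRUE)
}
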