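#' Water-table bin specification
#'
#' Half-open bins `[lo, hi)` of the stated width spanning the WTL range;
#' defaults: 0.3-m bins from -1.5 to 0 m (5 bins).
#'
#' @param lower,upper range in m (negative below surface).
#' @param width bin width in m.
#' @return object of class `wtl_bins` with a `breaks` vector.
#' @export
wtl_bins <- function(lower = -1.5, upper = 0, width = 0.3) {
  nb <- (upper - lower) / width
  if (abs(nb - round(nb)) > 1e-9) {
    stop("(upper - lower) must be an integer multiple of width")
  }
  structure(list(lower = lower, upper = upper, width = width,
                 breaks = seq(lower, upper, by = width)),
            class = "wtl_bins")
}

#' Assign observed CO2 records to water-table bins
#'
#' Only measured (never gap-filled) records enter the light-response
#' analysis; each record is binned by the WTL of its own plot at measurement
#' time, on the half-open convention `[lo, hi)`. Records outside the bin
#' range are dropped and counted.
#'
#' @param obs data.frame with `WTL`, `Rg` and `flux` columns (e.g. the CO2
#'   rows of [build_features()]).
#' @param spec a [wtl_bins()].
#' @return list of data.frames, one per bin (named `"[lo,hi)"`), with the
#'   number of out-of-range records as attribute `"n_dropped"`.
#' @export
bin_by_wtl <- function(obs, spec = wtl_bins()) {
  inside <- obs$WTL >= spec$lower & obs$WTL < spec$upper
  dropped <- sum(!inside)
  obs <- obs[inside, , drop = FALSE]
  idx <- findInterval(obs$WTL, spec$breaks) # half-open [lo, hi)
  labs <- sprintf("[%g,%g)", utils::head(spec$breaks, -1),
                  utils::tail(spec$breaks, -1))
  out <- lapply(seq_len(length(spec$breaks) - 1),
                function(b) obs[idx == b, , drop = FALSE])
  names(out) <- labs
  attr(out, "n_dropped") <- dropped
  out
}

#' Fit the Michaelis-Menten light response to one observation set
#'
#' Nonlinear least squares of NEE = -(alpha Rg GPPmax)/(alpha Rg + GPPmax)
#' + Rd with all three parameters constrained non-negative (magnitude
#' parameterization, emission positive). Starting values come from the data
#' (Rd from the mean dark flux, GPPmax from the flux span, alpha from an
#' initial-slope regression); on non-convergence a small grid of alternative
#' starts is tried before the fit is flagged as failed.
#'
#' @param obs data.frame with `Rg` (W m-2) and `flux` (mg CO2 m-2 h-1).
#' @param min_obs minimum observations required.
#' @return object of class `light_response_fit`: `alpha`, `gppmax`, `rd`,
#'   `lcp`, `n_obs`, `converged`, `model`.
#' @export
fit_light_response <- function(obs, min_obs = 10) {
  if (nrow(obs) < min_obs) {
    stop("need at least ", min_obs, " observations spanning dark and light")
  }
  dark <- obs$flux[obs$Rg < 10]
  rd0 <- if (length(dark) >= 3) max(mean(dark), 1) else
    max(stats::quantile(obs$flux, 0.9, names = FALSE), 1)
  g0 <- max(rd0 - min(obs$flux), 50)
  bright <- obs$Rg > stats::quantile(obs$Rg, 0.5, names = FALSE)
  a0 <- if (any(bright) && mean(obs$Rg[bright]) > 0) {
    max((rd0 - mean(obs$flux[bright])) / mean(obs$Rg[bright]), 0.05)
  } else 0.5
  starts <- list(c(a0, g0, rd0))
  for (f in c(0.3, 3)) starts <- c(starts, list(c(a0 * f, g0 * f, rd0)))
  fit <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        flux ~ -(a * Rg * g) / (a * Rg + g) + rd, data = obs,
        start = list(a = st[1], g = st[2], rd = st[3]),
        lower = c(a = 0, g = 0, rd = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    # light-independent data leave alpha/GPPmax unidentifiable (singular
    # gradient); the boundary solution GPPmax -> 0 reduces the curve to the
    # constant Rd, which is the least-squares answer there
    rd_hat <- mean(obs$flux)
    light_dep <- stats::var(obs$flux) > 0 && stats::var(obs$Rg) > 0 &&
      stats::cor(obs$Rg, obs$flux) < -0.2
    if (!light_dep && rd_hat >= 0) {
      out <- structure(list(alpha = 0, gppmax = 0, rd = rd_hat,
                            lcp = NA_real_, n_obs = nrow(obs),
                            converged = TRUE, model = NULL),
                       class = "light_response_fit")
      return(out)
    }
    return(structure(list(alpha = NA_real_, gppmax = NA_real_,
                          rd = NA_real_, lcp = NA_real_,
                          n_obs = nrow(obs), converged = FALSE,
                          model = NULL),
                     class = "light_response_fit"))
  }
  cf <- stats::coef(fit)
  out <- structure(list(alpha = unname(cf["a"]), gppmax = unname(cf["g"]),
                        rd = unname(cf["rd"]), lcp = NA_real_,
                        n_obs = nrow(obs), converged = TRUE, model = fit),
                   class = "light_response_fit")
  out$lcp <- compute_lcp(out)
  out
}

#' Light compensation point of a fitted light response
#'
#' The radiation level at which the net CO2 flux crosses zero:
#' LCP = (Rd GPPmax) / (alpha (GPPmax - Rd)) in the magnitude
#' parameterization, defined only when GPPmax > Rd (otherwise the curve
#' never reaches zero and `NA` is returned). The defining property
#' NEE(LCP) = 0 holds to numerical precision.
#'
#' @param fit a `light_response_fit`, or any list with `alpha`, `gppmax`,
#'   `rd`.
#' @return LCP in W m-2, or `NA` if undefined.
#' @export
compute_lcp <- function(fit) {
  if (any(is.na(c(fit$alpha, fit$gppmax, fit$rd)))) return(NA_real_)
  if (fit$gppmax <= fit$rd) return(NA_real_)
  (fit$rd * fit$gppmax) / (fit$alpha * (fit$gppmax - fit$rd))
}

#' Bootstrap the light-response parameters
#'
#' Case-resampling bootstrap: rows are resampled with replacement and the
#' hyperbola is refit per replicate; failed or non-finite replicates are
#' dropped and counted. If more than half the replicates fail the bin is
#' flagged unreliable.
#'
#' @param obs observation set as in [fit_light_response()].
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @return list: `summary` data.frame (mean, sd per parameter incl. LCP),
#'   `n_failed`, `reliable`, `draws` (replicate x parameter matrix).
#' @export
bootstrap_params <- function(obs, n_boot = 300, seed = 1L) {
  full <- fit_light_response(obs)
  if (!full$converged) stop("full-set fit failed; nothing to bootstrap")
  set.seed(seed)
  draws <- matrix(NA_real_, n_boot, 4,
                  dimnames = list(NULL, c("alpha", "gppmax", "rd", "lcp")))
  for (b in seq_len(n_boot)) {
    rs <- obs[sample(nrow(obs), replace = TRUE), , drop = FALSE]
    f <- tryCatch(fit_light_response(rs), error = function(e) NULL)
    if (!is.null(f) && f$converged) {
      draws[b, ] <- c(f$alpha, f$gppmax, f$rd, f$lcp)
    }
  }
  ok <- stats::complete.cases(draws[, c("alpha", "gppmax", "rd")])
  summary <- data.frame(
    parameter = colnames(draws),
    estimate = c(full$alpha, full$gppmax, full$rd, full$lcp),
    boot_mean = colMeans(draws[ok, , drop = FALSE], na.rm = TRUE),
    boot_sd = apply(draws[ok, , drop = FALSE], 2, stats::sd, na.rm = TRUE)
  )
  list(summary = summary, n_failed = sum(!ok),
       reliable = mean(!ok) <= 0.5, draws = draws[ok, , drop = FALSE])
}

#' Per-bin light-response table along the water-table gradient
#'
#' Convenience wrapper: bins observed CO2 records by WTL, fits the
#' hyperbola per bin and (optionally) bootstraps the parameter SDs.
#'
#' @param obs observed CO2 feature rows (`Rg`, `WTL`, `flux`).
#' @param spec a [wtl_bins()].
#' @param n_boot bootstrap replicates per bin (0 to skip).
#' @param min_obs minimum observations per bin.
#' @param seed integer seed.
#' @return data.frame with one row per non-empty bin: bin bounds, `n_obs`,
#'   `alpha`, `gppmax`, `rd`, `lcp` and bootstrap SDs (`NA` when skipped).
#' @export
light_response_by_bin <- function(obs, spec = wtl_bins(), n_boot = 300,
                                  min_obs = 10, seed = 1L) {
  bins <- bin_by_wtl(obs, spec)
  rows <- vector("list", length(bins))
  for (b in seq_along(bins)) {
    dat <- bins[[b]]
    lo <- spec$breaks[b]; hi <- spec$breaks[b + 1]
    if (nrow(dat) < min_obs) next
    fit <- fit_light_response(dat, min_obs)
    if (!fit$converged) next
    sds <- c(alpha = NA_real_, gppmax = NA_real_, rd = NA_real_,
             lcp = NA_real_)
    if (n_boot > 0) {
      bs <- bootstrap_params(dat, n_boot, seed + b)
      sds <- stats::setNames(bs$summary$boot_sd, bs$summary$parameter)
    }
    rows[[b]] <- data.frame(
      bin = names(bins)[b], wtl_lo = lo, wtl_hi = hi, wtl_mid = (lo + hi) / 2,
      n_obs = fit$n_obs, alpha = fit$alpha, gppmax = fit$gppmax,
      rd = fit$rd, lcp = fit$lcp,
      alpha_sd = sds[["alpha"]], gppmax_sd = sds[["gppmax"]],
      rd_sd = sds[["rd"]], lcp_sd = sds[["lcp"]]
    )
  }
  do.call(rbind, rows)
}
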