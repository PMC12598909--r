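# Vectorised dynamic-window search over a matrix of traces (one column per
# trace, 1-Hz rows). All candidate windows end at the last sample; the start
# is scanned forward from the closure start in `step_s` increments, subject
# to a minimum window length. Returns, per column, the window maximising the
# linear-fit R-squared, ties broken toward the longer window.
.window_search <- function(ppm, min_window_s, step_s) {
  nt <- nrow(ppm)
  nc <- ncol(ppm)
  if (nt < min_window_s) stop("trace shorter than the minimum window")
  x <- seq_len(nt) - 1
  # centre both axes: windowed sxx/sxy/syy are shift-invariant and centring
  # avoids catastrophic cancellation for near-constant ppm series
  xc <- x - mean(x)
  yc <- sweep(ppm, 2, colMeans(ppm))
  cy <- apply(yc, 2, cumsum)
  cxy <- apply(yc * xc, 2, cumsum)
  cy2 <- apply(yc * yc, 2, cumsum)
  cx <- cumsum(xc)
  cx2 <- cumsum(xc * xc)
  tot <- function(m) m[nt, ]

  starts <- seq(0, nt - min_window_s, by = step_s)
  best_r2 <- rep(-Inf, nc)
  best <- list(start = numeric(nc), slope = numeric(nc),
               intercept = numeric(nc), n = numeric(nc), r2 = numeric(nc))
  for (s in starts) {
    n <- nt - s
    pre <- function(cum) if (s == 0) 0 else if (is.matrix(cum)) cum[s, ] else cum[s]
    sy <- tot(cy) - pre(cy)
    sxy <- tot(cxy) - pre(cxy)
    sy2 <- tot(cy2) - pre(cy2)
    sx <- cx[nt] - pre(cx)
    sx2 <- cx2[nt] - pre(cx2)
    sxx <- sx2 - sx^2 / n
    sxyc <- sxy - sx * sy / n
    syyc <- pmax(sy2 - sy^2 / n, 0)
    slope <- ifelse(syyc > 0, sxyc / sxx, 0)
    r2 <- ifelse(syyc > 0, pmin(1, sxyc^2 / (sxx * syyc)), 0)
    take <- r2 > best_r2 + 1e-12 # strict improvement keeps earlier (longer)
    if (any(take)) {
      best_r2[take] <- r2[take]
      best$start[take] <- s
      best$slope[take] <- slope[take]
      best$n[take] <- n
      best$r2[take] <- r2[take]
      best$intercept[take] <- (sy[take] - slope[take] * sx[take]) / n
    }
  }
  # intercept back on the original (uncentred) axes
  mu_y <- colMeans(ppm)
  best$intercept <- best$intercept + mu_y - best$slope * mean(x)
  data.frame(start_s = best$start, end_s = nt - 1, n = best$n,
             slope = best$slope, intercept = best$intercept, r2 = best$r2)
}

#' Select the dynamic fit window of a chamber closure trace
#'
#' Early parts of a closure can be biased by chamber stabilization, so the
#' best linear fit is taken from the latter part of the measurement: all
#' candidate windows end at the last sample and their start is scanned from
#' the closure start forward in `step_s` increments, keeping at least
#' `min_window_s` of data. The window with the highest linear-fit R-squared
#' wins; ties go to the longer window, so a perfectly linear trace keeps the
#' full closure.
#'
#' @param trace a `conc_trace` (or any list with `t_s` and `ppm` at 1 Hz).
#' @param min_window_s minimum window length, seconds.
#' @param step_s start-scan increment, seconds.
#' @return one-row data.frame (class `fit_window`): `start_s`, `end_s`, `n`,
#'   `slope` (ppm s-1), `intercept` (ppm), `r2`.
#' @export
select_window <- function(trace, min_window_s = 240, step_s = 10) {
  ppm <- matrix(trace$ppm, ncol = 1)
  if (nrow(ppm) < min_window_s) {
    stop("trace shorter than the minimum window: reject measurement")
  }
  w <- .window_search(ppm, min_window_s, step_s)
  class(w) <- c("fit_window", class(w))
  w
}
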