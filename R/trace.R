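# batch AR(1) noise: one column per trace, marginal sd `sd_ppm`
.ar1_noise <- function(nt, ncol, sd_ppm, ar1) {
  if (sd_ppm == 0) return(matrix(0, nt, ncol))
  innov_sd <- sd_ppm * sqrt(1 - ar1^2)
  e <- matrix(stats::rnorm(nt * ncol, sd = innov_sd), nt, ncol)
  init <- stats::rnorm(ncol, sd = sd_ppm)
  m <- stats::filter(e, ar1, method = "recursive", init = matrix(init, 1))
  matrix(as.numeric(m), nt, ncol)
}

# deterministic part of the ppm series for given slopes (vector, ppm s-1)
.trace_mean <- function(slopes, base_ppm, t_s, noise) {
  mean_part <- outer(t_s, slopes) # nt x N linear rise
  if (noise$curvature != 0) {
    tau <- noise$curvature_tau_s
    bend <- noise$curvature * tau * (1 - exp(-t_s / tau)) # per unit slope
    mean_part <- mean_part + outer(bend, slopes)
  }
  mean_part + base_ppm
}

#' Generate one synthetic chamber closure trace
#'
#' Builds the 1-Hz ppm series a chamber closure would record for a known
#' surface flux: a linear rise whose slope is the exact inverse of the flux
#' conversion used by [compute_flux()] (ideal gas at the given conditions,
#' V/A = headspace height), plus optional AR(1) noise and an early-trace
#' stabilization artefact (see [trace_noise()]). The generating slope and
#' flux are stored alongside for round-trip tests.
#'
#' @param flux true flux, mg gas m-2 h-1.
#' @param gas gas id.
#' @param geom a [chamber_geometry()].
#' @param met list with `Tair_K` and `pressure_Pa`.
#' @param closure_min closure length in minutes (1 Hz sampling).
#' @param noise a [trace_noise()].
#' @param seed integer seed for the noise.
#' @return object of class `conc_trace`: list with `t_s`, `ppm`, `gas`,
#'   `true_flux`, `true_slope`, `met`.
#' @export
gen_trace <- function(flux, gas, geom = chamber_geometry(),
                      met = list(Tair_K = 283.15, pressure_Pa = 101325),
                      closure_min = 10, noise = trace_noise(), seed = 1L) {
  stopifnot(closure_min > 0)
  gas <- gas_id(gas)
  set.seed(seed)
  nt <- round(closure_min * 60)
  t_s <- seq_len(nt) - 1
  slope <- flux_to_slope(flux, gas, geom$headspace_height,
                         met$Tair_K, met$pressure_Pa)
  ppm <- .trace_mean(slope, .AMBIENT_PPM[[gas]], t_s, noise)[, 1] +
    .ar1_noise(nt, 1, noise$sd_ppm, noise$ar1)[, 1]
  structure(list(t_s = t_s, ppm = ppm, gas = gas,
                 true_flux = flux, true_slope = slope, met = met),
            class = "conc_trace")
}

# batch trace generation for the campaign generator: returns an nt x N
# matrix of ppm series for per-trace fluxes/temperatures
.gen_trace_matrix <- function(flux, gas, geom, tair_k, pressure_pa,
                              closure_min, noise) {
  nt <- round(closure_min * 60)
  t_s <- seq_len(nt) - 1
  slopes <- flux_to_slope(flux, gas, geom$headspace_height, tair_k,
                          pressure_pa)
  .trace_mean(slopes, .AMBIENT_PPM[[gas]], t_s, noise) +
    .ar1_noise(nt, length(slopes), noise$sd_ppm, noise$ar1)
}
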