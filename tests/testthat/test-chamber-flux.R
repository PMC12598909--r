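geom <- chamber_geometry()
met <- list(Tair_K = 283.15, pressure_Pa = 101325)

test_that("a perfectly linear trace keeps the full window with R2 = 1", {
  tr <- gen_trace(800, "co2", geom, met,
                  noise = trace_noise(sd_ppm = 0, curvature = 0))
  w <- select_window(tr)
  expect_equal(w$start_s, 0)
  expect_equal(w$n, 600)
  expect_equal(w$r2, 1, tolerance = 1e-12)
})

test_that("window search matches exhaustive brute force on noisy curved traces", {
  for (i in 1:12) {
    tr <- gen_trace(runif(1, 100, 1500), "co2", geom, met,
                    noise = trace_noise(), seed = 200 + i)
    w <- select_window(tr)
    b <- brute_force_window(tr)
    expect_equal(w$start_s, b$start_s)
    expect_equal(w$slope, b$slope, tolerance = 1e-8)
    expect_equal(w$r2, b$r2, tolerance = 1e-8)
  }
})

test_that("strong early curvature pushes the window start past the bend", {
  # heavy artefact, light noise: the transient dominates the first ~2 min
  nz <- trace_noise(sd_ppm = 0.05, curvature = 6, curvature_tau_s = 90)
  starts <- vapply(1:5, function(i) {
    tr <- gen_trace(1000, "co2", geom, met, noise = nz, seed = i)
    select_window(tr)$start_s
  }, numeric(1))
  expect_true(all(starts >= 120))
})

test_that("traces shorter than the minimum window are rejected", {
  tr <- gen_trace(500, "co2", geom, met, closure_min = 3,
                  noise = trace_noise(sd_ppm = 0, curvature = 0))
  expect_error(select_window(tr, min_window_s = 240), "reject")
})

test_that("flux conversion is linear in slope and V/A and offset-invariant", {
  w <- data.frame(start_s = 0, end_s = 599, n = 600, slope = 0.1,
                  intercept = 420, r2 = 0.99)
  f1 <- compute_flux(list(met = met, gas = "co2"), w, geom)
  expect_equal(compute_flux(list(met = met, gas = "co2"),
                            transform(w, slope = 0), geom), 0)
  expect_equal(compute_flux(list(met = met, gas = "co2"), w,
                            chamber_geometry(headspace_height = 1.2)),
               2 * f1)
  w2 <- transform(w, intercept = 999) # ppm offset does not enter
  expect_equal(compute_flux(list(met = met, gas = "co2"), w2, geom), f1)
  expect_error(compute_flux(list(met = list(Tair_K = -1, pressure_Pa = 1e5),
                                 gas = "co2"), w, geom), "positive")
})

test_that("QC flags follow the R2 and small-flux rules", {
  rec <- data.frame(
    gas = c("co2", "co2", "co2", "ch4", "ch4", "n2o", "n2o"),
    flux = c(500, 50, 500, 0.05, -0.5, 0.1, 0.3),
    r2 = c(0.95, 0.3, 0.3, 0.5, 0.5, 0.5, 0.5))
  out <- assign_qc(rec)
  expect_equal(out$qc_flag, c(0L, 1L, 2L, 1L, 2L, 1L, 2L))
  # boundary: R2 must strictly exceed 0.8
  expect_equal(assign_qc(data.frame(gas = "co2", flux = 500,
                                    r2 = 0.8))$qc_flag, 2L)
})

test_that("every record gets exactly one flag", {
  set.seed(1)
  rec <- data.frame(gas = sample(c("co2", "ch4", "n2o"), 500, TRUE),
                    flux = rnorm(500, 0, 200), r2 = runif(500))
  out <- assign_qc(rec)
  expect_true(all(out$qc_flag %in% 0:2))
  expect_equal(length(out$qc_flag), 500)
})

test_that("filtering removes exactly the flag-2 records and reports fractions", {
  rec <- data.frame(gas = rep("co2", 100),
                    flux = rep(500, 100),
                    r2 = c(rep(0.95, 97), rep(0.3, 3)))
  out <- filter_records(assign_qc(rec))
  expect_equal(nrow(out), 97)
  expect_equal(unname(attr(out, "removed_fraction")["co2"]), 0.03)
})

test_that("processed campaign records round-trip true fluxes on quiet traces", {
  quiet <- campaign_noise(co2 = trace_noise(0, curvature = 0),
                          ch4 = trace_noise(0, curvature = 0),
                          n2o = trace_noise(0, curvature = 0))
  camp <- small_campaign(obs_fraction = 0.3, noise = quiet)
  rec <- process_traces(camp)
  m <- camp$measurements
  for (g in c("co2", "ch4", "n2o")) {
    r <- rec[rec$gas == g, ]
    tru <- m[[paste0("true_", g)]][match(r$measurement_id, m$measurement_id)]
    expect_equal(r$flux, tru, tolerance = 1e-6)
  }
})
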