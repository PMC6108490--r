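test_that("stress and strain use the standardized cylinder geometry", {
  rec <- force_displacement_record(time = 0:3 / 4,
                                   force = c(10, 100, 196.3, 0),
                                   displacement = c(0, 0.05, 0.10, 0.12))
  cv <- compute_stress_strain(rec)
  expect_equal(length(cv$stress), 4L)
  expect_equal(cv$stress[3], 10.00, tolerance = 1e-3)
  expect_equal(cv$strain[3], 0.01)
  expect_equal(cv$stress[4], 0)
  expect_equal(cv$area, pi * 2.5^2)
})

test_that("negative displacement is rejected", {
  rec <- force_displacement_record(time = 0:2 / 4, force = c(10, 11, 12),
                                   displacement = c(0.5, 0.2, 0.6))
  expect_error(compute_stress_strain(rec), "negative displacement")
})

test_that("modulus on an exact line is exact in any window", {
  eps <- seq(0, 0.05, by = 5e-4)
  em <- estimate_elastic_modulus(make_curve(eps, 300 * eps))
  expect_equal(em$E, 300, tolerance = 1e-10)
  em2 <- estimate_elastic_modulus(make_curve(eps, 300 * eps),
                                  window_width = 0.02)
  expect_equal(em2$E, 300, tolerance = 1e-10)
})

test_that("modulus on a noiseless bilinear curve picks the elastic segment", {
  eps <- seq(0, 0.05, by = 5e-4)
  knee <- 0.025
  sig <- ifelse(eps <= knee, 320.44 * eps,
                320.44 * knee + 50 * (eps - knee))
  em <- estimate_elastic_modulus(make_curve(eps, sig))
  expect_equal(em$E, 320.44, tolerance = 1e-8)
  expect_lte(em$window[2], knee + 1e-9)
})

test_that("generator round trip recovers the true modulus", {
  # noiseless: exact to well within 0.5%
  s0 <- summarize_record(generate_load_curve(
    load_curve_config(E_true = 344.09, F_peak_true = 940.80,
                      yield_strain = 0.04, noise_sd = 0, seed = 1)))
  expect_equal(s0$elastic_modulus, 344.09, tolerance = 0.005)
  # seeded noisy record: within 2%
  s1 <- summarize_record(generate_load_curve(
    load_curve_config(E_true = 344.09, F_peak_true = 940.80,
                      yield_strain = 0.04, noise_sd = 2, seed = 1)))
  expect_equal(s1$elastic_modulus, 344.09, tolerance = 0.02)
})

test_that("maximum compressive strength is the peak stress times the area", {
  rec <- generate_load_curve(load_curve_config(
    E_true = 300, F_peak_true = 940.80, yield_strain = 0.04, seed = 1))
  st <- max_compressive_strength(compute_stress_strain(rec))
  expect_equal(st$F_max, 940.80, tolerance = 1e-9)
  expect_equal(st$F_max, st$sigma_max * cylinder_contact_area())

  # sigma from a 32 N peak
  cv <- make_curve(c(0, 0.01), c(0, 32 / cylinder_contact_area()))
  st2 <- max_compressive_strength(cv)
  expect_equal(st2$sigma_max, 1.63, tolerance = 1e-2)

  # monotone curve peaks at the final sample
  eps <- seq(0, 0.03, by = 1e-3)
  st3 <- max_compressive_strength(make_curve(eps, 100 * eps))
  expect_equal(st3$sigma_max, 100 * max(eps))
})

test_that("replicate aggregation takes means and standard deviations", {
  one <- summarize_record(generate_load_curve(
    load_curve_config(E_true = 200, F_peak_true = 300, seed = 1)))
  agg5 <- aggregate_replicates(rep(list(one), 5))
  expect_equal(agg5$elastic_modulus, one$elastic_modulus)
  expect_equal(unname(agg5$replicate_sd["elastic_modulus"]), 0)
  expect_equal(agg5$replicate_n, 5L)

  mk <- function(E) { s <- one; s$elastic_modulus <- E; s }
  agg3 <- aggregate_replicates(lapply(c(100, 110, 120), mk))
  expect_equal(agg3$elastic_modulus, 110)
  expect_equal(unname(agg3$replicate_sd["elastic_modulus"]), 10)

  expect_error(aggregate_replicates(list()), "no replicate")
})

test_that("seeded 5-replicate noisy aggregate recovers E within 2%", {
  reps <- lapply(1:5, function(r) summarize_record(generate_load_curve(
    load_curve_config(E_true = 344.09, F_peak_true = 940.80,
                      yield_strain = 0.04, noise_sd = 2, seed = 100 + r))))
  agg <- aggregate_replicates(reps)
  expect_equal(agg$elastic_modulus, 344.09, tolerance = 0.02)
})

test_that("unit consistency: slope in N/mm times h0/A equals E", {
  rec <- generate_load_curve(load_curve_config(
    E_true = 250, F_peak_true = 600, yield_strain = 0.04, seed = 2))
  el <- rec$displacement <= 0.04 * 10 / 2  # safely inside the elastic ramp
  slope_N_mm <- coef(lm(rec$force[el] ~ rec$displacement[el]))[[2]]
  E <- estimate_elastic_modulus(compute_stress_strain(rec))$E
  expect_equal(E, slope_N_mm * 10 / cylinder_contact_area(),
               tolerance = 1e-8)
})

test_that("modulus is invariant to uniform resampling of a noiseless record", {
  base <- generate_load_curve(load_curve_config(
    E_true = 280, F_peak_true = 500, yield_strain = 0.04, seed = 3))
  half <- force_displacement_record(
    base$time[c(TRUE, FALSE)], base$force[c(TRUE, FALSE)],
    base$displacement[c(TRUE, FALSE)], preload = base$preload,
    sample_rate = base$sample_rate / 2)
  E1 <- estimate_elastic_modulus(compute_stress_strain(base))$E
  E2 <- estimate_elastic_modulus(compute_stress_strain(half))$E
  expect_equal(E1, E2, tolerance = 1e-6)
})

test_that("record duration and rate set the sample count", {
  rec <- generate_load_curve(load_curve_config(
    E_true = 300, F_peak_true = 500, yield_strain = 0.04, seed = 1,
    duration_s = 60))
  expect_length(rec$time, 240L)
  expect_equal(rec$force[1], 10)
})

test_that("config invariants and short-record errors are enforced", {
  expect_error(load_curve_config(E_true = 0, F_peak_true = 100), "E_true")
  expect_error(load_curve_config(E_true = 100, F_peak_true = 5), "preload")
  expect_error(load_curve_config(E_true = 300, F_peak_true = 50,
                                 yield_strain = 0.1), "yield_strain")
  expect_error(estimate_elastic_modulus(make_curve(seq(0, 1e-3, length.out = 9),
                                                   rep(1, 9))),
               "at least 10")
})

test_that("record CSV round trip preserves data and metadata", {
  rec <- generate_load_curve(load_curve_config(
    E_true = 300, F_peak_true = 500, yield_strain = 0.04, noise_sd = 1,
    seed = 5))
  path <- tempfile(fileext = ".csv")
  write_record(rec, path)
  back <- read_record(path)
  expect_equal(back$force, rec$force, tolerance = 1e-9)
  expect_equal(back$preload, rec$preload)
  expect_equal(back$sample_rate, rec$sample_rate)
  unlink(path)
})
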