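test_that("sinusoid generator is seeded, bounded, and straight at A = 0", {
  s1 <- make_sinusoid_vessel(5, 40, 120, seed = 9)
  s2 <- make_sinusoid_vessel(5, 40, 120, seed = 9)
  expect_identical(s1$image$pixels, s2$image$pixels)
  s3 <- make_sinusoid_vessel(5, 40, 120, seed = 10)
  expect_false(identical(s1$image$pixels, s3$image$pixels))

  straight <- make_sinusoid_vessel(0, 40, 120, seed = 1)
  expect_identical(compute_vti(straight$centerline)$vti, 0)
  expect_error(make_sinusoid_vessel(-1, 40, 120), "invalid")
})

test_that("truth centerline lies inside the rendered vessel band", {
  sv <- make_sinusoid_vessel(8, 50, 150, width_px = 3, seed = 4)
  expect_true(all(sv$truth_mask[sv$centerline$points]))
  expect_true(all(abs(diff(sv$centerline$points)) <= 1))
})

test_that("vessel trees are reproducible, nested, and report exact fractions", {
  t1 <- make_vessel_tree(8, seed = 5)
  t2 <- make_vessel_tree(8, seed = 5)
  expect_identical(t1$map$mask, t2$map$mask)
  expect_identical(t1$vessel_fraction, mean(t1$map$mask))
  t_small <- make_vessel_tree(5, seed = 5)
  t_big <- make_vessel_tree(20, seed = 5)
  expect_true(all(t_big$map$mask[t_small$map$mask]))  # same-seed nesting
  expect_gte(t_big$vessel_fraction, t_small$vessel_fraction)
})

test_that("Doppler phantom reports the analytic Poiseuille flow as truth", {
  meta <- scan_meta(ascan_rate_hz = 140000)
  one <- make_doppler_phantom(
    list(list(center_mm = c(1, 1), radius_mm = 0.05,
              peak_velocity_mm_s = 20)), meta = meta)
  expect_equal(one$true_total_flow, 20 * pi * 0.05^2 / 2 * 60)
  expect_equal(one$true_total_flow, 4.712, tolerance = 1e-3)

  two <- make_doppler_phantom(
    list(list(center_mm = c(0.7, 0.7), radius_mm = 0.05,
              peak_velocity_mm_s = 20),
         list(center_mm = c(1.4, 1.4), radius_mm = 0.04,
              peak_velocity_mm_s = 8)), meta = meta)
  expect_equal(two$true_total_flow,
               one$true_total_flow + 8 * pi * 0.04^2 / 2 * 60)

  zero <- make_doppler_phantom(
    list(list(center_mm = c(1, 1), radius_mm = 0.05,
              peak_velocity_mm_s = 0)), meta = meta)
  expect_identical(zero$true_total_flow, 0)
  ef <- suppressWarnings(
    total_retinal_blood_flow(zero$volumes, zero$vein_masks))
  expect_identical(ef$trbf, 0)
})

test_that("phantom enforces the phase-wrap limit of the scan protocol", {
  expect_error(make_doppler_phantom(
    list(list(center_mm = c(1, 1), radius_mm = 0.05,
              peak_velocity_mm_s = 20))), "wrap violation")
  expect_silent(make_doppler_phantom(
    list(list(center_mm = c(1, 1), radius_mm = 0.05,
              peak_velocity_mm_s = 10))))
})

test_that("phantom volumes are reproducible under a fixed seed", {
  meta <- scan_meta(ascan_rate_hz = 140000)
  args <- list(list(list(center_mm = c(1, 1), radius_mm = 0.05,
                         peak_velocity_mm_s = 15)))
  p1 <- make_doppler_phantom(args[[1]], meta = meta,
                             phase_noise_sd_rad = 0.1, seed = 2)
  p2 <- make_doppler_phantom(args[[1]], meta = meta,
                             phase_noise_sd_rad = 0.1, seed = 2)
  expect_identical(p1$volumes[[1]]$phase, p2$volumes[[1]]$phase)
})

test_that("default cohort reproduces the study layout", {
  co <- make_cohort(seed = 6)
  expect_identical(nrow(co$subjects), 31L)
  expect_identical(nrow(co$eyes), 41L)
  expect_identical(sum(co$eyes$group == "SCR"), 15L)
  expect_identical(sum(co$eyes$group == "NC"), 26L)
  expect_identical(table(co$subjects$sex, co$subjects$group)["M", "SCR"], 2L)
  expect_identical(table(co$subjects$sex, co$subjects$group)["M", "NC"], 10L)
  # one row per (subject, laterality)
  expect_false(any(duplicated(co$eyes[, c("subject_id", "laterality")])))
  # MAP column is realized from the blood-pressure readings
  expect_equal(co$subjects$map,
               vapply(co$subjects$bp_readings, mean_arterial_pressure,
                      numeric(1)))
  co2 <- make_cohort(seed = 6)
  expect_identical(co$eyes, co2$eyes)
})

test_that("large cohorts match the configured group means", {
  co <- make_cohort(n_scr = 10000, n_nc = 10000, scr_bilateral = 0,
                    nc_bilateral = 0, seed = 99)
  scr <- co$eyes$vti[co$eyes$group == "SCR"]
  nc <- co$eyes$vti[co$eyes$group == "NC"]
  expect_lt(abs(mean(scr) - 0.61), 3 * 0.36 / sqrt(length(scr)))
  expect_lt(abs(mean(nc) - 0.42), 3 * 0.11 / sqrt(length(nc)))
})

test_that("uncoupled cohorts give near-nominal type-I error for association", {
  rej <- vapply(1:200, function(s) {
    co <- make_cohort(coupling = list(outcome = "vti", slope = 0,
                                      subject_sd = 0.1, resid_sd = 0.1),
                      seed = 5000 + s)
    fit_association_model(co$eyes, "vti")$p_value <= 0.05
  }, logical(1))
  expect_lt(mean(rej), 0.11)
})
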