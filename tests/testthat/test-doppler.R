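test_that("phase-to-velocity follows the phase-resolved relation", {
  meta <- scan_meta()
  expect_identical(phase_to_velocity(0, meta), 0)
  v_pi <- 840e-6 * 70000 / (4 * 1.38)     # lambda * f / (4 n), mm/s
  expect_equal(phase_to_velocity(pi, meta), v_pi)
  expect_equal(v_pi, 10.652, tolerance = 1e-4)
  ph <- c(0.3, -1.2, 2.9)
  expect_equal(phase_to_velocity(-ph, meta), -phase_to_velocity(ph, meta))
  expect_error(phase_to_velocity(3.5, meta), "wrap")
  expect_equal(phase_to_velocity(velocity_to_phase(5, meta), meta), 5)
})

test_that("plane flow integrates velocity times pixel area", {
  meta <- scan_meta()            # pixel area = (2/500)*(2/80) = 1e-4 mm^2
  expect_equal(pixel_area_mm2(meta), 1e-4)
  v <- matrix(0, 80, 500)
  mask <- matrix(FALSE, 80, 500)
  mask[10:19, 21:30] <- TRUE     # 100 px -> 0.01 mm^2
  v[mask] <- 10
  expect_equal(plane_flow(v, mask, meta), 6)   # 0.1 uL/s = 6 uL/min
  expect_equal(plane_flow(matrix(0, 80, 500), mask, meta), 0)
  expect_warning(f0 <- plane_flow(v, matrix(FALSE, 80, 500), meta), "empty")
  expect_identical(f0, 0)
})

test_that("a finely-sampled parabolic profile integrates to v_peak*pi*R^2/2", {
  meta <- scan_meta(n_bscans = 400L, n_ascans = 400L)  # 5 um pixels
  dy <- meta$field_mm / meta$n_bscans
  y <- (seq_len(400) - 0.5) * dy - 1
  d2 <- outer(y^2, y^2, `+`)
  R <- 0.05
  v <- ifelse(d2 < R^2, 20 * (1 - d2 / R^2), 0)
  q <- plane_flow(v, d2 < R^2, meta)
  expect_equal(q, 20 * pi * R^2 / 2 * 60, tolerance = 0.03)
})

test_that("vein flow records the maximal en-face plane", {
  meta <- scan_meta(n_bscans = 16L, n_ascans = 20L)
  mask <- matrix(FALSE, 16, 20)
  mask[6:9, 6:9] <- TRUE
  base <- matrix(0, 16, 20)
  base[mask] <- 0.5
  phase <- array(0, c(16, 20, 3))
  for (z in 1:3) phase[, , z] <- base * c(3, 7, 5)[z] / 7
  vf <- vein_flow(doppler_volume(phase, meta), mask)
  expect_equal(which.max(abs(vf$plane_flows)), 2L)
  expect_equal(vf$max_flow, max(vf$plane_flows))
  expect_equal(vf$plane_flows[1] / vf$plane_flows[2], 3 / 7, tolerance = 1e-12)

  flat <- array(rep(base, 3), c(16, 20, 3))
  vf2 <- vein_flow(doppler_volume(flat, meta), mask)
  expect_equal(vf2$max_flow, vf2$plane_flows[1])
})

test_that("phantom vein flow peaks at the mid-vessel plane", {
  meta <- scan_meta(ascan_rate_hz = 140000)
  ph <- make_doppler_phantom(
    list(list(center_mm = c(1, 1), radius_mm = 0.05,
              peak_velocity_mm_s = 20)),
    meta = meta, n_depth = 16)
  vf <- vein_flow(ph$volumes[[1]], ph$vein_masks[[1]])
  peak <- which.max(abs(vf$plane_flows))
  expect_gt(peak, 4)
  expect_lt(peak, 13)
  expect_equal(vf$max_flow, ph$true_total_flow, tolerance = 0.05)
})

test_that("TRBF sums veins within a volume and averages across volumes", {
  meta <- scan_meta(n_bscans = 16L, n_ascans = 20L)
  m1 <- matrix(FALSE, 16, 20); m1[3:6, 3:6] <- TRUE
  m2 <- matrix(FALSE, 16, 20); m2[10:13, 10:13] <- TRUE
  px <- pixel_area_mm2(meta)
  v1 <- 30 / (sum(m1) * px * 60)          # uniform velocities giving 30, 40
  v2 <- 40 / (sum(m2) * px * 60)
  vel <- matrix(0, 16, 20); vel[m1] <- v1; vel[m2] <- v2
  phase <- array(velocity_to_phase(vel, meta), c(16, 20, 2))
  vol <- doppler_volume(phase, meta)
  ef <- suppressWarnings(total_retinal_blood_flow(vol, list(m1, m2)))
  expect_equal(ef$trbf, 70, tolerance = 1e-9)
  ef3 <- suppressWarnings(
    total_retinal_blood_flow(list(vol, vol, vol), list(m1, m2)))
  expect_equal(ef3$trbf, ef$trbf)
  expect_identical(ef3$n_volumes, 3L)
  expect_error(total_retinal_blood_flow(vol, list()), "no veins")
  expect_warning(total_retinal_blood_flow(vol, list(m1)), "fewer than 3")
})

test_that("flow is linear in phase and invariant to splitting a vein mask", {
  meta <- scan_meta(ascan_rate_hz = 140000)
  ph <- make_doppler_phantom(
    list(list(center_mm = c(1, 1), radius_mm = 0.05,
              peak_velocity_mm_s = 10)),
    meta = meta, n_depth = 12)
  ef1 <- suppressWarnings(
    total_retinal_blood_flow(ph$volumes, ph$vein_masks))
  scaled <- doppler_volume(ph$volumes[[1]]$phase * 0.5, meta)
  ef_half <- suppressWarnings(
    total_retinal_blood_flow(scaled, ph$vein_masks))
  expect_equal(ef_half$trbf, ef1$trbf * 0.5, tolerance = 1e-9)

  mask <- ph$vein_masks[[1]]
  left <- mask; left[, 251:500] <- FALSE
  right <- mask; right[, 1:250] <- FALSE
  ef_split <- suppressWarnings(
    total_retinal_blood_flow(ph$volumes, list(left, right)))
  expect_equal(ef_split$trbf, ef1$trbf, tolerance = 0.01)
})

test_that("Doppler volumes round-trip through binary + JSON sidecar files", {
  meta <- scan_meta(n_bscans = 16L, n_ascans = 20L)
  set.seed(8)
  phase <- array(runif(16 * 20 * 4, -pi, pi), c(16, 20, 4))
  vol <- doppler_volume(phase, meta)
  prefix <- tempfile()
  write_doppler_volume(vol, prefix)
  back <- read_doppler_volume(prefix)
  expect_identical(back$phase, vol$phase)
  expect_equal(unclass(back$meta), unclass(vol$meta))
})
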