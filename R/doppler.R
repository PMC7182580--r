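#' Doppler OCT scan metadata
#'
#' Acquisition parameters of the en-face Doppler OCT protocol: a 2 x 2 mm
#' raster centred on the optic nerve head, 80 B-scans of 500 A-scans each,
#' 840 nm centre wavelength at a 70 kHz A-scan rate, ~5 um axial resolution,
#' and a tissue group refractive index of 1.38.
#'
#' @param wavelength_nm Centre wavelength (nm).
#' @param ascan_rate_hz A-scan rate (Hz); the inter-A-scan time is its inverse.
#' @param depth_res_um Axial (depth) resolution (um).
#' @param field_mm En-face field width (mm).
#' @param n_bscans,n_ascans Raster dimensions.
#' @param refractive_index Tissue group index.
#' @return Object of class `scan_meta`.
#' @export
scan_meta <- function(wavelength_nm = 840, ascan_rate_hz = 70000,
                      depth_res_um = 5, field_mm = 2.0,
                      n_bscans = 80L, n_ascans = 500L,
                      refractive_index = 1.38) {
  vals <- c(wavelength_nm, ascan_rate_hz, depth_res_um, field_mm,
            n_bscans, n_ascans, refractive_index)
  if (anyNA(vals) || any(vals <= 0)) stop("all scan parameters must be positive")
  structure(list(wavelength_nm = wavelength_nm, ascan_rate_hz = ascan_rate_hz,
                 depth_res_um = depth_res_um, field_mm = field_mm,
                 n_bscans = as.integer(n_bscans),
                 n_ascans = as.integer(n_ascans),
                 refractive_index = refractive_index),
            class = "scan_meta")
}

#' En-face pixel area implied by scan metadata
#' @param meta A [scan_meta].
#' @return Pixel area in mm^2.
#' @export
pixel_area_mm2 <- function(meta) {
  (meta$field_mm / meta$n_ascans) * (meta$field_mm / meta$n_bscans)
}

#' Doppler phase-shift volume
#'
#' @param phase 3-D array (`n_bscans x n_ascans x n_depth`) of phase shifts in
#'   radians, each in `(-pi, pi]`.
#' @param meta A [scan_meta]; its raster dimensions must match `phase`.
#' @return Object of class `doppler_volume`.
#' @export
doppler_volume <- function(phase, meta = scan_meta()) {
  if (length(dim(phase)) != 3L) stop("phase must be a 3-D array")
  if (dim(phase)[1L] != meta$n_bscans || dim(phase)[2L] != meta$n_ascans)
    stop("phase dimensions do not match scan metadata")
  if (any(abs(phase) > pi + 1e-12))
    stop("phase values outside (-pi, pi]: wrapped data required")
  structure(list(phase = phase, meta = meta), class = "doppler_volume")
}

#' Convert Doppler phase shift to axial velocity
#'
#' Standard phase-resolved relation
#' `v = lambda * dphi / (4 * pi * n * tau)` with `tau = 1 / ascan_rate`;
#' the sign of the phase shift is preserved. With the default metadata a full
#' `pi` shift corresponds to ~10.65 mm/s.
#'
#' @param phase_rad Phase shift(s) in radians, each in `(-pi, pi]`.
#' @param meta A [scan_meta].
#' @return Axial velocity in mm/s (same shape as input).
#' @export
phase_to_velocity <- function(phase_rad, meta = scan_meta()) {
  if (any(abs(phase_rad) > pi + 1e-12))
    stop("phase outside (-pi, pi]: wrap error")
  lambda_mm <- meta$wavelength_nm * 1e-6
  tau <- 1 / meta$ascan_rate_hz
  lambda_mm * phase_rad / (4 * pi * meta$refractive_index * tau)
}

#' Inverse of [phase_to_velocity()]
#' @param v_mm_s Axial velocity in mm/s.
#' @inheritParams phase_to_velocity
#' @return Phase shift in radians (unchecked against the wrap limit).
#' @export
velocity_to_phase <- function(v_mm_s, meta = scan_meta()) {
  lambda_mm <- meta$wavelength_nm * 1e-6
  tau <- 1 / meta$ascan_rate_hz
  v_mm_s * 4 * pi * meta$refractive_index * tau / lambda_mm
}

#' Blood flow through a vein mask on one en-face plane
#'
#' Integrates axial velocity over the mask: `Q = sum(v) * pixel_area` in
#' mm^3/s (= uL/s), reported in uL/min. The en-face plane is normal to the
#' beam so no Doppler-angle correction is applied.
#'
#' @param velocity_plane Numeric matrix of axial velocities (mm/s).
#' @param vein_mask Logical matrix, same shape.
#' @param meta A [scan_meta].
#' @return Flow in uL/min (signed).
#' @export
plane_flow <- function(velocity_plane, vein_mask, meta = scan_meta()) {
  velocity_plane <- as.matrix(velocity_plane)
  vein_mask <- as.matrix(vein_mask) > 0
  if (!all(dim(velocity_plane) == dim(vein_mask)))
    stop("velocity plane and vein mask shapes differ")
  if (!any(vein_mask)) {
    warning("empty vein mask: flow is 0")
    return(0)
  }
  sum(velocity_plane[vein_mask]) * pixel_area_mm2(meta) * 60
}

#' Per-vein flow: maximum over en-face depth planes
#'
#' Computes the vein's flow on every en-face plane of the volume and records
#' the plane with the largest magnitude. Venous flow (toward the optic nerve
#' head) is reported positive.
#'
#' @param vol A [doppler_volume].
#' @param vein_mask A logical matrix applied to every depth plane, or a list
#'   with one mask per plane.
#' @param vein_id Identifier carried through to the result.
#' @return Object of class `vein_measurement`: list with `vein_id`,
#'   `plane_flows` (uL/min per plane) and `max_flow`.
#' @export
vein_flow <- function(vol, vein_mask, vein_id = 1L) {
  nz <- dim(vol$phase)[3L]
  if (nz < 1L) stop("volume has no en-face planes")
  masks <- if (is.list(vein_mask)) vein_mask else rep(list(vein_mask), nz)
  if (length(masks) != nz) stop("need one vein mask per en-face plane")
  flows <- vapply(seq_len(nz), function(z) {
    v <- phase_to_velocity(vol$phase[, , z], vol$meta)
    suppressWarnings(plane_flow(v, masks[[z]], vol$meta))
  }, numeric(1))
  structure(list(vein_id = vein_id, plane_flows = flows,
                 max_flow = max(abs(flows))),
            class = "vein_measurement")
}

#' Total retinal blood flow of an eye
#'
#' For each volume, sums the per-vein maximum flows; TRBF is the mean of the
#' per-volume sums. The study protocol averaged between 3 and 26 volumes per
#' eye; fewer than 3 triggers a warning.
#'
#' @param volumes List of [doppler_volume] objects (>= 1).
#' @param veins List of vein masks (one entry per vein; each a matrix or a
#'   per-plane list as in [vein_flow()]).
#' @return Object of class `eye_flow`: list with `per_volume_trbf`, `trbf`
#'   (uL/min) and `n_volumes`.
#' @export
total_retinal_blood_flow <- function(volumes, veins) {
  if (inherits(volumes, "doppler_volume")) volumes <- list(volumes)
  if (length(volumes) < 1L) stop("at least one Doppler volume required")
  if (length(veins) < 1L) stop("no veins detected")
  if (length(volumes) < 3L)
    warning("fewer than 3 volumes: TRBF average may be unstable")
  per_vol <- vapply(volumes, function(v) {
    sum(vapply(seq_along(veins), function(i)
      vein_flow(v, veins[[i]], vein_id = i)$max_flow, numeric(1)))
  }, numeric(1))
  structure(list(per_volume_trbf = per_vol, trbf = mean(per_vol),
                 n_volumes = length(volumes)),
            class = "eye_flow")
}

#' Write / read a Doppler volume as raw binary plus JSON sidecar
#'
#' The phase array is stored as little-endian doubles in `<prefix>.bin`; the
#' sidecar `<prefix>.json` holds the array dimensions and the full scan
#' metadata.
#'
#' @param vol A [doppler_volume].
#' @param prefix Path prefix (without extension).
#' @return `write_doppler_volume` the prefix, invisibly;
#'   `read_doppler_volume` the reconstructed [doppler_volume].
#' @export
write_doppler_volume <- function(vol, prefix) {
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(vol$phase), con, size = 8L, endian = "little")
  side <- c(list(dim = dim(vol$phase)), unclass(vol$meta))
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_doppler_volume
#' @export
read_doppler_volume <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  dm <- as.integer(side$dim)
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, what = "numeric", n = prod(dm), size = 8L,
               endian = "little")
  meta <- scan_meta(side$wavelength_nm, side$ascan_rate_hz, side$depth_res_um,
                    side$field_mm, side$n_bscans, side$n_ascans,
                    side$refractive_index)
  doppler_volume(array(x, dm), meta)
}
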