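# run expr with a locally-seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Synthetic sinusoidal vessel image with known centerline
#'
#' Renders a bright curvilinear band `y = A * sin(2 * pi * x / period)` of
#' given width on a dark background with additive Gaussian noise, and returns
#' the exact (rounded, 8-connected) ground-truth centerline alongside, so the
#' rendered image never has to be re-analysed to know the truth.
#'
#' @param amplitude_px Sinusoid amplitude (px); 0 gives a straight vessel.
#' @param period_px Sinusoid period (px).
#' @param length_px Horizontal extent (px).
#' @param width_px Vessel width (px).
#' @param contrast Foreground:background intensity ratio.
#' @param noise_sd Additive Gaussian noise SD (intensity units; background is
#'   20, vessel `20 * contrast`).
#' @param seed Integer seed (`NULL` uses the current RNG state).
#' @param margin_px Dark margin around the vessel.
#' @return List with `image` ([en_face_image]), `centerline` (truth
#'   [centerline]) and `truth_mask` (logical matrix of rendered vessel
#'   pixels).
#' @export
make_sinusoid_vessel <- function(amplitude_px, period_px, length_px,
                                 width_px = 3, contrast = 5, noise_sd = 8,
                                 seed = NULL, margin_px = 10) {
  if (amplitude_px < 0 || period_px <= 0 || length_px < 16 || width_px < 1)
    stop("invalid sinusoid specification")
  nrow_img <- ceiling(2 * amplitude_px + width_px + 2 * margin_px)
  nrow_img <- max(nrow_img, 16L)
  ncol_img <- max(ceiling(length_px), 16L)
  if (2 * amplitude_px + width_px > nrow_img)
    stop("amplitude too large for canvas")
  mid <- nrow_img / 2

  # dense sub-pixel sampling keeps the rounded path 8-connected
  dx <- min(0.25, period_px / (8 * pi * max(amplitude_px, 1)))
  xs <- seq(1, ncol_img, by = dx)
  ys <- mid + amplitude_px * sin(2 * pi * xs / period_px)
  rr <- round(ys); cc <- round(xs)
  keep <- c(TRUE, diff(rr) != 0 | diff(cc) != 0)
  path <- cbind(row = rr[keep], col = cc[keep])

  mask <- matrix(FALSE, nrow_img, ncol_img)
  half <- (width_px - 1) / 2
  offs <- expand.grid(dr = seq(-ceiling(half), ceiling(half)),
                      dc = seq(-ceiling(half), ceiling(half)))
  offs <- offs[offs$dr^2 + offs$dc^2 <= (half + 0.5)^2, , drop = FALSE]
  for (i in seq_len(nrow(offs))) {
    r <- path[, 1L] + offs$dr[i]
    c <- path[, 2L] + offs$dc[i]
    ok <- r >= 1 & r <= nrow_img & c >= 1 & c <= ncol_img
    mask[cbind(r[ok], c[ok])] <- TRUE
  }

  bg <- 20; fg <- 20 * contrast
  img <- with_seed(seed, {
    base <- matrix(bg, nrow_img, ncol_img)
    base[mask] <- fg
    pmax(base + matrix(stats::rnorm(length(base), 0, noise_sd),
                       nrow_img, ncol_img), 0)
  })
  list(image = en_face_image(img, scale_mm_per_px = 6 / ncol_img),
       centerline = centerline(path),
       truth_mask = mask)
}

# one smooth random stroke: a correlated random walk painted with a width
draw_stroke <- function(mask, start, heading, width, n_steps, turn_sd) {
  nr <- nrow(mask); nc <- ncol(mask)
  pos <- start; th <- heading
  half <- (width - 1) / 2
  offs <- expand.grid(dr = seq(-ceiling(half), ceiling(half)),
                      dc = seq(-ceiling(half), ceiling(half)))
  offs <- as.matrix(offs[offs$dr^2 + offs$dc^2 <= (half + 0.5)^2, ])
  pts <- matrix(NA_real_, n_steps, 2L)
  for (s in seq_len(n_steps)) {
    th <- th + stats::rnorm(1, 0, turn_sd)
    pos <- pos + c(sin(th), cos(th))
    if (pos[1] < 2 || pos[1] > nr - 1 || pos[2] < 2 || pos[2] > nc - 1) break
    pts[s, ] <- pos
    r <- round(pos[1]) + offs[, 1L]
    c <- round(pos[2]) + offs[, 2L]
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    mask[cbind(r[ok], c[ok])] <- TRUE
  }
  list(mask = mask, pts = pts[stats::complete.cases(pts), , drop = FALSE])
}

#' Synthetic branching vessel tree
#'
#' Paints `n_branches` smooth strokes on a blank canvas; after the first,
#' each stroke starts from a random point of an earlier stroke (a branch).
#' Strokes are seeded individually from `seed`, so trees with the same seed
#' are nested across increasing `n_branches` and the foreground fraction is
#' non-decreasing in the branch count.
#'
#' @param n_branches Number of strokes (>= 1).
#' @param width_range Stroke width range (px), sampled per stroke.
#' @param canvas Canvas dimensions `c(rows, cols)`.
#' @param seed Integer seed.
#' @return List with `map` ([vessel_map]) and `vessel_fraction` (the exact
#'   painted foreground fraction).
#' @export
make_vessel_tree <- function(n_branches, width_range = c(2, 5),
                             canvas = c(200L, 200L), seed = 1L) {
  if (n_branches < 1) stop("n_branches must be >= 1")
  mask <- matrix(FALSE, canvas[1L], canvas[2L])
  anchors <- NULL
  for (b in seq_len(n_branches)) {
    res <- with_seed(if (is.null(seed)) NULL else seed + 1000L * b, {
      w <- round(stats::runif(1, width_range[1L], width_range[2L]))
      if (b == 1L || is.null(anchors) || nrow(anchors) == 0L) {
        start <- c(stats::runif(1, canvas[1L] * 0.2, canvas[1L] * 0.8),
                   stats::runif(1, canvas[2L] * 0.2, canvas[2L] * 0.8))
      } else {
        start <- anchors[sample.int(nrow(anchors), 1L), ]
      }
      heading <- stats::runif(1, 0, 2 * pi)
      n_steps <- round(stats::runif(1, 40, 120))
      draw_stroke(mask, start, heading, w, n_steps, turn_sd = 0.08)
    })
    mask <- res$mask
    if (nrow(res$pts)) anchors <- rbind(anchors, res$pts)
  }
  list(map = vessel_map(mask), vessel_fraction = mean(mask))
}

#' Doppler flow phantom with known total flow
#'
#' Builds Doppler phase volumes containing cylindrical veins with parabolic
#' (Poiseuille) axial-velocity profiles, `v(r) = v_peak * (1 - (r/R)^2)`, so
#' the true volumetric flow of each vein is the analytic
#' `Q = v_peak * pi * R^2 / 2` (in uL/min after the x60 conversion). Pixels
#' are rendered by supersampled averaging of the velocity field, so the
#' discrete mask sum reproduces the analytic integral closely. Each vein
#' spans a contiguous depth range with an axial envelope equal to 1 only at
#' the mid-vessel plane, which therefore carries the maximal flow. Optional
#' Gaussian phase noise is added per volume and re-wrapped to `(-pi, pi]`.
#'
#' @param veins List of veins, each
#'   `list(center_mm = c(y, x), radius_mm, peak_velocity_mm_s)`.
#' @param meta A [scan_meta]; peak velocities must stay below its phase-wrap
#'   limit.
#' @param phase_noise_sd_rad Phase noise SD (radians).
#' @param n_volumes Number of repeated volumes.
#' @param n_depth Number of en-face depth planes.
#' @param seed Integer seed for the noise.
#' @param supersample Sub-pixel sampling factor per axis.
#' @return List with `volumes` (list of [doppler_volume]), `vein_masks`
#'   (one logical matrix per vein) and `true_total_flow` (uL/min).
#' @export
make_doppler_phantom <- function(veins, meta = scan_meta(),
                                 phase_noise_sd_rad = 0, n_volumes = 1L,
                                 n_depth = 16L, seed = NULL,
                                 supersample = 6L) {
  if (!length(veins)) stop("phantom needs at least one vein")
  wrap_v <- phase_to_velocity(pi, meta)
  for (vn in veins) {
    if (vn$peak_velocity_mm_s > wrap_v + 1e-12)
      stop("wrap violation: peak velocity ", vn$peak_velocity_mm_s,
           " mm/s exceeds the phase-wrap limit ", signif(wrap_v, 6), " mm/s")
    if (2 * vn$radius_mm >= meta$field_mm)
      stop("vein does not fit within the field")
  }
  dy <- meta$field_mm / meta$n_bscans
  dx <- meta$field_mm / meta$n_ascans
  base <- matrix(0, meta$n_bscans, meta$n_ascans)
  masks <- vector("list", length(veins))
  ss <- (seq_len(supersample) - 0.5) / supersample

  for (k in seq_along(veins)) {
    vn <- veins[[k]]
    r0 <- vn$center_mm[1L]; c0 <- vn$center_mm[2L]; R <- vn$radius_mm
    rows <- which(abs((seq_len(meta$n_bscans) - 0.5) * dy - r0) <= R + dy)
    cols <- which(abs((seq_len(meta$n_ascans) - 0.5) * dx - c0) <= R + dx)
    mk <- matrix(FALSE, meta$n_bscans, meta$n_ascans)
    for (i in rows) for (j in cols) {
      yy <- (i - 1 + ss) * dy - r0
      xx <- (j - 1 + ss) * dx - c0
      d2 <- outer(yy^2, xx^2, `+`)
      inside <- d2 < R^2
      if (!any(inside)) next
      v <- vn$peak_velocity_mm_s * (1 - d2 / R^2)
      base[i, j] <- base[i, j] + sum(v[inside]) / length(d2)
      mk[i, j] <- TRUE
    }
    masks[[k]] <- mk
  }
  phase_plane <- velocity_to_phase(base, meta)

  # axial envelope: vessel occupies the middle half of the depth range,
  # tapering linearly to the ends, exactly 1 only at the mid-vessel plane
  z1 <- max(1L, floor(n_depth / 4) + 1L)
  z2 <- min(n_depth, z1 + max(2L, floor(n_depth / 2)) - 1L)
  zm <- (z1 + z2) / 2
  env <- numeric(n_depth)
  span <- max(z2 - zm, 1)
  env[z1:z2] <- 1 - 0.7 * abs((z1:z2) - zm) / span
  zmid <- z1:z2
  env[zmid[which.min(abs(zmid - zm))]] <- 1

  make_vol <- function(s) {
    phase <- array(0, c(meta$n_bscans, meta$n_ascans, n_depth))
    for (z in seq_len(n_depth)) phase[, , z] <- phase_plane * env[z]
    if (phase_noise_sd_rad > 0) {
      phase <- with_seed(s, phase + stats::rnorm(length(phase), 0,
                                                 phase_noise_sd_rad))
      phase <- wrap_angle(phase)
    }
    doppler_volume(phase, meta)
  }
  seeds <- if (is.null(seed)) vector("list", n_volumes)
           else as.list(seed + seq_len(n_volumes))
  volumes <- lapply(seeds, make_vol)
  true_total <- sum(vapply(veins, function(vn)
    vn$peak_velocity_mm_s * pi * vn$radius_mm^2 / 2 * 60, numeric(1)))
  list(volumes = volumes, vein_masks = masks, true_total_flow = true_total)
}

#' Study-condition group summaries for the synthetic cohort
#'
#' Default per-group means and SDs for the cohort generator: VTI, VD, SSV,
#' SLV, TRBF (uL/min), MAP (mmHg), haematocrit (%) and age (years) for the
#' sickle cell retinopathy (SCR) and normal control (NC) groups.
#'
#' @return Named list; each element is
#'   `c(scr_mean, scr_sd, nc_mean, nc_sd)`.
#' @export
cohort_group_defaults <- function() {
  list(
    vti = c(scr_mean = 0.61, scr_sd = 0.36, nc_mean = 0.42, nc_sd = 0.11),
    vd = c(scr_mean = 0.51, scr_sd = 0.06, nc_mean = 0.50, nc_sd = 0.04),
    ssv = c(scr_mean = 0.32, scr_sd = 0.02, nc_mean = 0.35, nc_sd = 0.01),
    slv = c(scr_mean = 0.17, scr_sd = 0.05, nc_mean = 0.15, nc_sd = 0.03),
    trbf = c(scr_mean = 70.42, scr_sd = 32.30, nc_mean = 45.85, nc_sd = 11.97),
    map = c(scr_mean = 86, scr_sd = 13, nc_mean = 102, nc_sd = 13),
    haematocrit = c(scr_mean = 29, scr_sd = 4, nc_mean = 44, nc_sd = 3),
    age = c(scr_mean = 44, scr_sd = 14, nc_mean = 36, nc_sd = 15)
  )
}

#' Synthetic two-group cohort with subject-level random effects
#'
#' Samples a sickle cell retinopathy (SCR) vs normal control (NC) cohort at
#' the study's size: 12 SCR subjects contributing 15 eyes and 19 NC subjects
#' contributing 26 eyes (both eyes for the first `scr_bilateral` /
#' `nc_bilateral` subjects of each group). Each eye-level metric is
#' `group mean + subject effect + residual` with the subject share of the
#' variance set by `icc`, so the marginal SD matches the configured group SD.
#' Sex follows the study counts (SCR 2 M / 10 F; NC 10 M / 9 F). MAP is
#' realized through three synthetic (systolic, diastolic) readings whose
#' per-reading MAPs average to the sampled value.
#'
#' An optional linear coupling replaces the marginal draw of one outcome by
#' `group mean + slope * (trbf - group mean trbf) / 100 + u + e` with
#' user-set subject / residual SDs, giving a known association slope per
#' 100 uL/min of TRBF for parameter-recovery experiments.
#'
#' @param n_scr,n_nc Subjects per group.
#' @param scr_bilateral,nc_bilateral Subjects of each group contributing both
#'   eyes.
#' @param group_stats Named list as [cohort_group_defaults()].
#' @param icc Intraclass correlation: subject share of each metric's variance.
#' @param coupling `NULL`, or `list(outcome, slope, subject_sd, resid_sd)`.
#' @param seed Integer seed.
#' @return List with data frames `subjects` (subject_id, group, sex, age,
#'   map, haematocrit, bp readings) and `eyes` (subject_id, group,
#'   laterality, vti, vd, ssv, slv, trbf_ul_min, map).
#' @export
make_cohort <- function(n_scr = 12L, n_nc = 19L,
                        scr_bilateral = 3L, nc_bilateral = 7L,
                        group_stats = cohort_group_defaults(),
                        icc = 0.5, coupling = NULL, seed = NULL) {
  stopifnot(scr_bilateral <= n_scr, nc_bilateral <= n_nc)
  with_seed(seed, {
    groups <- c(rep("SCR", n_scr), rep("NC", n_nc))
    ids <- sprintf("S%02d", seq_along(groups))
    sex <- c(rep(c("M", "F"), c(2L, n_scr - 2L))[seq_len(n_scr)],
             rep(c("M", "F"), c(10L, max(n_nc - 10L, 0L)))[seq_len(n_nc)])
    bilateral <- c(seq_len(n_scr) <= scr_bilateral,
                   seq_len(n_nc) <= nc_bilateral)

    gpar <- function(metric, grp, which) {
      v <- group_stats[[metric]]
      unname(v[paste0(ifelse(grp == "SCR", "scr_", "nc_"), which)])
    }
    age <- stats::rnorm(length(ids), gpar("age", groups, "mean"),
                        gpar("age", groups, "sd"))
    map <- stats::rnorm(length(ids), gpar("map", groups, "mean"),
                        gpar("map", groups, "sd"))
    hct <- pmin(pmax(stats::rnorm(length(ids),
                                  gpar("haematocrit", groups, "mean"),
                                  gpar("haematocrit", groups, "sd")), 5), 95)
    # three BP readings whose per-reading MAPs average to the sampled MAP
    bp <- lapply(map, function(m) {
      jitter <- stats::rnorm(3L, 0, 2)
      jitter <- jitter - mean(jitter)
      dbp <- m - 40 / 3 + jitter
      cbind(systolic = dbp + 40, diastolic = dbp)
    })
    map_realized <- vapply(bp, mean_arterial_pressure, numeric(1))

    subjects <- data.frame(subject_id = ids, group = groups, sex = sex,
                           age = age, map = map_realized,
                           haematocrit = hct, stringsAsFactors = FALSE)
    subjects$bp_readings <- bp

    lat_single <- sample(c("OD", "OS"), length(ids), replace = TRUE)
    eye_rows <- do.call(rbind, lapply(seq_along(ids), function(i) {
      lats <- if (bilateral[i]) c("OD", "OS") else lat_single[i]
      data.frame(subject_id = ids[i], group = groups[i], laterality = lats,
                 stringsAsFactors = FALSE)
    }))
    n_eyes <- nrow(eye_rows)
    sidx <- match(eye_rows$subject_id, ids)

    draw_metric <- function(metric) {
      mu <- gpar(metric, eye_rows$group, "mean")
      sd_tot <- gpar(metric, eye_rows$group, "sd")
      u <- stats::rnorm(length(ids)) # per-subject standard-normal effect
      mu + sd_tot * (sqrt(icc) * u[sidx] +
                     sqrt(1 - icc) * stats::rnorm(n_eyes))
    }
    eye_rows$trbf_ul_min <- pmax(draw_metric("trbf"), 1)
    for (metric in c("vti", "vd", "ssv", "slv")) {
      if (!is.null(coupling) && identical(coupling$outcome, metric)) {
        # common intercept: the outcome's group structure then arises solely
        # through TRBF, so the association model is correctly specified and
        # the configured slope is the exact estimand
        mu0 <- mean(gpar(metric, c("SCR", "NC"), "mean"))
        mu_trbf <- mean(gpar("trbf", c("SCR", "NC"), "mean"))
        u <- stats::rnorm(length(ids), 0, coupling$subject_sd)
        eye_rows[[metric]] <- mu0 +
          coupling$slope * (eye_rows$trbf_ul_min - mu_trbf) / 100 +
          u[sidx] + stats::rnorm(n_eyes, 0, coupling$resid_sd)
      } else {
        eye_rows[[metric]] <- draw_metric(metric)
      }
    }
    eye_rows$map <- subjects$map[sidx]
    list(subjects = subjects,
         eyes = eye_rows[, c("subject_id", "group", "laterality", "vti",
                             "vd", "ssv", "slv", "trbf_ul_min", "map")])
  })
}
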