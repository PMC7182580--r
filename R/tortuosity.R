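#' Local tangent angles of a centerline relative to its chord
#'
#' At each interior point the tangent direction is estimated by a central
#' difference over `+/- step` points and measured against the direction of the
#' segment chord (first to last point). Angles are wrapped to (-pi, pi].
#'
#' @param c A [centerline] with at least `2 * step + 1` points.
#' @param step Half-width (in points) of the central difference.
#' @return Numeric vector of angles in radians, one per interior point.
#' @export
tangent_angles <- function(c, step = 2L) {
  pts <- centerline_pts(c)
  n <- nrow(pts)
  step <- as.integer(step)
  if (step < 1L) stop("step must be >= 1")
  if (n < 2L * step + 1L) stop("segment too short for tangent estimation")
  chord_ang <- atan2(pts[n, 1L] - pts[1L, 1L], pts[n, 2L] - pts[1L, 2L])
  i <- (step + 1L):(n - step)
  tang <- atan2(pts[i + step, 1L] - pts[i - step, 1L],
                pts[i + step, 2L] - pts[i - step, 2L])
  wrap_angle(tang - chord_ang)
}

# wrap to (-pi, pi]
wrap_angle <- function(x) {
  w <- x %% (2 * pi)
  w[w > pi] <- w[w > pi] - 2 * pi
  w
}

centerline_pts <- function(c) {
  if (inherits(c, "centerline")) c$points else {
    p <- as.matrix(c)
    if (ncol(p) != 2L) stop("expected a centerline or a two-column matrix")
    p
  }
}

#' Vessel tortuosity index of one centerline
#'
#' Computes the VTI, `0.1 * SD_theta * N * M * L_A / L_C`, where `SD_theta` is
#' the standard deviation of the local tangent-angle changes relative to the
#' chord, `N` the number of critical points of the chord-deviation profile
#' (local extrema, detected as sign changes of its first difference with a
#' small tolerance `eps` against flat-profile jitter), `M` the mean absolute
#' deviation-profile value at the critical points normalized by the chord
#' length, `L_A` the arc length and `L_C` the chord length. A straight segment
#' has no critical points and zero angle spread, hence VTI = 0.
#'
#' @param c A [centerline].
#' @param step Tangent central-difference half-width (points).
#' @param eps Tolerance below which first differences of the deviation profile
#'   are treated as flat.
#' @return An object of class `tortuosity_components`: list with `sd_theta`,
#'   `n_critical`, `m_amplitude`, `l_a`, `l_c`, `vti`.
#' @export
compute_vti <- function(c, step = 2L, eps = 1e-6) {
  pts <- centerline_pts(c)
  n <- nrow(pts)
  if (n < 2L * step + 2L) stop("segment too short for tangent estimation")
  d <- diff(pts)
  l_a <- sum(sqrt(rowSums(d^2)))
  chord <- pts[n, ] - pts[1L, ]
  l_c <- sqrt(sum(chord^2))
  if (l_c <= eps) stop("degenerate segment: zero chord length")
  ang <- tangent_angles(c, step = step)
  sd_theta <- stats::sd(ang)

  # signed perpendicular deviation of each point from the chord line
  u <- chord / l_c
  rel_r <- pts[, 1L] - pts[1L, 1L]
  rel_c <- pts[, 2L] - pts[1L, 2L]
  dev <- rel_r * u[2L] - rel_c * u[1L]

  dd <- diff(dev)
  s <- sign(dd)
  s[abs(dd) < eps] <- 0
  crit <- integer(0)
  last <- 0
  for (i in seq_along(s)) {
    if (s[i] == 0) next
    if (last != 0 && s[i] != last) crit <- c(crit, i)
    last <- s[i]
  }
  n_critical <- length(crit)
  m_amplitude <- if (n_critical > 0) mean(abs(dev[crit])) / l_c else 0
  vti <- if (n_critical == 0) 0 else
    0.1 * sd_theta * n_critical * m_amplitude * l_a / l_c
  structure(list(sd_theta = sd_theta, n_critical = n_critical,
                 m_amplitude = m_amplitude, l_a = l_a, l_c = l_c, vti = vti),
            class = "tortuosity_components")
}

#' Per-eye mean vessel tortuosity index
#'
#' @param components Non-empty list of `tortuosity_components` (or a numeric
#'   vector of VTI values).
#' @return List with `mean_vti` and `n_segments`.
#' @export
eye_mean_vti <- function(components) {
  if (length(components) == 0L) stop("no segments: cannot average VTI")
  v <- if (is.numeric(components)) components
       else vapply(components, function(x) x$vti, numeric(1))
  list(mean_vti = mean(v), n_segments = length(v))
}

#' Mean VTI of all sufficiently long centerlines of a vessel map
#'
#' Convenience wrapper: extracts centerlines, computes the VTI for each,
#' silently skipping segments that are too short for tangent estimation, and
#' averages per eye.
#'
#' @inheritParams extract_centerlines
#' @inheritParams compute_vti
#' @return List with `mean_vti`, `n_segments`, and `segments` (the per-segment
#'   component lists).
#' @export
eye_vti_from_mask <- function(map, min_length_px = 10L, step = 2L) {
  cls <- extract_centerlines(map, min_length_px = min_length_px)
  comps <- list()
  for (cl in cls) {
    res <- tryCatch(compute_vti(cl, step = step), error = function(e) NULL)
    if (!is.null(res)) comps[[length(comps) + 1L]] <- res
  }
  if (!length(comps)) stop("no usable segments for VTI")
  c(eye_mean_vti(comps), list(segments = comps))
}
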