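#' Local fractal dimension map of a binary vessel image
#'
#' For every pixel a box-counting dimension is estimated inside a centred
#' moving window (default 3 x 3) at the two available box scales: box size 1
#' (count `N1` = foreground pixels in the window) and box size `window`
#' (count 1 if the window holds any foreground, else 0). The LFD is
#' `log(N1) / log(window)` where the window is non-empty and 0 elsewhere, so
#' values lie in `[0, 2]`. Image borders are zero-padded.
#'
#' @param map A [vessel_map] or logical/0-1 matrix.
#' @param window Odd window size >= 3.
#' @return Numeric matrix of local fractal dimensions, same shape as input.
#' @export
local_fractal_dimension <- function(map, window = 3L) {
  if (!is.numeric(window) || length(window) != 1L || window < 3 ||
      window %% 2 == 0)
    stop("window must be an odd integer >= 3")
  window <- as.integer(window)
  mask <- if (inherits(map, "vessel_map")) map$mask else as.matrix(map) > 0
  m <- mask * 1L
  h <- (window - 1L) %/% 2L
  n1 <- matrix(0L, nrow(m), ncol(m))
  for (dr in -h:h) for (dc in -h:h) n1 <- n1 + shift_mat(m, dr, dc)
  lfd <- matrix(0, nrow(m), ncol(m))
  nz <- n1 > 0L
  lfd[nz] <- log(n1[nz]) / log(window)
  lfd
}

#' Fractal-dimension-ratio map
#'
#' Normalizes a local-fractal-dimension grid by its global maximum so the
#' result lies in `[0, 1]`; an all-zero grid maps to all zeros.
#'
#' @param lfd Non-negative numeric matrix, e.g. from
#'   [local_fractal_dimension()].
#' @return Object of class `fdr_map`: list with `lfd` and `fdr` matrices.
#' @export
fdr_map <- function(lfd) {
  lfd <- as.matrix(lfd)
  if (anyNA(lfd) || any(lfd < 0)) stop("lfd grid must be non-negative")
  mx <- max(lfd)
  fdr <- if (mx > 0) lfd / mx else lfd * 0
  structure(list(lfd = lfd, fdr = fdr), class = "fdr_map")
}

#' Vessel-density / vessel-spacing partition of an FDR map
#'
#' Partitions pixels into vessel density (VD, `0.7 <= FDR <= 1`, large and
#' small vessels), spacing between small vessels (SSV, `0.3 < FDR < 0.7`) and
#' spacing between large vessels (SLV, `0 <= FDR <= 0.3`), each reported as a
#' fraction of all image pixels. SLV is computed as the complement
#' `1 - vd - ssv` so the three fractions always sum to exactly 1 (SLV agrees
#' with its own pixel-count ratio to within one floating-point ulp).
#'
#' @param m An [fdr_map] (or a numeric matrix of FDR values in `[0, 1]`).
#' @param low,high Band thresholds (defaults 0.3 and 0.7).
#' @return Object of class `lfd_metrics`: list with `vd`, `ssv`, `slv`.
#' @export
lfd_metrics <- function(m, low = 0.3, high = 0.7) {
  fdr <- if (inherits(m, "fdr_map")) m$fdr else as.matrix(m)
  if (anyNA(fdr) || any(fdr < 0) || any(fdr > 1))
    stop("FDR values must lie in [0, 1]")
  if (!(low > 0 && low < high && high < 1))
    stop("thresholds must satisfy 0 < low < high < 1")
  n <- length(fdr)
  vd <- sum(fdr >= high) / n
  ssv <- sum(fdr > low & fdr < high) / n
  structure(list(vd = vd, ssv = ssv, slv = 1 - (vd + ssv)),
            class = "lfd_metrics")
}

#' All LFD metrics of a binary vessel map
#'
#' Convenience wrapper chaining [local_fractal_dimension()], [fdr_map()] and
#' [lfd_metrics()].
#'
#' @inheritParams local_fractal_dimension
#' @inheritParams lfd_metrics
#' @export
lfd_metrics_from_mask <- function(map, window = 3L, low = 0.3, high = 0.7) {
  lfd_metrics(fdr_map(local_fractal_dimension(map, window)), low, high)
}
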