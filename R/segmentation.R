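#' En-face OCTA image
#'
#' Container for a grayscale en-face OCT angiography image of the superficial
#' capillary plexus, as acquired over a 6 x 6 mm macular field.
#'
#' @param pixels Numeric matrix of non-negative intensities (arbitrary units),
#'   at least 16 x 16.
#' @param scale_mm_per_px Physical size of one pixel in mm (> 0).
#' @param field_mm Nominal field width in mm.
#' @param laterality `"OD"`, `"OS"` or `"unknown"`.
#' @param quality Optional instrument scan-quality score.
#'
#' @return An object of class `en_face_image`.
#' @export
en_face_image <- function(pixels, scale_mm_per_px, field_mm = 6.0,
                          laterality = c("unknown", "OD", "OS"),
                          quality = NA_real_) {
  laterality <- match.arg(laterality)
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels)) stop("pixels must be numeric")
  if (nrow(pixels) < 16L || ncol(pixels) < 16L)
    stop("image must be at least 16 x 16 pixels")
  if (anyNA(pixels) || any(pixels < 0))
    stop("pixel intensities must be non-negative and finite")
  if (!is.numeric(scale_mm_per_px) || length(scale_mm_per_px) != 1L ||
      scale_mm_per_px <= 0)
    stop("scale_mm_per_px must be a positive scalar")
  structure(
    list(pixels = pixels, scale = scale_mm_per_px, field_mm = field_mm,
         laterality = laterality, quality = quality),
    class = "en_face_image"
  )
}

#' Binary vessel map
#'
#' @param mask Logical matrix; `TRUE` marks vessel (foreground) pixels.
#' @return An object of class `vessel_map` with elements `mask` and
#'   `vessel_fraction` (foreground pixels / total pixels).
#' @export
vessel_map <- function(mask) {
  mask <- as.matrix(mask)
  if (is.numeric(mask)) mask <- mask > 0
  if (!is.logical(mask) || anyNA(mask)) stop("mask must be logical without NA")
  structure(list(mask = mask, vessel_fraction = mean(mask)),
            class = "vessel_map")
}

#' Ordered vessel centerline
#'
#' An ordered pixel path of a vessel segment between bifurcation points
#' (0-based (row, col) coordinates are not used; coordinates here are R's
#' 1-based matrix indices, converted on CSV export).
#'
#' @param points Two-column numeric matrix of (row, col) coordinates, ordered
#'   from one endpoint to the other, with at least 2 points and no consecutive
#'   repeats. When all coordinates are whole numbers, consecutive points must
#'   be 8-connected.
#' @return Object of class `centerline`.
#' @export
centerline <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 2L || nrow(points) < 2L)
    stop("centerline needs a two-column matrix with >= 2 points")
  storage.mode(points) <- "double"
  d <- diff(points)
  if (any(rowSums(abs(d)) == 0)) stop("centerline has repeated points")
  if (all(points == round(points)) && any(abs(d) > 1))
    stop("consecutive centerline pixels must be 8-connected")
  dimnames(points) <- list(NULL, c("row", "col"))
  structure(list(points = points,
                 endpoints = points[c(1L, nrow(points)), , drop = FALSE]),
            class = "centerline")
}

#' Segment vessels by intensity k-means
#'
#' Clusters pixel intensities with 1-D k-means (Lloyd's algorithm, centers
#' initialized evenly between the intensity minimum and maximum, run to
#' convergence) and returns the brightest cluster as the binary vessel map.
#' With `k = 2` this reduces to a deterministic midpoint-style threshold
#' between the two converged cluster centers.
#'
#' @param image An [en_face_image] or a numeric matrix.
#' @param k Number of intensity clusters (>= 2).
#' @return A [vessel_map].
#' @export
binarize_vessels <- function(image, k = 2L) {
  px <- if (inherits(image, "en_face_image")) image$pixels else as.matrix(image)
  if (!is.numeric(k) || length(k) != 1L || k < 2)
    stop("k must be at least 2")
  k <- as.integer(k)
  v <- as.numeric(px)
  rng <- range(v)
  if (length(unique(v)) < 2L || diff(rng) == 0)
    stop("degenerate input: image has fewer than 2 distinct intensity values")
  if (length(unique(v)) < k)
    stop("degenerate input: fewer distinct intensities than clusters")
  centers <- matrix(seq(rng[1], rng[2], length.out = k), ncol = 1L)
  km <- suppressWarnings(
    stats::kmeans(v, centers = centers, iter.max = 200L, algorithm = "Lloyd")
  )
  fg <- which.max(km$centers[, 1L])
  vessel_map(matrix(km$cluster == fg, nrow(px), ncol(px)))
}

# shift a matrix by (dr, dc), zero-filling: out[i, j] = m[i + dr, j + dc]
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  sr <- max(1L, 1L + dr):min(nr, nr + dr)
  sc <- max(1L, 1L + dc):min(nc, nc + dc)
  out[sr - dr, sc - dc] <- m[sr, sc]
  out
}

# number of foreground 8-neighbours of every pixel
neighbour_count <- function(m) {
  m <- m * 1L
  shift_mat(m, -1L, 0L) + shift_mat(m, -1L, 1L) + shift_mat(m, 0L, 1L) +
    shift_mat(m, 1L, 1L) + shift_mat(m, 1L, 0L) + shift_mat(m, 1L, -1L) +
    shift_mat(m, 0L, -1L) + shift_mat(m, -1L, -1L)
}

# Zhang-Suen thinning: iteratively peels border pixels, preserving
# 8-connectivity, until a unit-width skeleton remains.
skeletonize_mask <- function(mask) {
  m <- mask * 1L
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      # neighbours clockwise from north
      P2 <- shift_mat(m, -1L, 0L);  P3 <- shift_mat(m, -1L, 1L)
      P4 <- shift_mat(m, 0L, 1L);   P5 <- shift_mat(m, 1L, 1L)
      P6 <- shift_mat(m, 1L, 0L);   P7 <- shift_mat(m, 1L, -1L)
      P8 <- shift_mat(m, 0L, -1L);  P9 <- shift_mat(m, -1L, -1L)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (P2 == 0L & P3 == 1L) + (P3 == 0L & P4 == 1L) +
           (P4 == 0L & P5 == 1L) + (P5 == 0L & P6 == 1L) +
           (P6 == 0L & P7 == 1L) + (P7 == 0L & P8 == 1L) +
           (P8 == 0L & P9 == 1L) + (P9 == 0L & P2 == 1L)
      del <- m == 1L & B >= 2L & B <= 6L & A == 1L
      if (pass == 1L) {
        del <- del & (P2 * P4 * P6 == 0L) & (P4 * P6 * P8 == 0L)
      } else {
        del <- del & (P2 * P4 * P8 == 0L) & (P2 * P6 * P8 == 0L)
      }
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

# strict 8-thinning: sequentially delete non-endpoint skeleton pixels whose
# foreground neighbours remain mutually 8-connected without them (removes the
# 2-px staircase redundancies Zhang-Suen leaves on diagonal runs)
prune_redundant <- function(sk) {
  nr <- nrow(sk); nc <- ncol(sk)
  offs <- cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
                dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  repeat {
    changed <- FALSE
    for (p in which(sk)) {
      r <- (p - 1L) %% nr + 1L
      c <- (p - 1L) %/% nr + 1L
      nb <- offs[sk[cbind(pmin(pmax(r + offs[, 1L], 1L), nr),
                          pmin(pmax(c + offs[, 2L], 1L), nc))] &
                   r + offs[, 1L] >= 1L & r + offs[, 1L] <= nr &
                   c + offs[, 2L] >= 1L & c + offs[, 2L] <= nc, ,
                 drop = FALSE]
      k <- nrow(nb)
      if (k < 2L) next
      # BFS over the neighbour set using mutual 8-adjacency
      seen <- logical(k)
      seen[1L] <- TRUE
      queue <- 1L
      while (length(queue)) {
        i <- queue[1L]; queue <- queue[-1L]
        for (j in seq_len(k)) {
          if (!seen[j] &&
              max(abs(nb[i, 1L] - nb[j, 1L]),
                  abs(nb[i, 2L] - nb[j, 2L])) <= 1L) {
            seen[j] <- TRUE
            queue <- c(queue, j)
          }
        }
      }
      if (all(seen)) {
        sk[p] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sk
}

# extend skeleton tips straight along their local direction to the vessel
# endpoint on the mask (thinning retracts line ends by about the half-width)
extend_endpoints <- function(sk, mask, max_steps = 50L) {
  nr <- nrow(sk); nc <- ncol(sk)
  nb <- neighbour_count(sk)
  ends <- which(sk & nb == 1L)
  for (p in ends) {
    r <- (p - 1L) %% nr + 1L
    c <- (p - 1L) %/% nr + 1L
    # the unique skeleton neighbour gives the outward direction
    dr <- dc <- 0L
    for (ddr in -1:1) for (ddc in -1:1) {
      if (ddr == 0L && ddc == 0L) next
      rr <- r + ddr; cc <- c + ddc
      if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc && sk[rr, cc]) {
        dr <- -ddr; dc <- -ddc
      }
    }
    if (dr == 0L && dc == 0L) next
    for (s in seq_len(max_steps)) {
      r <- r + dr; c <- c + dc
      if (r < 1L || r > nr || c < 1L || c > nc) break
      if (!mask[r, c] || sk[r, c]) break
      sk[r, c] <- TRUE
    }
  }
  sk
}

# 8-connected component labelling by flood fill (skeletons are sparse)
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  offs <- cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
                dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- (p - 1L) %% nr + 1L
      c <- (p - 1L) %/% nr + 1L
      for (o in seq_len(8L)) {
        rr <- r + offs[o, 1L]; cc <- c + offs[o, 2L]
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        q <- rr + (cc - 1L) * nr
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          stack <- c(stack, q)
        }
      }
    }
  }
  lab
}

# order the pixels of a simple path / cycle component into a walk
order_component <- function(pts) {
  n <- nrow(pts)
  if (n == 1L) return(pts)
  key <- paste(pts[, 1L], pts[, 2L])
  idx <- stats::setNames(seq_len(n), key)
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      j <- idx[paste(pts[i, 1L] + dr, pts[i, 2L] + dc)]
      if (!is.na(j)) nb <- c(nb, j)
    }
    adj[[i]] <- nb
  }
  deg <- lengths(adj)
  start <- if (any(deg <= 1L)) which(deg <= 1L)[1L] else 1L
  visited <- logical(n)
  path <- integer(n)
  cur <- start
  for (step in seq_len(n)) {
    path[step] <- cur
    visited[cur] <- TRUE
    nxt <- adj[[cur]][!visited[adj[[cur]]]]
    if (!length(nxt)) break
    cur <- nxt[1L]
  }
  pts[path[seq_len(step)], , drop = FALSE]
}

#' Extract vessel centerlines between bifurcation points
#'
#' Thins the binary vessel map to a unit-width 8-connected skeleton, flags
#' skeleton pixels with 3 or more skeleton neighbours as bifurcation points,
#' removes them (repeatedly, until every remaining pixel has at most two
#' neighbours), and orders each remaining connected component from one
#' endpoint to the other. Components shorter than `min_length_px` pixels are
#' discarded as spurs.
#'
#' @param map A [vessel_map] (or logical matrix).
#' @param min_length_px Minimum segment length in pixels (points) to retain.
#' @return A list of [centerline] objects (empty list for an empty mask).
#' @export
extract_centerlines <- function(map, min_length_px = 10L) {
  mask <- if (inherits(map, "vessel_map")) map$mask else as.matrix(map) > 0
  if (!any(mask)) return(list())
  sk <- prune_redundant(skeletonize_mask(mask))
  sk <- extend_endpoints(sk, mask)
  repeat {
    bif <- sk & neighbour_count(sk) >= 3L
    if (!any(bif)) break
    sk[bif] <- FALSE
  }
  if (!any(sk)) return(list())
  lab <- label_components(sk)
  out <- list()
  for (l in seq_len(max(lab))) {
    w <- which(lab == l)
    pts <- cbind(row = (w - 1L) %% nrow(lab) + 1L,
                 col = (w - 1L) %/% nrow(lab) + 1L)
    if (nrow(pts) < max(2L, min_length_px)) next
    ord <- order_component(pts)
    if (nrow(ord) < max(2L, min_length_px)) next
    out[[length(out) + 1L]] <- centerline(ord)
  }
  out
}

#' Read a grayscale image file into an [en_face_image]
#'
#' @param path PNG file path; RGB(A) images are averaged to gray.
#' @inheritParams en_face_image
#' @export
read_enface_image <- function(path, scale_mm_per_px, field_mm = 6.0,
                              laterality = "unknown", quality = NA_real_) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- apply(a[, , 1:min(3L, dim(a)[3L]), drop = FALSE], c(1, 2), mean)
  en_face_image(a, scale_mm_per_px, field_mm, laterality, quality)
}

#' Write a binary vessel map as a PNG
#'
#' @param map A [vessel_map].
#' @param path Output PNG path.
#' @export
write_mask_png <- function(map, path) {
  png::writePNG(map$mask * 1, path)
  invisible(path)
}

#' Write centerlines to CSV
#'
#' Columns: `segment_id`, `point_index`, `row`, `col` (0-based pixel
#' coordinates, origin top-left).
#'
#' @param centerlines List of [centerline] objects.
#' @param path Output CSV path.
#' @export
write_centerlines_csv <- function(centerlines, path) {
  rows <- lapply(seq_along(centerlines), function(i) {
    p <- centerlines[[i]]$points
    data.frame(segment_id = i, point_index = seq_len(nrow(p)) - 1L,
               row = p[, 1L] - 1, col = p[, 2L] - 1)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
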