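# Geometry and intensity descriptors of segmented ROIs. Conventions follow
# the manual measurement tool radiologists use on such images: regions are
# measured on their pixel-corner outline (a single pixel is a 1x1 square, so
# its longest caliper is sqrt(2)), the perimeter is the corner-cut boundary
# polygon arc length, and the roundness major axis comes from second-order
# moments of the pixel centers (with the 1/12 pixel-extent term).

mask_corner_points <- function(mask) {
  px <- which(mask > 0, arr.ind = TRUE)
  r <- px[, 1]; c <- px[, 2]
  cbind(c(r - 0.5, r - 0.5, r + 0.5, r + 0.5),
        c(c - 0.5, c + 0.5, c - 0.5, c + 0.5))
}

#' Feret's (longest caliper) diameter of a binary region
#'
#' The maximum pairwise distance between pixel-corner points of the region,
#' scaled to millimetres. Computed over the convex hull, so it is exact and
#' fast for any mask size.
#'
#' @param mask binary slice (matrix).
#' @param pixel_size pixel edge length, mm.
#' @return Diameter in mm.
#' @export
feret_diameter <- function(mask, pixel_size = 1) {
  mask <- as_binary_mask(mask)
  if (!any(mask > 0)) stopf("no ROI: mask is empty")
  corners <- mask_corner_points(mask)
  hull <- corners[grDevices::chull(corners), , drop = FALSE]
  d2 <- outer(hull[, 1], hull[, 1], "-")^2 + outer(hull[, 2], hull[, 2], "-")^2
  sqrt(max(d2)) * pixel_size
}

# crack (pixel-edge) perimeter and the number of 90-degree boundary turns,
# counted from 2x2 neighbourhood configurations
crack_perimeter_turns <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(0, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  inner <- pad[2:(nr + 1L), 2:(nc + 1L)]
  edges <- sum(inner & !pad[1:nr, 2:(nc + 1L)]) +
           sum(inner & !pad[3:(nr + 2L), 2:(nc + 1L)]) +
           sum(inner & !pad[2:(nr + 1L), 1:nc]) +
           sum(inner & !pad[2:(nr + 1L), 3:(nc + 2L)])
  a <- pad[1:(nr + 1L), 1:(nc + 1L)]
  b <- pad[1:(nr + 1L), 2:(nc + 2L)]
  d <- pad[2:(nr + 2L), 1:(nc + 1L)]
  e <- pad[2:(nr + 2L), 2:(nc + 2L)]
  s <- a + b + d + e
  diagonalish <- (s == 2L) & (a == e)  # checkerboard 2x2: two opposite corners
  turns <- sum(s == 1L) + sum(s == 3L) + 2L * sum(diagonalish)
  list(edges = edges, turns = turns)
}

# trace all closed boundary contours of a binary mask along pixel edges
# (corner lattice points), foreground kept on the right of travel. Holes
# yield their own contours. Returns a list of k x 2 corner-point matrices.
trace_crack_contours <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  inner <- pad[2:(nr + 1L), 2:(nc + 1L)] > 0
  cid <- function(i, j) i * (nc + 1L) + j + 1L
  from <- integer(0); to <- integer(0); dir <- integer(0)
  add_edges <- function(sel, fi, fj, ti, tj, d) {
    if (!any(sel)) return(invisible(NULL))
    px <- which(sel, arr.ind = TRUE)
    r <- px[, 1]; c <- px[, 2]
    from <<- c(from, cid(r + fi, c + fj))
    to <<- c(to, cid(r + ti, c + tj))
    dir <<- c(dir, rep(d, nrow(px)))
    invisible(NULL)
  }
  # dirs: 1 = +col, 2 = +row, 3 = -col, 4 = -row (rows grow downward)
  add_edges(inner & !(pad[1:nr, 2:(nc + 1L)] > 0), -1L, -1L, -1L, 0L, 1L)  # top
  add_edges(inner & !(pad[2:(nr + 1L), 3:(nc + 2L)] > 0), -1L, 0L, 0L, 0L, 2L)  # right
  add_edges(inner & !(pad[3:(nr + 2L), 2:(nc + 1L)] > 0), 0L, 0L, 0L, -1L, 3L)  # bottom
  add_edges(inner & !(pad[2:(nr + 1L), 1:nc] > 0), 0L, -1L, -1L, -1L, 4L)  # left
  ne <- length(from)
  if (ne == 0L) return(list())
  out_by_corner <- split(seq_len(ne), from)
  used <- rep(FALSE, ne)
  contours <- list()
  corner_xy <- function(id) {
    id0 <- id - 1L
    c(id0 %/% (nc + 1L), id0 %% (nc + 1L))
  }
  for (e0 in seq_len(ne)) {
    if (used[e0]) next
    pts <- list()
    e <- e0
    repeat {
      used[e] <- TRUE
      pts[[length(pts) + 1L]] <- corner_xy(from[e])
      cands <- out_by_corner[[as.character(to[e])]]
      cands <- cands[!used[cands]]
      if (length(cands) == 0L) break  # contour closed
      if (length(cands) > 1L) {
        # right turn first, then straight, then left (never reverse)
        pri <- match(dir[cands], c(dir[e] %% 4L + 1L, dir[e], (dir[e] + 2L) %% 4L + 1L))
        cands <- cands[order(pri)]
      }
      e <- cands[1L]
    }
    contours[[length(contours) + 1L]] <- do.call(rbind, pts)
  }
  contours
}

# drop vertices interior to straight runs of a closed polygon
merge_collinear <- function(pts) {
  k <- nrow(pts)
  if (k < 4L) return(pts)
  prv <- rbind(pts[k, ], pts[-k, , drop = FALSE])
  nxt <- rbind(pts[-1L, , drop = FALSE], pts[1L, ])
  v1 <- pts - prv; v2 <- nxt - pts
  keep <- (v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1]) != 0 |
          (v1[, 1] * v2[, 1] + v1[, 2] * v2[, 2]) < 0
  if (!any(keep)) return(pts[c(1L, ceiling(k / 2)), , drop = FALSE])
  pts[keep, , drop = FALSE]
}

# one corner-cutting pass: every turning vertex is replaced by two points a
# chord apart, each at most `cap` (and at most half the adjacent edge) from
# the vertex, so a unit staircase collapses to its exact diagonal
cut_corners_once <- function(pts, cap = 0.5) {
  k <- nrow(pts)
  if (k < 3L) return(pts)
  prv <- rbind(pts[k, ], pts[-k, , drop = FALSE])
  nxt <- rbind(pts[-1L, , drop = FALSE], pts[1L, ])
  v1 <- pts - prv; v2 <- nxt - pts
  l1 <- sqrt(rowSums(v1^2)); l2 <- sqrt(rowSums(v2^2))
  turning <- (v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1]) != 0
  cut <- pmin(cap, l1 / 2, l2 / 2)
  out <- vector("list", k)
  for (i in seq_len(k)) {
    if (!turning[i]) {
      out[[i]] <- pts[i, , drop = FALSE]
    } else {
      out[[i]] <- rbind(pts[i, ] - v1[i, ] / l1[i] * cut[i],
                        pts[i, ] + v2[i, ] / l2[i] * cut[i])
    }
  }
  do.call(rbind, out)
}

polygon_length <- function(pts) {
  nxt <- rbind(pts[-1L, , drop = FALSE], pts[1L, ])
  sum(sqrt(rowSums((nxt - pts)^2)))
}

# perimeter of the traced boundary polygon after two corner-smoothing passes;
# the dominant source of circularity differences between implementations
boundary_perimeter <- function(mask, passes = 2L) {
  contours <- trace_crack_contours(mask)
  total <- 0
  for (pts in contours) {
    pts <- merge_collinear(pts)
    for (p in seq_len(passes)) pts <- cut_corners_once(pts)
    total <- total + polygon_length(pts)
  }
  total
}

#' Circularity and roundness of a binary region
#'
#' Circularity is `4 * pi * area / perimeter^2` with the perimeter measured
#' on the traced corner-cut boundary polygon; roundness is
#' `4 * area / (pi * major_axis^2)` with the major axis of the
#' moments-equivalent ellipse (`4 * sqrt(lambda_max)` of the pixel-center
#' covariance, including the 1/12 pixel-extent term). Both are 1 for an
#' ideal disc and decrease with boundary irregularity (circularity) or
#' elongation (roundness).
#'
#' @param mask binary slice (matrix).
#' @return List with `circularity` and `roundness`.
#' @export
shape_descriptors <- function(mask) {
  mask <- as_binary_mask(mask)
  if (!any(mask > 0)) stopf("no ROI: mask is empty")
  area <- sum(mask)
  perim <- boundary_perimeter(mask)
  circularity <- 4 * pi * area / perim^2
  px <- which(mask > 0, arr.ind = TRUE)
  mu <- colMeans(px)
  xc <- sweep(px, 2L, mu, "-")
  cov <- crossprod(xc) / area + diag(1 / 12, 2L)
  lambda_max <- max(eigen(cov, symmetric = TRUE, only.values = TRUE)$values)
  major <- 4 * sqrt(lambda_max)
  list(circularity = circularity, roundness = 4 * area / (pi * major^2))
}

#' ROI intensity summary over the valid voxels of a map slice
#'
#' Exact sums over the mask intersected with the finite (valid) voxels of
#' the map slice: `mean_intensity = intensity_sum / pixel_sum`, the mean ROI
#' value used by the probe-accumulation statistic.
#'
#' @param mask binary slice.
#' @param map_slice numeric matrix of the same shape (NA where invalid).
#' @return List: `pixel_sum`, `intensity_sum`, `mean_intensity`.
#' @export
roi_intensity <- function(mask, map_slice) {
  mask <- as_binary_mask(mask)
  check_shape_equal(mask, map_slice, "mask", "map_slice")
  sel <- mask > 0 & is.finite(map_slice)
  if (!any(sel)) stopf("no ROI: mask is empty or covers no valid voxels")
  vals <- map_slice[sel]
  list(pixel_sum = sum(sel), intensity_sum = sum(vals),
       mean_intensity = mean(vals))
}

#' All per-slice ROI metrics as one row
#'
#' Convenience wrapper combining [feret_diameter()], [shape_descriptors()]
#' and [roi_intensity()] for one slice.
#'
#' @param mask binary slice.
#' @param map_slice matching map slice (optional; intensity fields are NA
#'   when absent).
#' @param pixel_size pixel edge, mm.
#' @return A one-row data.frame: feret_mm, circularity, roundness,
#'   pixel_sum, intensity_sum, mean_intensity.
#' @export
roi_metrics <- function(mask, map_slice = NULL, pixel_size = 1) {
  f <- feret_diameter(mask, pixel_size)
  s <- shape_descriptors(mask)
  if (is.null(map_slice)) {
    int <- list(pixel_sum = sum(as_binary_mask(mask)),
                intensity_sum = NA_real_, mean_intensity = NA_real_)
  } else {
    int <- roi_intensity(mask, map_slice)
  }
  data.frame(feret_mm = f, circularity = s$circularity,
             roundness = s$roundness, pixel_sum = int$pixel_sum,
             intensity_sum = int$intensity_sum,
             mean_intensity = int$mean_intensity)
}

#' Longest lesion diameter across a mask stack
#'
#' The per-map "longest tumor diameter" used for response classification:
#' the maximum per-slice Feret diameter over all slices with a non-empty ROI.
#'
#' @param roi an `roi_mask` (see [predict_mask()]) or a 3-D binary array.
#' @param pixel_size pixel edge, mm (taken from the `roi_mask` if present).
#' @return Diameter in mm; 0 when every slice is empty (lesion dissolution).
#' @export
longest_diameter <- function(roi, pixel_size = NULL) {
  if (inherits(roi, "roi_mask")) {
    pixel_size <- pixel_size %||% roi$pixel_size
    roi <- roi$mask
  }
  pixel_size <- pixel_size %||% 1
  per_slice <- vapply(seq_len(dim(roi)[1]), function(s) {
    m <- roi[s, , ]
    if (!any(m > 0)) 0 else feret_diameter(m, pixel_size)
  }, numeric(1))
  max(per_slice)
}
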