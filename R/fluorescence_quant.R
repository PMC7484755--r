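#' Corrected total cell fluorescence
#'
#' Per-cell CTCF on a single-channel intensity image:
#' `CTCF = Integrated Density - (cell area x mean background fluorescence)`,
#' with the integrated density summed over the cell region and the background
#' mean taken over an explicit background mask (a reproducible stand-in for a
#' freehand background selection). Multi-cell masks are handled by labeling
#' connected components and emitting one row per cell; an already-labeled
#' integer mask keeps its labels.
#'
#' @param image numeric intensity matrix (one channel; split multi-channel
#'   images and convert to grayscale upstream).
#' @param cell_mask binary or integer-labeled matrix of cell regions.
#' @param background_mask binary matrix of the background region; must not
#'   overlap any cell and must be non-empty.
#' @return data.frame with one row per cell: `cell_id`, `area`,
#'   `integrated_density`, `background_mean`, `ctcf`.
#' @export
ctcf <- function(image, cell_mask, background_mask) {
  check_shape_equal(image, cell_mask, "image", "cell_mask")
  check_shape_equal(image, background_mask, "image", "background_mask")
  background_mask <- as_binary_mask(background_mask, "background_mask")
  if (!is.numeric(cell_mask) || anyNA(cell_mask) ||
      any(cell_mask < 0) || any(cell_mask != round(cell_mask)))
    stopf("`cell_mask` must be binary or a non-negative integer label matrix")
  if (any(cell_mask > 0 & background_mask > 0))
    stopf("cell and background masks overlap on %d pixel(s)",
          sum(cell_mask > 0 & background_mask > 0))
  if (!any(background_mask > 0)) stopf("background mask is empty")
  if (!any(cell_mask > 0)) stopf("no ROI: cell mask is empty")
  labels <- if (max(cell_mask) > 1) cell_mask else EBImage::bwlabel(cell_mask)
  bg_mean <- mean(image[background_mask > 0])
  ids <- sort(unique(labels[labels > 0]))
  rows <- lapply(ids, function(id) {
    sel <- labels == id
    area <- sum(sel)
    int_den <- sum(image[sel])
    data.frame(cell_id = id, area = area, integrated_density = int_den,
               background_mean = bg_mean, ctcf = int_den - area * bg_mean)
  })
  do.call(rbind, rows)
}

#' Compare CTCF values between two groups
#'
#' Student t comparison of per-cell (or per-image) CTCF values between, e.g.,
#' treated and untreated conditions. Delegates to [compare_groups()].
#'
#' @param ctcf_a,ctcf_b numeric vectors of CTCF values.
#' @param var_equal pool variances (classical t) or not (Welch).
#' @return The `htest` object.
#' @export
compare_ctcf <- function(ctcf_a, ctcf_b, var_equal = TRUE) {
  compare_groups(ctcf_a, ctcf_b, var_equal = var_equal)
}
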