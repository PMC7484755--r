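# File exchange in the formats the surrounding tools speak: NIfTI for
# volumes and maps, PNG (0/255) for per-slice masks, CSV for tables, JSON
# for results. Internal array order is (slice, row, col) 0-based-slice-major;
# NIfTI files are written (row, col, slice[, echo]) so standard viewers show
# in-plane slices.

#' Write / read a multi-echo series as NIfTI
#'
#' The 4-D volume is stored `(row, col, slice, echo)` with the in-plane
#' pixel size in the header; echo times (ms) travel in a JSON sidecar next
#' to the volume.
#'
#' @param series an `echo_series`.
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly (writer); an `echo_series` (reader).
#' @export
write_echo_series <- function(series, path) {
  stopifnot(inherits(series, "echo_series"))
  arr <- aperm(series$data, c(3L, 4L, 2L, 1L))  # (row, col, slice, echo)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(series$pixel_size, series$pixel_size, 1, 1)
  RNifti::writeNifti(img, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(echo_times_ms = series$echo_times,
                            pixel_size_mm = series$pixel_size),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_echo_series
#' @param path path written by [write_echo_series()].
#' @export
read_echo_series <- function(path) {
  img <- RNifti::readNifti(path)
  meta <- jsonlite::read_json(sub("\\.nii(\\.gz)?$", ".json", path),
                              simplifyVector = TRUE)
  arr <- aperm(array(as.numeric(img), dim(img)), c(4L, 3L, 1L, 2L))
  new_echo_series(arr, meta$echo_times_ms, meta$pixel_size_mm)
}

#' Write / read a T2 map as NIfTI
#'
#' Stored `(row, col, slice)`; invalid voxels are NA (written as NaN).
#'
#' @param t2map a `t2_map`.
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly (writer); a `t2_map` (reader).
#' @export
write_t2_map <- function(t2map, path) {
  stopifnot(inherits(t2map, "t2_map"))
  arr <- aperm(t2map$t2, c(2L, 3L, 1L))
  arr[is.na(arr)] <- NaN
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(t2map$pixel_size, 3)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @rdname write_t2_map
#' @export
read_t2_map <- function(path) {
  img <- RNifti::readNifti(path)
  t2 <- aperm(array(as.numeric(img), dim(img)), c(3L, 1L, 2L))
  t2[is.nan(t2)] <- NA_real_
  ps <- RNifti::pixdim(img)[1]
  structure(list(t2 = t2, a = NULL, valid = is.finite(t2),
                 pixel_size = ps, n_invalid = sum(!is.finite(t2))),
            class = "t2_map")
}

#' Write / read an ROI mask as per-slice PNG files
#'
#' One 0/255 grayscale PNG per slice, slice index zero-padded in the
#' filename (`mask_slice_01.png`, ...).
#'
#' @param roi an `roi_mask`.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return The written paths, invisibly (writer); an `roi_mask` (reader).
#' @export
write_mask_png <- function(roi, dir, prefix = "mask") {
  stopifnot(inherits(roi, "roi_mask"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- dim(roi$mask)[1]
  paths <- character(n)
  for (s in seq_len(n)) {
    paths[s] <- file.path(dir, sprintf("%s_slice_%02d.png", prefix, s))
    png::writePNG(roi$mask[s, , ], paths[s])
  }
  invisible(paths)
}

#' @rdname write_mask_png
#' @param pixel_size pixel size (mm) to attach on read.
#' @export
read_mask_png <- function(dir, prefix = "mask", pixel_size = 1) {
  paths <- sort(list.files(dir, pattern = paste0("^", prefix,
                                                 "_slice_\\d+\\.png$"),
                           full.names = TRUE))
  if (length(paths) == 0L) stopf("no '%s_slice_*.png' files in %s", prefix, dir)
  slices <- lapply(paths, function(p) {
    m <- png::readPNG(p)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    (m > 0.5) * 1
  })
  mask <- array(0, c(length(slices), dim(slices[[1]])))
  for (s in seq_along(slices)) mask[s, , ] <- slices[[s]]
  new_roi_mask(mask, pixel_size)
}

#' Read / write ratings tables as long-format CSV
#'
#' Columns `subject`, `rater`, `value`; the design must be complete.
#'
#' @param table a [ratings_table()].
#' @param path CSV path.
#' @return `path`, invisibly (writer); a `ratings_table` (reader).
#' @export
write_ratings_csv <- function(table, path) {
  stopifnot(inherits(table, "ratings_table"))
  long <- data.frame(
    subject = rep(rownames(table) %||% seq_len(nrow(table)), ncol(table)),
    rater = rep(colnames(table) %||% seq_len(ncol(table)),
                each = nrow(table)),
    value = as.vector(unclass(table)))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ratings_csv
#' @export
read_ratings_csv <- function(path) {
  ratings_table(utils::read.csv(path))
}
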