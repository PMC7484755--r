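# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stopf("`%s` must be TRUE or FALSE", name)
  x
}

assert_number <- function(x, name, lower = -Inf, upper = Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  ok <- if (strict) (x > lower && x < upper) else (x >= lower && x <= upper)
  if (!ok) stopf("`%s` = %g is outside [%g, %g]", name, x, lower, upper)
  as.numeric(x)
}

assert_count <- function(x, name, lower = 0L) {
  x <- assert_number(x, name, lower = lower)
  if (x != round(x)) stopf("`%s` must be an integer", name)
  as.integer(x)
}

# binary mask sanity: 0/1 (or logical), no NA
as_binary_mask <- function(mask, name = "mask") {
  if (is.logical(mask)) mask <- mask * 1L
  if (!is.numeric(mask) || anyNA(mask) || !all(mask %in% c(0, 1)))
    stopf("`%s` must be binary (0/1, no NA)", name)
  mask
}

# keep the largest 4-connected foreground component of a binary matrix;
# ties broken by the lowest label id so results are deterministic
largest_component <- function(mask) {
  mask <- as_binary_mask(mask)
  if (!any(mask > 0)) return(mask * 0)
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  (lab == keep) * 1
}

# Otsu threshold (between-class variance maximization) over finite values,
# delegated to EBImage with the data range made explicit
otsu_threshold <- function(x, levels = 256L) {
  v <- x[is.finite(x)]
  if (length(v) == 0L || diff(range(v)) == 0) return(NA_real_)
  EBImage::otsu(matrix(v, nrow = 1L), range = range(v), levels = levels)
}

# dimension tags used by array-based containers: (slice, row, col)
check_shape_equal <- function(a, b, name_a, name_b) {
  da <- dim(a) %||% length(a)
  db <- dim(b) %||% length(b)
  if (!identical(as.integer(da), as.integer(db)))
    stopf("shape mismatch: `%s` is [%s] but `%s` is [%s]",
          name_a, paste(da, collapse = "x"), name_b, paste(db, collapse = "x"))
  invisible(TRUE)
}
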