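#' Mean tumor T2 over a masked map
#'
#' The per-map average is pooled across slices with pixel-count weighting:
#' the total of all per-slice ROI intensity sums divided by the total ROI
#' pixel count, i.e. the plain mean over every masked valid voxel. This is
#' invariant to how the volume is sliced, unlike an unweighted mean of
#' per-slice means.
#'
#' @param t2map a `t2_map`.
#' @param mask an `roi_mask` or 3-D binary array matching the map shape.
#' @return List: `mean` (ms), `n_voxels`, `n_slices_used`, and a
#'   `per_slice` data.frame (slice, pixel_sum, intensity_sum, mean).
#' @export
average_t2 <- function(t2map, mask) {
  stopifnot(inherits(t2map, "t2_map"))
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  m <- as_binary_mask(m)
  check_shape_equal(t2map$t2, m, "t2map$t2", "mask")
  n_slices <- dim(m)[1]
  per <- lapply(seq_len(n_slices), function(s) {
    sel <- m[s, , ] > 0 & is.finite(t2map$t2[s, , ])
    if (!any(sel)) return(NULL)
    vals <- t2map$t2[s, , ][sel]
    data.frame(slice = s, pixel_sum = sum(sel), intensity_sum = sum(vals),
               mean = mean(vals))
  })
  per <- do.call(rbind, per)
  if (is.null(per)) stopf("no tumor found: ROI is empty on every slice")
  list(mean = sum(per$intensity_sum) / sum(per$pixel_sum),
       n_voxels = sum(per$pixel_sum), n_slices_used = nrow(per),
       per_slice = per)
}

#' deltaT2 probe-accumulation statistic
#'
#' `deltaT2 = mean ROI T2 (pre-injection) - mean ROI T2 (post-injection)`,
#' positive when probe accumulation shortened tumor T2. Pre and post sides
#' are masked independently; slices with an empty ROI are excluded from the
#' pooled means on their side.
#'
#' @param t2map_pre,t2map_post `t2_map` objects for the two timepoints.
#' @param mask_pre,mask_post matching ROI masks.
#' @return Object of class `delta_t2_result`: `mean_roi_pre`,
#'   `mean_roi_post`, `delta_t2` (ms), `n_slices_used_pre/post`,
#'   `per_slice_pre/post`.
#' @export
delta_t2 <- function(t2map_pre, mask_pre, t2map_post, mask_post) {
  pre <- tryCatch(average_t2(t2map_pre, mask_pre), error = function(e)
    stopf("pre-injection side: %s", conditionMessage(e)))
  post <- tryCatch(average_t2(t2map_post, mask_post), error = function(e)
    stopf("post-injection side: %s", conditionMessage(e)))
  structure(list(mean_roi_pre = pre$mean, mean_roi_post = post$mean,
                 delta_t2 = pre$mean - post$mean,
                 n_slices_used_pre = pre$n_slices_used,
                 n_slices_used_post = post$n_slices_used,
                 per_slice_pre = pre$per_slice, per_slice_post = post$per_slice),
            class = "delta_t2_result")
}

#' RECIST response category from longest-diameter change
#'
#' Applies the solid-tumor response rules to the longest lesion diameter:
#' complete response (CR) when the lesion has dissolved; progressive disease
#' (PD) on a >= 20 percent diameter increase or any new lesion; partial
#' response (PR) on a >= 30 percent decrease; stable disease (SD) otherwise.
#' Both thresholds are inclusive. Precedence: CR, then PD (new lesions),
#' then PD (diameter), then PR, then SD.
#'
#' @param baseline_mm longest diameter before therapy, mm (> 0).
#' @param followup_mm longest diameter at follow-up, mm.
#' @param followup_lesion_present FALSE when no lesion is detectable at
#'   follow-up (dissolution).
#' @param new_lesions count of new lesions at follow-up.
#' @return Object of class `recist_call`: `baseline_diameter`,
#'   `followup_diameter`, `percent_change`, `category`.
#' @export
recist_classify <- function(baseline_mm, followup_mm,
                            followup_lesion_present = TRUE, new_lesions = 0L) {
  assert_number(baseline_mm, "baseline_mm", lower = 0, strict = TRUE)
  assert_flag(followup_lesion_present, "followup_lesion_present")
  new_lesions <- assert_count(new_lesions, "new_lesions", lower = 0L)
  if (!followup_lesion_present) followup_mm <- 0
  assert_number(followup_mm, "followup_mm", lower = 0)
  pct <- 100 * (followup_mm - baseline_mm) / baseline_mm
  category <- if (!followup_lesion_present) "CR"
    else if (new_lesions >= 1L) "PD"
    else if (pct >= 20) "PD"
    else if (pct <= -30) "PR"
    else "SD"
  structure(list(baseline_diameter = baseline_mm,
                 followup_diameter = followup_mm,
                 percent_change = pct, category = category),
            class = "recist_call")
}

#' Two-sample t comparison of deltaT2 (or any) groups
#'
#' Thin convenience wrapper over the classical two-sample t test
#' (equal-variance by default, Welch optional), as used to compare
#' probe-accumulation statistics between treated and control cohorts.
#'
#' @param x,y numeric vectors (>= 2 values each).
#' @param var_equal pool the variances (classical Student test) or not (Welch).
#' @return The `htest` object from [stats::t.test()].
#' @export
compare_groups <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2L || length(y) < 2L)
    stopf("each group needs at least 2 values (got %d and %d)",
          length(x), length(y))
  stats::t.test(x, y, var.equal = var_equal)
}
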