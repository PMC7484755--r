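# Two-way mixed-model, absolute-agreement intraclass correlation, built from
# the two-way ANOVA mean squares (rows = subjects, columns = raters):
#   ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))
#   ICC(A,k) = (MSR - MSE) / (MSR + (MSC - MSE)/n)
# with F = MSR/MSE on (n-1, (n-1)(k-1)) df and the standard absolute-
# agreement confidence interval (Satterthwaite df for the single-measures
# bound; average-measures bounds by the single-to-average relation).

#' Construct a complete subjects-by-raters ratings table
#'
#' @param values an `n_subjects x k_raters` numeric matrix (complete, no NA),
#'   or a long data.frame with columns `subject`, `rater`, `value`.
#' @param subject_ids,rater_ids optional dimension names.
#' @return Object of class `ratings_table` (a matrix with attributes).
#' @export
ratings_table <- function(values, subject_ids = NULL, rater_ids = NULL) {
  if (is.data.frame(values)) {
    if (!all(c("subject", "rater", "value") %in% names(values)))
      stopf("long-format ratings need columns subject, rater, value")
    wide <- stats::xtabs(value ~ subject + rater, data = values)
    if (any(table(values$subject, values$rater) != 1L))
      stopf("ratings must be a complete design with one value per cell")
    values <- matrix(wide, nrow(wide), ncol(wide),
                     dimnames = dimnames(wide))
  }
  values <- as.matrix(values)
  if (anyNA(values)) stopf("ratings must be complete (no missing cells)")
  if (nrow(values) < 2L || ncol(values) < 2L)
    stopf("need at least 2 subjects and 2 raters, got %d x %d",
          nrow(values), ncol(values))
  if (!is.null(subject_ids)) rownames(values) <- subject_ids
  if (!is.null(rater_ids)) colnames(values) <- rater_ids
  structure(values, class = c("ratings_table", "matrix"))
}

#' Absolute-agreement intraclass correlation (two-way mixed model)
#'
#' Single-measures and average-measures ICC under the two-way model with
#' random subject effects and fixed rater effects, using the absolute
#' agreement definition, plus the F test of the null ICC = 0 and 95%
#' confidence intervals.
#'
#' @param table a [ratings_table()] (or plain matrix / long data.frame).
#' @param conf_level confidence level for the intervals.
#' @return Object of class `icc_result`: `icc_single`, `icc_average`,
#'   `ci_single`, `ci_average`, `f_value`, `df1`, `df2`, `p_value`,
#'   `mean_squares` (MS_rows, MS_columns, MS_error), `n`, `k`.
#' @export
icc_absolute_agreement <- function(table, conf_level = 0.95) {
  if (!inherits(table, "ratings_table")) table <- ratings_table(table)
  x <- unclass(table)
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (mse <= 0 && msr <= 0)
    stopf("degenerate table: no subject variance and no residual variance")
  icc1 <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  icck <- (msr - mse) / (msr + (msc - mse) / n)
  fv <- msr / mse
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  p <- stats::pf(fv, df1, df2, lower.tail = FALSE)
  # absolute-agreement CI for the single-measures coefficient
  alpha <- 1 - conf_level
  if (1 - icc1 < .Machine$double.eps) {
    # perfect agreement: the interval construction degenerates
    ci_single <- c(lower = 1, upper = 1)
    return(structure(list(icc_single = 1, icc_average = 1,
                          ci_single = ci_single, ci_average = ci_single,
                          f_value = fv, df1 = df1, df2 = df2, p_value = p,
                          mean_squares = c(MS_rows = msr, MS_columns = msc,
                                           MS_error = mse),
                          n = n, k = k, conf_level = conf_level),
                     class = "icc_result"))
  }
  a <- (k * icc1) / (n * (1 - icc1))
  b <- 1 + (k * icc1 * (n - 1)) / (n * (1 - icc1))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, df1 = n - 1, df2 = v)
  f_u <- stats::qf(1 - alpha / 2, df1 = v, df2 = n - 1)
  lo1 <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi1 <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  ci_single <- c(lower = max(lo1, -1), upper = min(hi1, 1))
  # transform the bounds with the single-to-average relation; below the
  # relation's pole (r <= -1/(k-1)) the average-measures bound is floored
  sb_bound <- function(r) {
    den <- 1 + (k - 1) * r
    if (den <= 0) -1 else max(-1, min(1, k * r / den))
  }
  ci_average <- vapply(ci_single, sb_bound, numeric(1))
  structure(list(icc_single = icc1, icc_average = icck,
                 ci_single = ci_single, ci_average = ci_average,
                 f_value = fv, df1 = df1, df2 = df2, p_value = p,
                 mean_squares = c(MS_rows = msr, MS_columns = msc,
                                  MS_error = mse),
                 n = n, k = k, conf_level = conf_level),
            class = "icc_result")
}

#' Single-to-average measures relation (Spearman-Brown)
#'
#' `k * r / (1 + (k - 1) * r)`: the exact algebraic relation between the
#' single-measures and average-measures intraclass correlations of the same
#' table of k raters.
#'
#' @param icc_single single-measures ICC in (-1, 1].
#' @param k number of raters averaged (>= 1).
#' @return The average-measures ICC.
#' @export
spearman_brown <- function(icc_single, k) {
  if (k < 1) stopf("`k` must be >= 1, got %g", k)
  if (icc_single <= -1 || icc_single > 1)
    stopf("`icc_single` must lie in (-1, 1], got %g", icc_single)
  k * icc_single / (1 + (k - 1) * icc_single)
}

#' Inter-rater agreement report over paired mask sets
#'
#' Computes, per image, the three ROI descriptors used for rater validation
#' (pixel sum/size, circularity, roundness) for each rater's mask, then the
#' absolute-agreement ICC per metric across images.
#'
#' @param masks_rater_a,masks_rater_b named lists of binary slice masks;
#'   names pair the images.
#' @return List: `table` (per image and rater metric rows) and `icc`
#'   (named list of `icc_result`, one per metric).
#' @export
agreement_report <- function(masks_rater_a, masks_rater_b) {
  ids_a <- names(masks_rater_a) %||% as.character(seq_along(masks_rater_a))
  ids_b <- names(masks_rater_b) %||% as.character(seq_along(masks_rater_b))
  unmatched <- c(setdiff(ids_a, ids_b), setdiff(ids_b, ids_a))
  if (length(unmatched) > 0L)
    stopf("unpaired image id(s): %s", paste(unmatched, collapse = ", "))
  rows <- list()
  for (id in ids_a) {
    for (rater in c("A", "B")) {
      m <- if (rater == "A") masks_rater_a[[id]] else masks_rater_b[[id]]
      s <- shape_descriptors(m)
      rows[[length(rows) + 1L]] <- data.frame(
        image = id, rater = rater, pixel_sum = sum(as_binary_mask(m)),
        circularity = s$circularity, roundness = s$roundness)
    }
  }
  tab <- do.call(rbind, rows)
  icc <- lapply(c(size = "pixel_sum", circularity = "circularity",
                  roundness = "roundness"), function(metric) {
    wide <- cbind(tab[tab$rater == "A", metric], tab[tab$rater == "B", metric])
    icc_absolute_agreement(ratings_table(wide, subject_ids = ids_a,
                                         rater_ids = c("A", "B")))
  })
  list(table = tab, icc = icc)
}
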