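# Independent oracles used across test files. These deliberately avoid the
# package's own code paths (plain loops, brute force, closed forms).

# longest caliper diameter by exhaustive pairwise distances over all pixel
# corner points (no convex hull)
brute_feret <- function(mask, pixel_size = 1) {
  px <- which(mask > 0, arr.ind = TRUE)
  pts <- rbind(cbind(px[, 1] - 0.5, px[, 2] - 0.5),
               cbind(px[, 1] - 0.5, px[, 2] + 0.5),
               cbind(px[, 1] + 0.5, px[, 2] - 0.5),
               cbind(px[, 1] + 0.5, px[, 2] + 0.5))
  best <- 0
  for (i in seq_len(nrow(pts)))
    best <- max(best, (pts[i, 1] - pts[, 1])^2 + (pts[i, 2] - pts[, 2])^2)
  sqrt(best) * pixel_size
}

# two-way ANOVA mean squares by explicit sums-of-squares loops
brute_anova_ms <- function(x) {
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  ss_rows <- 0; ss_cols <- 0; ss_tot <- 0
  for (i in seq_len(n)) ss_rows <- ss_rows + k * (mean(x[i, ]) - grand)^2
  for (j in seq_len(k)) ss_cols <- ss_cols + n * (mean(x[, j]) - grand)^2
  for (i in seq_len(n)) for (j in seq_len(k))
    ss_tot <- ss_tot + (x[i, j] - grand)^2
  c(MS_rows = as.numeric(ss_rows / (n - 1)),
    MS_columns = as.numeric(ss_cols / (k - 1)),
    MS_error = as.numeric((ss_tot - ss_rows - ss_cols) /
                            ((n - 1) * (k - 1))))
}

# consistency-definition ICC (two-way), used as a contrast oracle for the
# absolute-agreement coefficient
consistency_icc <- function(x) {
  ms <- brute_anova_ms(x)
  (ms["MS_rows"] - ms["MS_error"]) /
    (ms["MS_rows"] + (ncol(x) - 1) * ms["MS_error"])
}

# exhaustive (A, T2) grid search minimizing the exact SSE of the decay model
grid_search_fit <- function(y, t, a_range, t2_range, step = 0.1) {
  a_grid <- seq(a_range[1], a_range[2], by = step)
  t2_grid <- seq(t2_range[1], t2_range[2], by = step)
  E <- exp(-outer(1 / t2_grid, t))
  best <- c(a = NA, t2 = NA, sse = Inf)
  for (a in a_grid) {
    sse <- rowSums((matrix(y, length(t2_grid), length(t), byrow = TRUE) -
                      a * E)^2)
    j <- which.min(sse)
    if (sse[j] < best["sse"]) best <- c(a = a, t2 = t2_grid[j], sse = sse[j])
  }
  best
}

# small default phantom spec used in several files (fast: 15 x 32 x 32)
small_spec <- function(...) {
  phantom_spec(grid_shape = c(15L, 32L, 32L), tumor_center = c(8, 16, 16),
               tumor_radii = c(3, 6, 6), ...)
}
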