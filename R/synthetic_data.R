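#' Specify a tumor-bearing multi-echo phantom
#'
#' Defines the geometry, relaxometry and noise of a synthetic multi-echo
#' T2-weighted acquisition: a uniform background with one axis-aligned
#' ellipsoidal lesion of distinct T2. The defaults emulate a coronal
#' small-animal stack: 15 slices of 64x64 voxels, 8 echoes spanning
#' 8-120 ms (bracketing both tumor and background T2), background T2
#' 80 ms, tumor T2 60 ms before probe injection and 45 ms after
#' (iron-oxide probes shorten T2), and near-gaussian magnitude noise.
#'
#' @param grid_shape integer vector `(slices, rows, cols)`.
#' @param pixel_size in-plane voxel edge, mm.
#' @param echo_times strictly increasing positive echo times, ms (>= 3).
#' @param tumor_center ellipsoid center `(slice, row, col)`, 1-based voxel
#'   coordinates.
#' @param tumor_radii ellipsoid semi-axes `(r_slice, r_row, r_col)`, voxels.
#' @param t2_background,t2_tumor_pre,t2_tumor_post tissue T2 values, ms.
#' @param amplitude proton-density amplitude `A` of the decay
#'   `y = A exp(-t/T2)`, signal units.
#' @param noise_sigma noise standard deviation, signal units.
#' @param noise_model `"gaussian"` or `"rician"` (magnitude-MRI noise;
#'   near-gaussian at high SNR).
#' @param seed integer seed making every generated phantom a pure function
#'   of its spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(15L, 64L, 64L),
                         pixel_size = 0.25,
                         echo_times = seq(8, 120, by = 16),
                         tumor_center = c(8, 32, 32),
                         tumor_radii = c(4, 10, 10),
                         t2_background = 80,
                         t2_tumor_pre = 60,
                         t2_tumor_post = 45,
                         amplitude = 100,
                         noise_sigma = 2,
                         noise_model = c("gaussian", "rician"),
                         seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (length(grid_shape) != 3L) stopf("`grid_shape` must be (slices, rows, cols)")
  grid_shape <- vapply(seq_along(grid_shape), function(i)
    assert_count(grid_shape[i], "grid_shape", lower = 1L), integer(1))
  if (length(echo_times) < 3L) stopf("at least 3 echo times are required, got %d",
                                     length(echo_times))
  if (any(echo_times <= 0) || any(diff(echo_times) <= 0))
    stopf("`echo_times` must be positive and strictly increasing")
  for (nm in c("t2_background", "t2_tumor_pre", "t2_tumor_post"))
    assert_number(get(nm), nm, lower = 0, strict = TRUE)
  assert_number(amplitude, "amplitude", lower = 0, strict = TRUE)
  assert_number(noise_sigma, "noise_sigma", lower = 0)
  assert_number(pixel_size, "pixel_size", lower = 0, strict = TRUE)
  if (length(tumor_center) != 3L || length(tumor_radii) != 3L)
    stopf("`tumor_center` and `tumor_radii` must each have 3 elements")
  for (ax in 1:3) {
    lo <- tumor_center[ax] - tumor_radii[ax]
    hi <- tumor_center[ax] + tumor_radii[ax]
    if (lo < 1 || hi > grid_shape[ax])
      stopf("tumor exceeds the grid on axis %d: radius %g around center %g spans [%g, %g] but the grid has %d voxels",
            ax, tumor_radii[ax], tumor_center[ax], lo, hi, grid_shape[ax])
  }
  structure(list(grid_shape = grid_shape, pixel_size = pixel_size,
                 echo_times = as.numeric(echo_times),
                 tumor_center = as.numeric(tumor_center),
                 tumor_radii = as.numeric(tumor_radii),
                 t2_background = t2_background, t2_tumor_pre = t2_tumor_pre,
                 t2_tumor_post = t2_tumor_post, amplitude = amplitude,
                 noise_sigma = noise_sigma, noise_model = noise_model,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# ellipsoid membership on the voxel grid, 1-based centers
ellipsoid_mask <- function(grid_shape, center, radii) {
  s <- slice.index(array(0, grid_shape), 1)
  r <- slice.index(array(0, grid_shape), 2)
  cc <- slice.index(array(0, grid_shape), 3)
  d <- ((s - center[1]) / radii[1])^2 +
       ((r - center[2]) / radii[2])^2 +
       ((cc - center[3]) / radii[3])^2
  (d <= 1) * 1
}

# brute-force longest caliper diameter over pixel-corner points of a binary
# slice; kept internal to the generator so ground truth is independent of
# the roi_metrics implementation it is used to check
brute_feret_mm <- function(mask, pixel_size) {
  px <- which(mask > 0, arr.ind = TRUE)
  if (nrow(px) == 0L) return(0)
  r <- px[, 1]; c <- px[, 2]
  corners <- cbind(c(r - 0.5, r - 0.5, r + 0.5, r + 0.5),
                   c(c - 0.5, c + 0.5, c - 0.5, c + 0.5))
  hull <- corners[grDevices::chull(corners), , drop = FALSE]
  d2 <- outer(hull[, 1], hull[, 1], "-")^2 + outer(hull[, 2], hull[, 2], "-")^2
  sqrt(max(d2)) * pixel_size
}

forward_signal <- function(t2_field, amplitude, echo_times) {
  ne <- length(echo_times)
  out <- array(0, c(ne, dim(t2_field)))
  for (e in seq_len(ne))
    out[e, , , ] <- amplitude * exp(-echo_times[e] / t2_field)
  out
}

add_noise <- function(signal, sigma, model, seed) {
  if (sigma == 0) return(signal)
  withr::with_seed(seed, {
    if (model == "gaussian") {
      signal + stats::rnorm(length(signal), 0, sigma)
    } else {
      n1 <- stats::rnorm(length(signal), 0, sigma)
      n2 <- stats::rnorm(length(signal), 0, sigma)
      sqrt((signal + n1)^2 + n2^2)
    }
  })
}

new_echo_series <- function(data, echo_times, pixel_size) {
  structure(list(data = data, echo_times = echo_times, pixel_size = pixel_size),
            class = "echo_series")
}

#' Generate a multi-echo phantom with analytic ground truth
#'
#' Simulates the acquisition forward model: every voxel decays as
#' `y(t) = A exp(-t/T2)` with the voxel's true T2, then noise is added
#' per the spec's noise model. The returned ground truth carries the
#' exact T2 field, the tumor mask, and the lesion's longest per-slice
#' caliper (Feret) diameter.
#'
#' @param spec a [phantom_spec()].
#' @param timepoint `"pre"` or `"post"` probe injection; selects the tumor T2.
#' @return A list with `series` (class `echo_series`: `data` is a
#'   `(echo, slice, row, col)` array) and `truth` (class `ground_truth`:
#'   `t2_field`, `tumor_mask`, `true_tumor_t2`, `true_feret_mm`).
#' @export
generate_phantom <- function(spec, timepoint = c("pre", "post")) {
  stopifnot(inherits(spec, "phantom_spec"))
  timepoint <- match.arg(timepoint)
  t2_tumor <- if (timepoint == "pre") spec$t2_tumor_pre else spec$t2_tumor_post
  mask <- ellipsoid_mask(spec$grid_shape, spec$tumor_center, spec$tumor_radii)
  t2_field <- array(spec$t2_background, spec$grid_shape)
  t2_field[mask == 1] <- t2_tumor
  clean <- forward_signal(t2_field, spec$amplitude, spec$echo_times)
  noisy <- add_noise(clean, spec$noise_sigma, spec$noise_model, spec$seed)
  feret <- max(vapply(seq_len(spec$grid_shape[1]), function(s)
    brute_feret_mm(mask[s, , ], spec$pixel_size), numeric(1)))
  truth <- structure(list(t2_field = t2_field, tumor_mask = mask,
                          true_tumor_t2 = t2_tumor, true_feret_mm = feret),
                     class = "ground_truth")
  list(series = new_echo_series(noisy, spec$echo_times, spec$pixel_size),
       truth = truth)
}

#' Generate a pre/post-injection phantom pair
#'
#' The two series share geometry, background T2 and amplitude; only the
#' tumor T2 differs (probe accumulation shortens it). The post-injection
#' noise realization uses an independent stream derived from the spec seed.
#'
#' @param spec_pre a [phantom_spec()]; its `t2_tumor_pre` is the baseline.
#' @param t2_tumor_post tumor T2 after injection, ms; must not exceed the
#'   pre-injection value.
#' @return A list `pre`, `post` (each class `echo_series`) and `truth`
#'   with the shared `t2_field` fields of both timepoints, `tumor_mask`,
#'   and `true_delta_t2` = mean true tumor T2(pre) - mean true tumor T2(post).
#' @export
generate_longitudinal_pair <- function(spec_pre, t2_tumor_post = spec_pre$t2_tumor_post) {
  stopifnot(inherits(spec_pre, "phantom_spec"))
  assert_number(t2_tumor_post, "t2_tumor_post", lower = 0, strict = TRUE)
  if (t2_tumor_post > spec_pre$t2_tumor_pre)
    stopf("post-injection tumor T2 (%g ms) exceeds pre-injection (%g ms); the probe can only shorten T2",
          t2_tumor_post, spec_pre$t2_tumor_pre)
  spec_post <- spec_pre
  spec_post$t2_tumor_post <- t2_tumor_post
  spec_post$seed <- spec_pre$seed + 1L
  pre <- generate_phantom(spec_pre, "pre")
  post <- generate_phantom(spec_post, "post")
  mask <- pre$truth$tumor_mask
  delta <- mean(pre$truth$t2_field[mask == 1]) - mean(post$truth$t2_field[mask == 1])
  truth <- structure(list(t2_field_pre = pre$truth$t2_field,
                          t2_field_post = post$truth$t2_field,
                          tumor_mask = mask, true_delta_t2 = delta,
                          true_feret_mm = pre$truth$true_feret_mm),
                     class = "ground_truth")
  list(pre = pre$series, post = post$series, truth = truth)
}

#' Generate an annotated slice corpus for segmentation training
#'
#' Emulates a radiologist-curated ground-truth set: phantoms with varied
#' lesion geometry, tumor T2 and background T2 are simulated, their T2 maps
#' reconstructed, and from each map the slices with the largest lesion
#' cross-sections are paired with the exact tumor masks. A small fraction of
#' lesion-free slices is mixed in as negative examples so a trained model
#' learns to stay silent on background-only slices.
#'
#' @param n_slices number of (slice, mask) training pairs to return.
#' @param slices_per_map annotated slices taken per simulated map.
#' @param empty_fraction fraction of `slices_per_map` drawn from the
#'   lesion-free end of each stack.
#' @param grid_shape,noise_sigma forwarded to [phantom_spec()].
#' @param seed integer seed; the corpus is a pure function of its arguments.
#' @return List of `list(x = <T2 slice matrix, ms>, y = <binary mask>)`.
#' @export
generate_training_corpus <- function(n_slices, slices_per_map = 5L,
                                     empty_fraction = 1 / 6,
                                     grid_shape = c(15L, 64L, 64L),
                                     noise_sigma = 2, seed = 1L) {
  n_slices <- assert_count(n_slices, "n_slices", lower = 1L)
  n_maps <- ceiling(n_slices / slices_per_map)
  examples <- list()
  rad_hi <- pmin(c(5L, 12L, 12L), (grid_shape - 1L) %/% 2L - 1L)
  rad_lo <- pmin(c(3L, 6L, 6L), rad_hi)
  for (i in seq_len(n_maps)) {
    draws <- withr::with_seed(seed * 1000L + i, {
      rad <- vapply(1:3, function(ax)
        sample(rad_lo[ax]:rad_hi[ax], 1), integer(1))
      ctr <- vapply(1:3, function(ax)
        sample((rad[ax] + 1L):(grid_shape[ax] - rad[ax]), 1), integer(1))
      list(ctr = ctr, rad = rad,
           t2_tumor = stats::runif(1, 40, 60),
           t2_bg = stats::runif(1, 75, 85))
    })
    sp <- phantom_spec(grid_shape = grid_shape,
                       tumor_center = draws$ctr, tumor_radii = draws$rad,
                       t2_tumor_pre = draws$t2_tumor, t2_background = draws$t2_bg,
                       noise_sigma = noise_sigma, seed = seed * 1000L + i)
    ph <- generate_phantom(sp)
    map <- suppressWarnings(reconstruct_t2_map(ph$series))
    areas <- apply(ph$truth$tumor_mask, 1, sum)
    n_empty <- round(empty_fraction * slices_per_map)
    keep <- c(order(areas, decreasing = TRUE)[seq_len(slices_per_map - n_empty)],
              if (n_empty > 0) order(areas)[seq_len(n_empty)])
    for (s in keep)
      examples[[length(examples) + 1L]] <-
        list(x = map$t2[s, , ], y = ph$truth$tumor_mask[s, , ])
  }
  examples[seq_len(n_slices)]
}

#' Simulate a complete two-way rater measurement table
#'
#' Draws `measurement(i, j) = mu + subject_i + rater_j + error_ij` with
#' independent normal components, the additive model under which the
#' absolute-agreement intraclass correlation has the closed form
#' `var_subject / (var_subject + var_rater + var_error)`.
#'
#' @param n_subjects,k_raters table dimensions (>= 2 each).
#' @param var_subject,var_rater,var_error variance components (>= 0),
#'   squared measurement units.
#' @param mu grand mean of the measurements.
#' @param seed integer seed.
#' @return A [ratings_table()] (`n_subjects` x `k_raters` matrix).
#' @export
generate_rater_table <- function(n_subjects, k_raters,
                                 var_subject, var_rater, var_error,
                                 mu = 10, seed = 1L) {
  n <- assert_count(n_subjects, "n_subjects", lower = 2L)
  k <- assert_count(k_raters, "k_raters", lower = 2L)
  for (nm in c("var_subject", "var_rater", "var_error"))
    assert_number(get(nm), nm, lower = 0)
  withr::with_seed(seed, {
    subj <- stats::rnorm(n, 0, sqrt(var_subject))
    rat <- stats::rnorm(k, 0, sqrt(var_rater))
    err <- matrix(stats::rnorm(n * k, 0, sqrt(var_error)), n, k)
    ratings_table(mu + outer(subj, rat, "+") + err)
  })
}

#' Simulate a fluorescence micrograph panel with known per-cell truth
#'
#' Places disjoint disc-shaped "cells" of uniform excess intensity on a
#' uniform-mean noisy background, re-sampling overlapping placements up
#' to a retry cap. The truth records each cell's noiseless integrated
#' density and its corrected total cell fluorescence
#' (area x excess intensity over background).
#'
#' @param n_cells number of cells.
#' @param shape image `(rows, cols)`.
#' @param bg_level mean background intensity.
#' @param cell_intensity excess intensity of a cell over the background.
#' @param cell_radius disc radius, pixels.
#' @param noise_sigma gaussian noise SD.
#' @param seed integer seed.
#' @param max_tries placement retry cap before rejection.
#' @return A list: `image` (matrix), `cell_masks` (labeled matrix, one
#'   integer id per cell), `background_mask` (binary matrix), and `truth`
#'   (data.frame: cell, area, true_integrated_density, true_ctcf).
#' @export
generate_fluorescence_panel <- function(n_cells = 5, shape = c(128L, 128L),
                                        bg_level = 10, cell_intensity = 20,
                                        cell_radius = 6, noise_sigma = 0.5,
                                        seed = 1L, max_tries = 200L) {
  n_cells <- assert_count(n_cells, "n_cells", lower = 1L)
  assert_number(bg_level, "bg_level", lower = 0)
  assert_number(noise_sigma, "noise_sigma", lower = 0)
  nr <- shape[1]; nc <- shape[2]
  rr <- slice.index(matrix(0, nr, nc), 1)
  cc <- slice.index(matrix(0, nr, nc), 2)
  withr::with_seed(seed, {
    labels <- matrix(0L, nr, nc)
    occupied <- matrix(FALSE, nr, nc)
    for (cell in seq_len(n_cells)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        cy <- stats::runif(1, cell_radius + 2, nr - cell_radius - 1)
        cx <- stats::runif(1, cell_radius + 2, nc - cell_radius - 1)
        disc <- ((rr - cy)^2 + (cc - cx)^2) <= cell_radius^2
        # require a 2-px moat so cells stay disjoint after labeling
        moat <- ((rr - cy)^2 + (cc - cx)^2) <= (cell_radius + 2)^2
        if (!any(occupied & moat)) {
          labels[disc] <- cell
          occupied <- occupied | moat
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stopf("could not place cell %d without overlap after %d tries", cell, max_tries)
    }
    clean <- bg_level + cell_intensity * (labels > 0)
    img <- clean + stats::rnorm(nr * nc, 0, noise_sigma)
  })
  background_mask <- (labels == 0) * 1
  areas <- tabulate(labels[labels > 0], nbins = n_cells)
  truth <- data.frame(cell = seq_len(n_cells), area = areas,
                      true_integrated_density = areas * (bg_level + cell_intensity),
                      true_ctcf = areas * cell_intensity)
  list(image = img, cell_masks = labels, background_mask = background_mask,
       truth = truth)
}
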