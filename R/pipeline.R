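#' Configuration for the end-to-end study pipeline
#'
#' Defines a simulated two-arm cohort: every subject gets a pre/post-probe
#' phantom pair at baseline (deltaT2 readout) and a follow-up phantom after
#' the therapy course (diameter readout for response classification).
#' Treated tumors receive a smaller probe-induced T2 drop than controls
#' (antigen downregulation means less probe binding), and their follow-up
#' growth factors are drawn below the controls', whose lesions roughly
#' double over the course.
#'
#' @param n_treated,n_control subjects per arm.
#' @param grid_shape phantom stack `(slices, rows, cols)`.
#' @param tumor_center,tumor_radii lesion geometry (voxels).
#' @param t2_background,t2_tumor_pre tissue T2 values, ms.
#' @param t2_post_treated,t2_post_control post-injection tumor T2, ms
#'   (treated > control: less probe accumulation after therapy).
#' @param growth_treated,growth_control follow-up diameter growth-factor
#'   ranges, `c(min, max)`.
#' @param noise_sigma signal noise SD.
#' @param segmentation `"oracle"` or `"trained"`.
#' @param model a trained `seg_model`, required when
#'   `segmentation = "trained"`.
#' @param seed master seed; every subject derives its own stream.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_treated = 3L, n_control = 3L,
                            grid_shape = c(15L, 32L, 32L),
                            tumor_center = c(8, 16, 16),
                            tumor_radii = c(3, 6, 6),
                            t2_background = 80, t2_tumor_pre = 60,
                            t2_post_treated = 52, t2_post_control = 42,
                            growth_treated = c(0.6, 1.1),
                            growth_control = c(1.7, 2.1),
                            noise_sigma = 2,
                            segmentation = c("oracle", "trained"),
                            model = NULL, seed = 1L) {
  segmentation <- match.arg(segmentation)
  if (segmentation == "trained" && (!inherits(model, "seg_model") ||
                                    !isTRUE(model$trained)))
    stopf("segmentation = 'trained' requires a trained `model`")
  structure(list(n_treated = assert_count(n_treated, "n_treated", 1L),
                 n_control = assert_count(n_control, "n_control", 1L),
                 grid_shape = grid_shape, tumor_center = tumor_center,
                 tumor_radii = tumor_radii, t2_background = t2_background,
                 t2_tumor_pre = t2_tumor_pre,
                 t2_post_treated = t2_post_treated,
                 t2_post_control = t2_post_control,
                 growth_treated = growth_treated,
                 growth_control = growth_control,
                 noise_sigma = noise_sigma, segmentation = segmentation,
                 model = model, seed = as.integer(seed)),
            class = "pipeline_config")
}

pipeline_segment <- function(config, map) {
  if (config$segmentation == "oracle") oracle_segment(map, "lower")
  else predict_mask(config$model, map)
}

#' Run the full study-shaped analysis pipeline
#'
#' For every simulated subject: generate the pre/post-injection multi-echo
#' pair, reconstruct both T2 maps, segment the tumor, compute deltaT2; then
#' simulate the follow-up stack, measure the longest lesion diameter on the
#' segmented baseline and follow-up maps, and classify the response. Output
#' is deterministic for a fixed config (including its seed).
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, per-subject JSON records
#'   and a cohort CSV are written there.
#' @param quiet suppress per-stage log lines.
#' @return List of class `pipeline_result`: `subjects` (one row each:
#'   group, ROI means, delta_t2, diameters, percent_change, recist),
#'   `group_test` (t test of deltaT2 treated vs control, when both arms
#'   have >= 2 subjects).
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log_line <- function(...) if (!quiet) message(sprintf(...))
  groups <- c(rep("treated", config$n_treated),
              rep("control", config$n_control))
  rows <- list()
  for (i in seq_along(groups)) {
    group <- groups[i]
    subject <- sprintf("%s_%02d", group, i)
    subj_seed <- config$seed + 97L * i
    t2_post <- if (group == "treated") config$t2_post_treated
               else config$t2_post_control
    g_range <- if (group == "treated") config$growth_treated
               else config$growth_control
    growth <- withr::with_seed(subj_seed, stats::runif(1, g_range[1], g_range[2]))

    spec <- phantom_spec(grid_shape = config$grid_shape,
                         tumor_center = config$tumor_center,
                         tumor_radii = config$tumor_radii,
                         t2_background = config$t2_background,
                         t2_tumor_pre = config$t2_tumor_pre,
                         t2_tumor_post = t2_post,
                         noise_sigma = config$noise_sigma, seed = subj_seed)
    pair <- generate_longitudinal_pair(spec)
    map_pre <- suppressWarnings(reconstruct_t2_map(pair$pre))
    map_post <- suppressWarnings(reconstruct_t2_map(pair$post))
    log_line("[%s] t2 maps reconstructed (%d + %d invalid voxels)",
             subject, map_pre$n_invalid, map_post$n_invalid)
    mask_pre <- pipeline_segment(config, map_pre)
    mask_post <- pipeline_segment(config, map_post)
    log_line("[%s] segmented: %d / %d tumor voxels",
             subject, sum(mask_pre$mask), sum(mask_post$mask))
    dt2 <- delta_t2(map_pre, mask_pre, map_post, mask_post)

    baseline_mm <- longest_diameter(mask_pre)
    radii_fu <- pmin(c(config$tumor_radii[1],
                       config$tumor_radii[2:3] * growth),
                     (config$grid_shape - 1) / 2 - 1)
    spec_fu <- phantom_spec(grid_shape = config$grid_shape,
                            tumor_center = config$tumor_center,
                            tumor_radii = radii_fu,
                            t2_background = config$t2_background,
                            t2_tumor_pre = config$t2_tumor_pre,
                            t2_tumor_post = t2_post,
                            noise_sigma = config$noise_sigma,
                            seed = subj_seed + 31L)
    ph_fu <- generate_phantom(spec_fu, "pre")
    map_fu <- suppressWarnings(reconstruct_t2_map(ph_fu$series))
    mask_fu <- pipeline_segment(config, map_fu)
    lesion_present <- any(mask_fu$mask > 0)
    followup_mm <- if (lesion_present) longest_diameter(mask_fu) else 0
    call <- recist_classify(baseline_mm, followup_mm,
                            followup_lesion_present = lesion_present)
    log_line("[%s] deltaT2 = %.2f ms; %.1f mm -> %.1f mm (%s)",
             subject, dt2$delta_t2, baseline_mm, followup_mm, call$category)
    rows[[i]] <- data.frame(
      subject = subject, group = group,
      mean_roi_pre = dt2$mean_roi_pre, mean_roi_post = dt2$mean_roi_post,
      delta_t2 = dt2$delta_t2,
      baseline_mm = baseline_mm, followup_mm = followup_mm,
      percent_change = call$percent_change, recist = call$category)
  }
  subjects <- do.call(rbind, rows)
  group_test <- NULL
  if (config$n_treated >= 2L && config$n_control >= 2L)
    group_test <- compare_groups(
      subjects$delta_t2[subjects$group == "treated"],
      subjects$delta_t2[subjects$group == "control"])
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(nrow(subjects)))
      jsonlite::write_json(as.list(subjects[i, ]),
                           file.path(out_dir, paste0(subjects$subject[i],
                                                     ".json")),
                           auto_unbox = TRUE, digits = NA)
    utils::write.csv(subjects, file.path(out_dir, "cohort.csv"),
                     row.names = FALSE)
  }
  structure(list(subjects = subjects, group_test = group_test,
                 config = config), class = "pipeline_result")
}

#' Write a seeded fixture corpus to disk
#'
#' Materializes the small test corpus (a phantom series with its T2 map and
#' ground-truth masks, a two-rater table, a fluorescence panel) under `dir`,
#' together with a manifest of MD5 checksums for reproducibility checks.
#'
#' @param dir target directory.
#' @param seed integer seed.
#' @param force overwrite an existing non-empty directory.
#' @return The manifest (data.frame: file, md5), invisibly.
#' @export
make_fixtures <- function(dir, seed = 1L, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !force)
    stopf("directory %s exists and is not empty; use force = TRUE", dir)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- phantom_spec(grid_shape = c(15L, 32L, 32L), tumor_center = c(8, 16, 16),
                     tumor_radii = c(3, 6, 6), seed = seed)
  ph <- generate_phantom(sp)
  write_echo_series(ph$series, file.path(dir, "phantom_pre.nii.gz"))
  map <- suppressWarnings(reconstruct_t2_map(ph$series))
  write_t2_map(map, file.path(dir, "t2map_pre.nii.gz"))
  write_mask_png(new_roi_mask(ph$truth$tumor_mask, sp$pixel_size),
                 file.path(dir, "masks"), prefix = "truth")
  jsonlite::write_json(list(true_tumor_t2 = ph$truth$true_tumor_t2,
                            true_feret_mm = ph$truth$true_feret_mm,
                            seed = seed),
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  rt <- generate_rater_table(20, 2, var_subject = 1, var_rater = 0.05,
                             var_error = 0.1, seed = seed)
  write_ratings_csv(rt, file.path(dir, "ratings.csv"))
  panel <- generate_fluorescence_panel(seed = seed)
  png::writePNG(panel$image / max(panel$image),
                file.path(dir, "fluorescence_panel.png"))
  utils::write.csv(panel$truth, file.path(dir, "fluorescence_truth.csv"),
                   row.names = FALSE)
  files <- setdiff(list.files(dir, recursive = TRUE), "manifest.json")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(dir, files))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA)
  invisible(manifest)
}
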