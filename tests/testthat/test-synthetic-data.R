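test_that("noiseless forward signal equals the closed-form decay", {
  sp <- phantom_spec(grid_shape = c(3L, 8L, 8L), echo_times = c(10, 30, 60),
                     tumor_center = c(2, 4, 4), tumor_radii = c(1, 2, 2),
                     t2_background = 50, t2_tumor_pre = 50,
                     amplitude = 100, noise_sigma = 0)
  ph <- generate_phantom(sp)
  expected <- 100 * exp(-c(10, 30, 60) / 50)
  for (e in 1:3)
    expect_equal(as.vector(ph$series$data[e, , , ]),
                 rep(expected[e], 3 * 8 * 8), tolerance = 1e-12)
})

test_that("generation is a pure function of the spec", {
  sp <- small_spec(noise_sigma = 5, seed = 7L)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$series$data, b$series$data)
  expect_identical(a$truth$t2_field, b$truth$t2_field)
  sp2 <- small_spec(noise_sigma = 5, seed = 8L)
  expect_false(identical(generate_phantom(sp2)$series$data, a$series$data))
})

test_that("noisy in-tumor mean matches an independent forward recomputation", {
  sp <- small_spec(t2_tumor_pre = 40, t2_background = 80, amplitude = 100,
                   echo_times = c(10, 30, 60), noise_sigma = 2, seed = 11L)
  ph <- generate_phantom(sp)
  # independent voxelwise recomputation of the noiseless model
  tum <- ph$truth$tumor_mask == 1
  for (e in 1:3) {
    clean_e <- 100 * exp(-sp$echo_times[e] / ph$truth$t2_field)
    expect_true(all(abs((ph$series$data[e, , , ] -
                           clean_e)[tum]) < 6 * 2))  # noise only
  }
  n_tum <- sum(tum)
  mean_t60 <- mean(ph$series$data[3, , , ][tum])
  se <- 2 / sqrt(n_tum)
  expect_lt(abs(mean_t60 - 100 * exp(-1.5)), 3 * se)
})

test_that("phantom spec rejects invalid geometry and echo grids", {
  expect_error(phantom_spec(tumor_center = c(8, 32, 60), tumor_radii = c(4, 10, 10)),
               "axis 3.*radius 10")
  expect_error(phantom_spec(echo_times = c(10, 30)), "at least 3 echo")
  expect_error(phantom_spec(echo_times = c(10, 10, 30)), "strictly increasing")
  expect_error(phantom_spec(t2_tumor_pre = -5), "t2_tumor_pre")
})

test_that("rician noise keeps signals non-negative; gaussian sigma is calibrated", {
  sp_r <- small_spec(noise_sigma = 10, noise_model = "rician", seed = 3L)
  expect_true(all(generate_phantom(sp_r)$series$data >= 0))
  # >= 1e5 values: 8 echoes x 15 x 32 x 32 = 122880
  sp_g <- small_spec(noise_sigma = 4, seed = 5L)
  ph <- generate_phantom(sp_g)
  clean <- generate_phantom(small_spec(noise_sigma = 0))$series$data
  emp <- sd(ph$series$data - clean)
  expect_lt(abs(emp - 4) / 4, 0.02)
})

test_that("longitudinal pairs share geometry and record the exact true deltaT2", {
  sp <- small_spec(t2_tumor_pre = 60, noise_sigma = 0)
  pair <- generate_longitudinal_pair(sp, t2_tumor_post = 45)
  expect_equal(pair$truth$true_delta_t2, 15)
  bg <- pair$truth$tumor_mask == 0
  expect_identical(pair$truth$t2_field_pre[bg], pair$truth$t2_field_post[bg])

  same <- generate_longitudinal_pair(sp, t2_tumor_post = 60)
  expect_equal(same$truth$true_delta_t2, 0)

  expect_error(generate_longitudinal_pair(sp, t2_tumor_post = 70),
               "exceeds pre-injection")
})

test_that("simulated rater tables reproduce the closed-form expected ICC", {
  # var_s/(var_s + var_r + var_e) = 1/1.15 = 0.8696; a single n = 200 table
  # estimates this with SE near 0.025, so average the estimator over a few
  # independent tables to separate estimator bias from sampling noise
  ests <- vapply(1:5, function(s)
    icc_absolute_agreement(generate_rater_table(
      200, 2, var_subject = 1, var_rater = 0.05, var_error = 0.1,
      seed = 40L + s))$icc_single, numeric(1))
  expect_lt(abs(mean(ests) - 0.8696), 0.05)

  perfect <- generate_rater_table(30, 2, var_subject = 1, var_rater = 0,
                                  var_error = 0, seed = 1L)
  expect_equal(icc_absolute_agreement(perfect)$icc_single, 1)

  tiny <- generate_rater_table(2, 2, var_subject = 1, var_rater = 0.1,
                               var_error = 0.1, seed = 2L)
  expect_true(is.finite(icc_absolute_agreement(tiny)$icc_single))
})

test_that("fluorescence panels carry exact per-cell ground truth", {
  p <- generate_fluorescence_panel(n_cells = 3, bg_level = 0,
                                   cell_intensity = 20, noise_sigma = 0,
                                   seed = 4L)
  expect_equal(p$truth$true_integrated_density, p$truth$area * 20)
  res <- ctcf(p$image, p$cell_masks, p$background_mask)
  expect_equal(res$ctcf, p$truth$true_ctcf, tolerance = 1e-12)
  # reproducibility and disjointness
  p2 <- generate_fluorescence_panel(n_cells = 3, bg_level = 0,
                                    cell_intensity = 20, noise_sigma = 0,
                                    seed = 4L)
  expect_identical(p$image, p2$image)
  expect_true(all((p$cell_masks > 0) + (p$background_mask > 0) <= 1))
})

test_that("training corpus slices are tumor-bearing and seeded", {
  ex <- generate_training_corpus(8, empty_fraction = 0,
                                 grid_shape = c(15L, 32L, 32L), seed = 2L)
  expect_length(ex, 8)
  expect_true(all(vapply(ex, function(e) sum(e$y) > 0, logical(1))))
  ex2 <- generate_training_corpus(8, empty_fraction = 0,
                                  grid_shape = c(15L, 32L, 32L), seed = 2L)
  expect_identical(ex, ex2)
  # default corpus mixes in lesion-free negatives at ~1 per 5 slices
  ex3 <- generate_training_corpus(10, grid_shape = c(15L, 32L, 32L), seed = 2L)
  n_empty <- sum(vapply(ex3, function(e) sum(e$y) == 0, logical(1)))
  expect_equal(n_empty, 2L)
})
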