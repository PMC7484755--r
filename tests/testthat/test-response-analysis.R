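make_map <- function(t2_arr, pixel_size = 1) {
  structure(list(t2 = t2_arr, a = NULL, valid = is.finite(t2_arr),
                 pixel_size = pixel_size, n_invalid = sum(!is.finite(t2_arr))),
            class = "t2_map")
}

test_that("average T2 pools across slices with pixel-count weights", {
  t2 <- array(NA_real_, c(2, 2, 2))
  mask <- array(0, c(2, 2, 2))
  t2[1, 1, ] <- c(20, 20); t2[1, 2, 1] <- 20    # slice 1: {20, 20, 20}
  mask[1, 1, ] <- 1; mask[1, 2, 1] <- 1
  t2[2, 1, 1] <- 40                             # slice 2: {40}
  mask[2, 1, 1] <- 1
  r <- average_t2(make_map(t2), mask)
  expect_equal(r$mean, 100 / 4)  # (60 + 40) / (3 + 1)
  expect_equal(r$n_slices_used, 2)

  # uniform tumor, exact mean; agrees with a flat loop over masked voxels
  sp <- small_spec(noise_sigma = 0, t2_tumor_pre = 45)
  ph <- generate_phantom(sp)
  m <- reconstruct_t2_map(ph$series)
  r2 <- average_t2(m, ph$truth$tumor_mask)
  expect_equal(r2$mean, 45, tolerance = 1e-8)
  acc <- c()
  for (s in 1:15) {
    sel <- ph$truth$tumor_mask[s, , ] == 1
    acc <- c(acc, m$t2[s, , ][sel])
  }
  expect_equal(r2$mean, mean(acc))
  expect_equal(r2$n_voxels, length(acc))

  expect_error(average_t2(m, array(0, dim(m$t2))), "no tumor found")
})

test_that("deltaT2 identity, antisymmetry and ground-truth recovery", {
  sp <- small_spec(noise_sigma = 2, seed = 77L)
  pair <- generate_longitudinal_pair(sp, t2_tumor_post = 40)  # 20 ms drop
  m_pre <- suppressWarnings(reconstruct_t2_map(pair$pre))
  m_post <- suppressWarnings(reconstruct_t2_map(pair$post))
  truth_mask <- pair$truth$tumor_mask

  same <- delta_t2(m_pre, truth_mask, m_pre, truth_mask)
  expect_equal(same$delta_t2, 0)

  d <- delta_t2(m_pre, truth_mask, m_post, truth_mask)
  expect_equal(d$delta_t2, d$mean_roi_pre - d$mean_roi_post)
  expect_lt(abs(d$delta_t2 - 20) / 20, 0.05)

  swapped <- delta_t2(m_post, truth_mask, m_pre, truth_mask)
  expect_equal(swapped$delta_t2, -d$delta_t2)

  empty <- array(0, dim(m_pre$t2))
  expect_error(delta_t2(m_pre, empty, m_post, truth_mask), "pre-injection")
  expect_error(delta_t2(m_pre, truth_mask, m_post, empty), "post-injection")
})

test_that("RECIST thresholds are inclusive and the classifier is total", {
  expect_equal(recist_classify(10, 7.0)$category, "PR")    # exactly -30%
  expect_equal(recist_classify(10, 12.0)$category, "PD")   # exactly +20%
  expect_equal(recist_classify(10, 9.0)$category, "SD")
  expect_equal(recist_classify(10, 0, followup_lesion_present = FALSE)$category,
               "CR")
  expect_equal(recist_classify(10, 9.5, new_lesions = 2)$category, "PD")
  expect_error(recist_classify(0, 5), "baseline_mm")

  # 0.1%-step sweep: category switches exactly at the printed thresholds
  pct <- seq(-50, 50, by = 0.1)
  cats <- vapply(pct, function(p)
    recist_classify(100, 100 * (1 + p / 100))$category, character(1))
  expect_true(all(cats %in% c("PR", "SD", "PD")))
  expect_equal(max(pct[cats == "PR"]), -30)
  expect_equal(min(pct[cats == "SD"]), -29.9)
  expect_equal(max(pct[cats == "SD"]), 19.9)
  expect_equal(min(pct[cats == "PD"]), 20)
})

test_that("group comparison reproduces the hand-worked t statistic", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1)
  shifted <- compare_groups(c(1, 2, 3), c(11, 12, 13))
  expect_lt(shifted$p.value, 0.01)
  # hand computation, pooled variance, 3 + 3
  x <- c(4, 6, 8); y <- c(1, 2, 3)
  sp2 <- ((3 - 1) * var(x) + (3 - 1) * var(y)) / (3 + 3 - 2)
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_hand <- 2 * pt(-abs(t_hand), df = 4)
  r <- compare_groups(x, y)
  expect_equal(unname(r$statistic), t_hand)
  expect_equal(r$p.value, p_hand)
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})
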