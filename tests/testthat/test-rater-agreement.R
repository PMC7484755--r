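test_that("perfect agreement gives ICC 1; offsets depress absolute agreement", {
  withr::with_seed(2L, x <- rnorm(20, 10, 2))
  perfect <- icc_absolute_agreement(ratings_table(cbind(x, x)))
  expect_equal(perfect$icc_single, 1)
  expect_equal(perfect$icc_average, 1)

  offset <- icc_absolute_agreement(ratings_table(cbind(x, x + 5)))
  expect_lt(offset$icc_single,
            unname(consistency_icc(cbind(x, x + 5))) - 0.2)
})

test_that("ANOVA mean squares match a brute-force sums-of-squares loop", {
  withr::with_seed(9L, for (case in list(c(5, 2), c(10, 3), c(7, 3))) {
    x <- matrix(rnorm(case[1] * case[2], 50, 5), case[1], case[2])
    r <- icc_absolute_agreement(ratings_table(x))
    expect_equal(unname(r$mean_squares), unname(brute_anova_ms(x)),
                 tolerance = 1e-12)
    expect_equal(r$df1, case[1] - 1)
    expect_equal(r$df2, (case[1] - 1) * (case[2] - 1))
    expect_equal(r$f_value,
                 unname(brute_anova_ms(x)["MS_rows"] /
                          brute_anova_ms(x)["MS_error"]))
  })
})

test_that("simulated tables recover the closed-form population ICC", {
  rt <- generate_rater_table(200, 2, var_subject = 1, var_rater = 0.05,
                             var_error = 0.1, seed = 7L)
  r <- icc_absolute_agreement(rt)
  expect_lt(abs(r$icc_single - 1 / 1.15), 0.05)
  expect_true(r$ci_single["lower"] <= r$icc_single)
  expect_true(r$icc_single <= r$ci_single["upper"])
})

test_that("single-to-average relation reproduces the published table rows", {
  expect_equal(round(spearman_brown(0.890, 2), 3), 0.942)
  expect_equal(round(spearman_brown(0.856, 2), 3), 0.922)
  expect_equal(spearman_brown(1, 5), 1)
  expect_equal(spearman_brown(0, 3), 0)
  expect_error(spearman_brown(0.5, 0), "k")
  expect_error(spearman_brown(1.2, 2), "icc_single")
})

test_that("average-measures ICC is exactly Spearman-Brown of single-measures", {
  withr::with_seed(15L, for (i in 1:8) {
    n <- sample(5:30, 1); k <- sample(2:4, 1)
    x <- matrix(rnorm(n * k, 20, 3), n, k) + rnorm(n, 0, 2)
    r <- icc_absolute_agreement(ratings_table(x))
    expect_equal(r$icc_average, spearman_brown(r$icc_single, k),
                 tolerance = 1e-12)
    # invariance to common shifts and positive rescaling
    r_shift <- icc_absolute_agreement(ratings_table(x + 100))
    r_scale <- icc_absolute_agreement(ratings_table(x * 3.5))
    expect_equal(r_shift$icc_single, r$icc_single, tolerance = 1e-9)
    expect_equal(r_scale$icc_single, r$icc_single, tolerance = 1e-9)
    expect_true(r$ci_single["lower"] <= r$icc_single + 1e-12)
    expect_true(r$icc_single <= r$ci_single["upper"] + 1e-12)
  })
})

test_that("ratings tables validate shape, completeness, and long format", {
  expect_error(ratings_table(matrix(1:3, 3, 1)), "at least 2")
  expect_error(ratings_table(matrix(c(1, NA, 3, 4), 2, 2)), "complete")
  long <- data.frame(subject = rep(1:3, each = 2), rater = rep(c("a", "b"), 3),
                     value = c(1, 1.1, 2, 2.2, 3, 2.9))
  rt <- ratings_table(long)
  expect_equal(dim(rt), c(3L, 2L))
  expect_equal(unclass(rt)[2, ], c(a = 2, b = 2.2))
})

test_that("agreement reports rate mask sets metric by metric", {
  withr::with_seed(44L, {
    masks_a <- list()
    for (i in 1:8) {
      m <- matrix(0, 24, 24)
      r0 <- sample(5:12, 1); c0 <- sample(5:12, 1); w <- sample(4:8, 1)
      m[r0:(r0 + w), c0:(c0 + w)] <- 1
      masks_a[[sprintf("img%02d", i)]] <- m
    }
  })
  same <- agreement_report(masks_a, masks_a)
  for (metric in c("size", "circularity", "roundness"))
    expect_equal(same$icc[[metric]]$icc_single, 1)

  # rater B dilates every mask by one pixel: size agreement degrades
  dilate1 <- function(m) {
    p <- matrix(0, nrow(m) + 2, ncol(m) + 2)
    p[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
    out <- p[2:(nrow(m) + 1), 2:(ncol(m) + 1)] |
      p[1:nrow(m), 2:(ncol(m) + 1)] | p[3:(nrow(m) + 2), 2:(ncol(m) + 1)] |
      p[2:(nrow(m) + 1), 1:ncol(m)] | p[2:(nrow(m) + 1), 3:(ncol(m) + 2)]
    out * 1
  }
  dil <- agreement_report(masks_a, lapply(masks_a, dilate1))
  expect_lt(dil$icc$size$icc_single, 1)

  # agreement decreases monotonically with rater jitter
  jitter_masks <- function(masks, amp, seed) {
    withr::with_seed(seed, lapply(masks, function(m) {
      px <- which(m > 0, arr.ind = TRUE)
      grow <- px[sample(nrow(px), min(amp * 3, nrow(px))), , drop = FALSE]
      for (g in seq_len(nrow(grow))) {
        r <- grow[g, 1] + sample(-amp:amp, 1)
        c <- grow[g, 2] + sample(-amp:amp, 1)
        if (r >= 1 && r <= nrow(m) && c >= 1 && c <= ncol(m)) m[r, c] <- 1
      }
      m
    }))
  }
  iccs <- vapply(c(1, 3, 6), function(amp)
    agreement_report(masks_a,
                     jitter_masks(masks_a, amp, 100 + amp))$icc$size$icc_single,
    numeric(1))
  expect_true(all(diff(iccs) < 0))

  expect_error(agreement_report(masks_a, masks_a[-1]), "unpaired")
})
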