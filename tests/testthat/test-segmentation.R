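test_that("dice loss endpoints, symmetry and bounds", {
  m <- matrix(0, 10, 10); m[3:6, 3:6] <- 1
  expect_equal(dice_loss(m, m), 0)
  disj <- matrix(0, 10, 10); disj[8:9, 8:9] <- 1
  expect_gt(dice_loss(disj, m), 0.95)
  # half-coverage: 1 - 100/150 = 1/3 at s -> 0
  tgt <- matrix(0, 20, 20); tgt[1:10, 1:10] <- 1    # 100 px
  half <- matrix(0, 20, 20); half[1:5, 1:10] <- 1   # 50 px inside target
  expect_equal(dice_loss(half, tgt, smooth = 0), 1 / 3)
  # symmetry and bounds for random binary masks
  withr::with_seed(8L, for (i in 1:10) {
    a <- matrix(rbinom(64, 1, 0.4), 8, 8)
    b <- matrix(rbinom(64, 1, 0.4), 8, 8)
    expect_equal(dice_loss(a, b), dice_loss(b, a))
    expect_gte(dice_loss(a, b), 0)
    expect_lte(dice_loss(a, b), 1)
  })
  expect_error(dice_loss(matrix(0, 2, 2), matrix(0, 3, 3)), "shape mismatch")
})

test_that("printed MSE cost/gradient formulas evaluate exactly", {
  r <- mse_cost_and_gradient(data.frame(x = c(0, 1), y = c(0, 1)), m = 1, b = 0)
  expect_equal(r$cost, 0)
  expect_equal(unname(r$gradient), c(0, 0))
  r2 <- mse_cost_and_gradient(data.frame(x = 1, y = 1), m = 0, b = 0)
  expect_equal(r2$cost, 1)
  expect_equal(unname(r2$gradient), c(-2, -2))
  expect_error(mse_cost_and_gradient(data.frame(x = numeric(0),
                                                y = numeric(0)), 1, 0),
               "at least one")
})

test_that("analytic MSE gradient matches central finite differences", {
  withr::with_seed(13L, {
    pts <- data.frame(x = rnorm(25), y = rnorm(25))
    for (i in 1:5) {
      m <- rnorm(1); b <- rnorm(1); h <- 1e-5
      g <- mse_cost_and_gradient(pts, m, b)$gradient
      fd_m <- (mse_cost_and_gradient(pts, m + h, b)$cost -
                 mse_cost_and_gradient(pts, m - h, b)$cost) / (2 * h)
      fd_b <- (mse_cost_and_gradient(pts, m, b + h)$cost -
                 mse_cost_and_gradient(pts, m, b - h)$cost) / (2 * h)
      expect_lt(abs(g["df_dm"] - fd_m), 1e-6)
      expect_lt(abs(g["df_db"] - fd_b), 1e-6)
    }
  })
})

test_that("network backprop matches finite differences on a tiny model", {
  withr::with_seed(42L, {
    params <- t2quant:::nn_init_params(2L)
    x <- array(rnorm(8 * 8), c(8, 8, 1))
    tgt <- matrix(rbinom(64, 1, 0.3), 8, 8)
  })
  loss_fn <- function(p) {
    fw <- t2quant:::nn_forward(p, x)
    pr <- fw$prob[, , 1]
    1 - (2 * sum(pr * tgt) + 1) / (sum(pr) + sum(tgt) + 1)
  }
  fw <- t2quant:::nn_forward(params, x)
  pr <- fw$prob[, , 1]
  num <- 2 * sum(pr * tgt) + 1; den <- sum(pr) + sum(tgt) + 1
  dprob <- array(-(2 * tgt * den - num) / den^2, dim(fw$prob))
  g <- t2quant:::nn_backward(params, fw, dprob)
  h <- 1e-6
  withr::with_seed(7L, for (nm in names(params)) {
    W <- params[[nm]]$W
    for (j in sample(length(W), min(4, length(W)))) {
      pp <- params; pp[[nm]]$W[j] <- W[j] + h
      pm <- params; pm[[nm]]$W[j] <- W[j] - h
      fd <- (loss_fn(pp) - loss_fn(pm)) / (2 * h)
      expect_lt(abs(fd - g[[nm]]$dW[j]), 1e-4)
    }
  })
})

test_that("training reduces dice loss and is reproducible under a seed", {
  # tiny corpus so two full trainings stay cheap
  withr::with_seed(3L, {
    ex <- lapply(1:10, function(i) {
      x <- matrix(80, 16, 16) + rnorm(256, 0, 2)
      y <- matrix(0, 16, 16)
      r0 <- sample(3:9, 1); c0 <- sample(3:9, 1)
      y[r0:(r0 + 4), c0:(c0 + 4)] <- 1
      x[y == 1] <- x[y == 1] - 35
      list(x = x, y = y)
    })
  })
  cfg <- training_config(epochs = 15L, base_channels = 2L, seed = 5L)
  m1 <- train_model(ex, cfg)
  expect_lt(m1$loss_history[length(m1$loss_history)], m1$loss_history[1])
  m2 <- train_model(ex, cfg)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(m1$params, m2$params)
  # epoch-mean trend is monotone up to occasional stochastic upticks
  diffs <- diff(m1$loss_history)
  expect_lte(sum(diffs > 0), 2)
})

test_that("trained model segments held-out phantom slices accurately", {
  model <- get_seg_model()
  expect_gte(holdout_dice(model, get_holdout_corpus()), 0.85)
})

test_that("predict_mask output shape, empty slices, slice independence", {
  model <- get_seg_model()
  sp <- phantom_spec(tumor_center = c(5, 32, 32), tumor_radii = c(3, 9, 9),
                     noise_sigma = 2, seed = 17L)
  ph <- generate_phantom(sp)
  map <- suppressWarnings(reconstruct_t2_map(ph$series))
  pm <- predict_mask(model, map)
  expect_identical(dim(pm$mask), dim(map$t2))
  # slices far from the lesion are all background -> empty prediction
  expect_equal(sum(pm$mask[12:15, , ]), 0)
  # slices are processed independently: permuting slices permutes masks
  perm <- c(3, 1, 2, seq(4, 15))
  map_perm <- map
  map_perm$t2 <- map$t2[perm, , ]
  map_perm$valid <- map$valid[perm, , ]
  pm_perm <- predict_mask(model, map_perm)
  expect_equal(pm_perm$mask, pm$mask[perm, , ])
  expect_error(predict_mask(structure(list(trained = FALSE),
                                      class = "seg_model"), map),
               "trained")
})

test_that("reference segmenter is exact on noiseless and robust on noisy phantoms", {
  sp0 <- small_spec(noise_sigma = 0)
  ph0 <- generate_phantom(sp0)
  m0 <- reconstruct_t2_map(ph0$series)
  seg0 <- oracle_segment(m0, "lower")
  expect_equal(seg0$mask, ph0$truth$tumor_mask)

  sp3 <- small_spec(noise_sigma = 3, seed = 23L)
  ph3 <- generate_phantom(sp3)
  m3 <- suppressWarnings(reconstruct_t2_map(ph3$series))
  seg3 <- oracle_segment(m3, "lower")
  expect_gte(dice_coefficient(seg3$mask, ph3$truth$tumor_mask), 0.95)

  flat <- structure(list(t2 = array(70, c(2L, 16L, 16L)),
                         valid = array(TRUE, c(2L, 16L, 16L)),
                         pixel_size = 1, n_invalid = 0L), class = "t2_map")
  expect_equal(sum(oracle_segment(flat, "lower")$mask), 0)
})
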