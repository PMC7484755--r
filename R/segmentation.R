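#' Soft dice loss
#'
#' `1 - (2 * sum(pred * target) + s) / (sum(pred) + sum(target) + s)` with
#' smoothing constant `s`. Zero at perfect (binary) agreement, approaching 1
#' for disjoint regions; the smoothing term keeps empty-vs-empty slices at
#' loss 0 instead of 0/0.
#'
#' @param pred soft prediction in `[0, 1]`, any array shape.
#' @param target binary reference mask of the same shape.
#' @param smooth smoothing constant `s` (default 1).
#' @return Scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(pred, target, smooth = 1) {
  check_shape_equal(pred, target, "pred", "target")
  if (any(pred < 0 | pred > 1)) stopf("`pred` must lie in [0, 1]")
  target <- as_binary_mask(target, "target")
  num <- 2 * sum(pred * target) + smooth
  den <- sum(pred) + sum(target) + smooth
  1 - num / den
}

# Dice overlap coefficient between two binary masks (evaluation metric)
#' @rdname dice_loss
#' @param a,b binary masks of equal shape.
#' @export
dice_coefficient <- function(a, b) {
  check_shape_equal(a, b, "a", "b")
  a <- as_binary_mask(a, "a"); b <- as_binary_mask(b, "b")
  if (sum(a) + sum(b) == 0) return(1)
  2 * sum(a * b) / (sum(a) + sum(b))
}

#' Mean-squared-error cost and gradient for a line fit
#'
#' Evaluates `f(m, b) = (1/N) * sum((y_i - (m * x_i + b))^2)` and its exact
#' gradient `[(1/N) sum(-2 x_i (y_i - (m x_i + b))), (1/N) sum(-2 (y_i - (m x_i + b)))]`.
#' This is the illustrative gradient-descent machinery shipped alongside the
#' segmentation trainer (which itself optimizes [dice_loss()]); the analytic
#' gradient is verified against central finite differences in the tests.
#'
#' @param points data.frame or matrix with columns `x` and `y` (N >= 1 rows).
#' @param m,b slope and intercept at which to evaluate.
#' @return List with `cost` and `gradient = c(df_dm, df_db)`.
#' @export
mse_cost_and_gradient <- function(points, m, b) {
  points <- as.data.frame(points)
  if (nrow(points) == 0L) stopf("`points` must contain at least one (x, y) pair")
  if (!all(c("x", "y") %in% names(points)))
    stopf("`points` needs columns `x` and `y`")
  r <- points$y - (m * points$x + b)
  list(cost = mean(r^2),
       gradient = c(df_dm = mean(-2 * points$x * r), df_db = mean(-2 * r)))
}

#' Training configuration for the segmentation network
#'
#' Defaults follow the hyperparameters used for the original tumor
#' segmentation model: learning rate 4e-3, batch size 8, weight decay 1e-7.
#'
#' @param lr learning rate (> 0).
#' @param batch_size examples per SGD step (>= 1).
#' @param wd weight decay (>= 0).
#' @param momentum classical SGD momentum coefficient in `[0, 1)`.
#' @param epochs passes over the training set.
#' @param seed integer seed controlling initialization and batch order.
#' @param model_depth encoder levels (fixed at 3 in this release).
#' @param base_channels channels of the first encoder level.
#' @return Object of class `training_config`.
#' @export
training_config <- function(lr = 4e-3, batch_size = 8L, wd = 1e-7,
                            epochs = 100L, seed = 0L, momentum = 0.95,
                            model_depth = 3L, base_channels = 4L) {
  assert_number(lr, "lr", lower = 0, strict = TRUE)
  batch_size <- assert_count(batch_size, "batch_size", lower = 1L)
  assert_number(wd, "wd", lower = 0)
  assert_number(momentum, "momentum", lower = 0, upper = 1)
  epochs <- assert_count(epochs, "epochs", lower = 1L)
  if (model_depth != 3L) stopf("only model_depth = 3 is supported")
  structure(list(lr = lr, batch_size = batch_size, wd = wd, epochs = epochs,
                 seed = as.integer(seed), momentum = momentum, model_depth = 3L,
                 base_channels = assert_count(base_channels, "base_channels", 1L)),
            class = "training_config")
}

# slice intensities -> network input: invalid voxels imputed with the corpus
# mean, then standardized by the corpus mean/SD stored in the model
nn_prepare_slice <- function(slice, norm_center, norm_scale) {
  slice[!is.finite(slice)] <- norm_center
  array((slice - norm_center) / norm_scale, c(dim(slice), 1L))
}

#' Train the slice-wise segmentation network
#'
#' Fits a compact 3-level encoder-decoder with skip connections to
#' (T2-map slice, binary mask) pairs by stochastic gradient descent on the
#' soft dice loss, using the configured learning rate, batch size and weight
#' decay. Slices are processed independently; the per-epoch mean training
#' loss is recorded.
#'
#' @param examples list of `list(x = <H x W numeric matrix>, y = <binary mask>)`;
#'   H and W must be multiples of 4.
#' @param config a [training_config()].
#' @return Object of class `seg_model` with elements `params`, `config`,
#'   `norm_scale`, `loss_history` (one mean dice loss per epoch), `trained`.
#' @export
train_model <- function(examples, config = training_config()) {
  stopifnot(inherits(config, "training_config"))
  if (length(examples) < config$batch_size)
    stopf("need at least `batch_size` = %d examples, got %d",
          config$batch_size, length(examples))
  for (i in seq_along(examples)) {
    ex <- examples[[i]]
    check_shape_equal(ex$x, ex$y, "x", "y")
    examples[[i]]$y <- as_binary_mask(ex$y, "y")
    d <- dim(ex$x)
    if (any(d %% 4L != 0L))
      stopf("slice dims must be multiples of 4 for the 3-level model, got %dx%d",
            d[1], d[2])
  }
  vals <- unlist(lapply(examples, function(e) e$x[is.finite(e$x)]))
  norm_center <- mean(vals)
  norm_scale <- max(stats::sd(vals), 1e-12)

  n <- length(examples)
  step <- 0L
  fg_prior <- mean(vapply(examples, function(e) mean(e$y), numeric(1)))
  withr::with_seed(config$seed, {
    params <- nn_init_params(config$base_channels)
    # start the output near the foreground prior instead of p = 0.5
    params$out$b <- stats::qlogis(min(max(fg_prior, 1e-3), 0.5))
    vel <- nn_grad_zero(params)
    loss_history <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_losses <- c()
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        # dice is per image, averaged over the batch: each slice's own
        # denominator keeps its gradient scale independent of batch size
        grads <- nn_grad_zero(params)
        batch_loss <- 0
        for (i in idx) {
          x <- nn_prepare_slice(examples[[i]]$x, norm_center, norm_scale)
          tgt <- examples[[i]]$y
          fw <- nn_forward(params, x)
          p <- fw$prob[, , 1]
          s <- 1
          num <- 2 * sum(p * tgt) + s
          den <- sum(p) + sum(tgt) + s
          loss <- 1 - num / den
          step <- step + 1L
          if (!is.finite(loss))
            stopf("non-finite training loss at step %d", step)
          batch_loss <- batch_loss + loss
          dprob <- array(-(2 * tgt * den - num) / den^2, dim(fw$prob))
          grads <- nn_grad_add(grads, nn_backward(params, fw, dprob))
        }
        upd <- nn_sgd_update(params, grads, vel, config$lr, config$wd,
                             config$momentum, scale = 1 / length(idx))
        params <- upd$params
        vel <- upd$vel
        ep_losses <- c(ep_losses, batch_loss / length(idx))
      }
      loss_history[ep] <- mean(ep_losses)
    }
  })
  structure(list(params = params, config = config,
                 norm_center = norm_center, norm_scale = norm_scale,
                 loss_history = loss_history, trained = TRUE),
            class = "seg_model")
}

#' Predict a tumor mask from a T2 map
#'
#' Runs each slice independently through the trained network, thresholds the
#' soft output at 0.5, and keeps the largest connected component per slice
#' (the single-lesion model).
#'
#' @param model a trained [train_model()] result.
#' @param t2map a `t2_map` (see [reconstruct_t2_map()]).
#' @param threshold probability cutoff for the soft mask.
#' @return Object of class `roi_mask`: binary `mask` over `(slice, row, col)`
#'   plus `pixel_size`.
#' @export
predict_mask <- function(model, t2map, threshold = 0.5) {
  if (!inherits(model, "seg_model") || !isTRUE(model$trained))
    stopf("`model` must be a trained seg_model")
  stopifnot(inherits(t2map, "t2_map"))
  d <- dim(t2map$t2)
  mask <- array(0, d)
  for (s in seq_len(d[1])) {
    x <- nn_prepare_slice(t2map$t2[s, , ], model$norm_center, model$norm_scale)
    p <- nn_forward(model$params, x)$prob[, , 1]
    mask[s, , ] <- largest_component((p > threshold) * 1)
  }
  new_roi_mask(mask, t2map$pixel_size)
}

new_roi_mask <- function(mask, pixel_size) {
  structure(list(mask = mask, pixel_size = pixel_size), class = "roi_mask")
}

# Otsu threshold with a bimodality acceptance gate: the split is kept only
# when the standardized between-class separation (mu_hi - mu_lo over the
# pooled within-class SD) clears `min_separation`. Splitting unimodal
# gaussian noise yields a separation near 2.65 regardless of scale, while a
# genuine two-tissue slice at the contrasts this pipeline sees sits above
# 4.5, so the default gate of 3.3 rejects noise-only slices.
gated_otsu <- function(values, min_separation) {
  v <- values[is.finite(values)]
  if (length(v) < 2L || diff(range(v)) == 0) return(NA_real_)
  thr <- otsu_threshold(v)
  if (!is.finite(thr)) return(NA_real_)
  lo <- v[v < thr]; hi <- v[v >= thr]
  if (length(lo) == 0L || length(hi) == 0L) return(NA_real_)
  sw2 <- (sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)) /
    max(length(v) - 2L, 1L)
  sep <- if (sw2 == 0) Inf else (mean(hi) - mean(lo)) / sqrt(sw2)
  if (sep <= min_separation) NA_real_ else thr
}

#' Deterministic reference segmenter
#'
#' Splits map intensities into two classes by between-class-variance
#' maximization (Otsu) and keeps, per slice, the largest connected component
#' on the expected-contrast side. A bimodality gate rejects thresholds whose
#' standardized class separation is no better than a split of unimodal
#' noise, so tumor-free slices yield empty masks instead of spurious noise
#' components. The threshold is per-slice by default; `scope = "volume"`
#' computes one gated threshold for the whole stack.
#'
#' @param t2map a `t2_map`.
#' @param expected_contrast `"lower"` if the lesion has lower values than
#'   background (e.g. a T2-shortened tumor), `"higher"` otherwise.
#' @param scope `"slice"` or `"volume"` threshold scope.
#' @param min_separation bimodality gate: minimum standardized between-class
#'   separation for a split to be accepted.
#' @return An `roi_mask`; empty where a slice (or the stack) is degenerate
#'   or unimodal.
#' @export
oracle_segment <- function(t2map, expected_contrast = c("lower", "higher"),
                           scope = c("slice", "volume"),
                           min_separation = 3.3) {
  stopifnot(inherits(t2map, "t2_map"))
  expected_contrast <- match.arg(expected_contrast)
  scope <- match.arg(scope)
  v <- t2map$t2
  d <- dim(v)
  mask <- array(0, d)
  thr_global <- if (scope == "volume") gated_otsu(v, min_separation)
                else NA_real_
  for (s in seq_len(d[1])) {
    sl <- v[s, , ]
    thr <- if (scope == "volume") thr_global
           else gated_otsu(sl, min_separation)
    if (!is.finite(thr)) next
    side <- if (expected_contrast == "lower") sl < thr else sl > thr
    side[!is.finite(sl)] <- FALSE
    mask[s, , ] <- largest_component(side * 1)
  }
  new_roi_mask(mask, t2map$pixel_size)
}
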