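# The trained segmentation model and its corpora are expensive (minutes),
# so they are built lazily once per test session and shared across files.
.model_cache <- new.env(parent = emptyenv())

get_train_corpus <- function() {
  if (is.null(.model_cache$train))
    .model_cache$train <- generate_training_corpus(48, seed = 1L)
  .model_cache$train
}

get_holdout_corpus <- function() {
  if (is.null(.model_cache$holdout))
    .model_cache$holdout <- generate_training_corpus(16, seed = 99L)
  .model_cache$holdout
}

get_seg_model <- function() {
  if (is.null(.model_cache$model))
    .model_cache$model <- train_model(get_train_corpus(), training_config())
  .model_cache$model
}

# mean Dice of a model over (slice, mask) examples
holdout_dice <- function(model, examples) {
  d <- vapply(examples, function(e) {
    map <- structure(list(t2 = array(e$x, c(1L, dim(e$x))),
                          a = NULL, valid = array(TRUE, c(1L, dim(e$x))),
                          pixel_size = 1, n_invalid = 0L),
                     class = "t2_map")
    pm <- predict_mask(model, map)
    dice_coefficient(pm$mask[1, , ], e$y)
  }, numeric(1))
  mean(d)
}
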