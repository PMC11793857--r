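# Training smoke tests run on deliberately tiny phantoms (32^3, two encoder
# halvings of margin) so the whole file stays within a couple of minutes.

make_dseg <- function(n, seed = 31L) {
  ph <- generate_dataset(n, class_mix = c(1, 0, 0), params = tiny_params(),
                         seed = seed)
  list(phantoms = ph,
       dseg = lapply(ph, function(p)
         list(ct = hu_normalize(p$ct)$data, labels = p$labels$data)))
}

make_dcls <- function(phantoms) {
  lapply(phantoms, function(p) {
    cr <- extract_gh_crop(hu_normalize(p$ct), p$labels, crop_edge = 24,
                          truth = p$truth)
    list(crop = cr$vol, truth = cr$truth)
  })
}

uniform_weights <- list(os = class_weights(c(1, 1, 1)),
                        js = class_weights(c(1, 1, 1)),
                        hsa = class_weights(c(1, 1)))

test_that("the train/test split reserves the rounded fraction", {
  sp <- train_test_split(571, 0.15, seed = 1L)
  expect_length(sp$test, 86)        # round(571 * 0.15)
  expect_length(sp$train, 485)
  expect_identical(sort(c(sp$train, sp$test)), 1:571)
  expect_identical(train_test_split(571, 0.15, seed = 1L)$test, sp$test)
})

test_that("segmentation training descends and is seed-reproducible", {
  d <- make_dseg(4)
  cfg <- train_config(max_epochs = 3L, batch_size = 2L, seed = 8L)
  fit1 <- train_segmentation(d$dseg, cfg)
  expect_lt(tail(fit1$record$train_loss, 1), fit1$record$train_loss[1])
  expect_true(all(is.finite(fit1$record$val_loss)))
  expect_identical(fit1$record$alpha, alpha_schedule(0:2))
  fit2 <- train_segmentation(d$dseg, cfg)
  expect_identical(fit1$record$train_loss, fit2$record$train_loss)
  expect_identical(fit1$record$val_loss, fit2$record$val_loss)
  expect_identical(param_group_hash(fit1$model), param_group_hash(fit2$model))
  # stopping bookkeeping: best + patience or the epoch cap
  rec <- fit1$record
  expect_true(rec$stopping_epoch == rec$best_epoch + cfg$patience ||
                rec$stopping_epoch == cfg$max_epochs)
})

test_that("transfer learning leaves the segmentation weights bit-identical", {
  d <- make_dseg(4, seed = 32L)
  seg <- train_segmentation(d$dseg, train_config(max_epochs = 2L, seed = 9L))
  dcls <- make_dcls(d$phantoms)
  before <- param_group_hash(seg$model)
  tl <- train_classification(seg$model, dcls,
                             train_config(max_epochs = 2L, batch_size = 4L,
                                          seed = 10L, freeze_setup = "TL"),
                             weights = uniform_weights)
  after <- param_group_hash(tl$model)
  expect_identical(after[["encoder"]], before[["encoder"]])
  expect_identical(after[["bottleneck"]], before[["bottleneck"]])
  expect_identical(after[["decoders"]], before[["decoders"]])
  expect_false(after[["classification"]] == before[["classification"]])
  # and the TL segmentation outputs equal the stage-1 outputs on any input
  x <- d$dseg[[1]]$ct
  a <- xcelunet:::nn_forward(seg$model, x, seg = TRUE, cls = FALSE)
  b <- xcelunet:::nn_forward(tl$model, x, seg = TRUE, cls = FALSE)
  expect_identical(a$md_probs, b$md_probs)
  expect_identical(a$cd_probs, b$cd_probs)
})

test_that("fine-tuning regimes modify exactly the re-trained groups", {
  d <- make_dseg(4, seed = 33L)
  seg <- train_segmentation(d$dseg, train_config(max_epochs = 1L, seed = 11L))
  dcls <- make_dcls(d$phantoms)
  before <- param_group_hash(seg$model)
  run <- function(setup) param_group_hash(
    train_classification(seg$model, dcls,
                         train_config(max_epochs = 1L, batch_size = 4L,
                                      seed = 12L, freeze_setup = setup),
                         weights = uniform_weights)$model)
  ftb <- run("FT-B")
  expect_identical(ftb[["encoder"]], before[["encoder"]])
  expect_identical(ftb[["decoders"]], before[["decoders"]])
  expect_false(ftb[["bottleneck"]] == before[["bottleneck"]])
  fte <- run("FT-E")
  expect_false(fte[["encoder"]] == before[["encoder"]])
  expect_false(fte[["bottleneck"]] == before[["bottleneck"]])
  expect_identical(fte[["decoders"]], before[["decoders"]])
})

test_that("a zero-epoch stage-2 run only applies the freeze", {
  d <- make_dseg(2, seed = 34L)
  seg <- train_segmentation(d$dseg, train_config(max_epochs = 1L, seed = 13L))
  dcls <- make_dcls(d$phantoms)
  z <- train_classification(seg$model, dcls,
                            train_config(max_epochs = 0L, seed = 14L,
                                         freeze_setup = "FT-N"),
                            weights = uniform_weights)
  expect_identical(param_group_hash(z$model), param_group_hash(seg$model))
  expect_identical(z$model$trainable, freeze_setup("FT-N"))
  expect_error(train_classification(seg$model,
                                    list(list(crop = dcls[[1]]$crop)),
                                    weights = uniform_weights),
               "truth")
})

test_that("class weights derived from training labels follow the counts", {
  d <- make_dseg(3, seed = 35L)
  seg <- train_segmentation(d$dseg, train_config(max_epochs = 1L, seed = 15L))
  dcls <- make_dcls(d$phantoms)
  # force a known label distribution covering every class
  os_g <- c(0, 1, 2); js_g <- c(2, 0, 1); hsa_g <- c(0, 1, 1)
  for (i in seq_along(dcls))
    dcls[[i]]$truth <- condition_labels(os_g[i], js_g[i], hsa_g[i])
  fit <- train_classification(seg$model, dcls,
                              train_config(max_epochs = 1L, seed = 16L,
                                           freeze_setup = "TL"))
  expect_equal(fit$weights$os$K, rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(fit$weights$hsa$K, class_weights(c(1, 2))$K, tolerance = 1e-12)
  expect_equal(sum(fit$weights$js$K), 1)
  # a task with an unobserved class cannot be balanced
  dcls[[3]]$truth <- condition_labels(0, js_g[3], hsa_g[3])
  expect_error(train_classification(seg$model, dcls,
                                    train_config(max_epochs = 1L, seed = 16L,
                                                 freeze_setup = "TL")),
               "zero counts")
})

test_that("inference runs patch-stitch-classify with explicit failure paths", {
  d <- make_dseg(3, seed = 36L)
  seg <- train_segmentation(d$dseg, train_config(max_epochs = 2L, seed = 17L))
  ph <- d$phantoms[[1]]
  ct <- hu_normalize(ph$ct)
  pr1 <- predict_volume(seg$model, ct, crop_edge = 24L)
  expect_s3_class(pr1$labels, "xcel_labels")
  expect_identical(dim(pr1$labels$data), dim(ct$data))
  expect_true(pr1$status %in% c("ok", "no GH joint found"))
  if (pr1$status == "ok") expect_s3_class(pr1$conditions,
                                          "xcel_condition_labels")
  # determinism of the full pipeline
  pr2 <- predict_volume(seg$model, ct, crop_edge = 24L)
  expect_identical(pr1$labels$data, pr2$labels$data)
  expect_identical(pr1$conditions, pr2$conditions)
  # an all-background segmentation skips classification with a status
  blind <- seg$model
  blind$params$decoders$md$head$b <- c(100, 0, 0)
  pr3 <- predict_volume(blind, ct, crop_edge = 24L)
  expect_identical(pr3$status, "no GH joint found")
  expect_null(pr3$conditions)
  # un-normalized input is rejected
  expect_error(predict_volume(seg$model, ph$ct), "normalize")
})

test_that("classification loss weights keep counts scale-free in training", {
  expect_equal(class_weights(c(311, 361, 328))$K,
               class_weights(c(0.311, 0.361, 0.328))$K, tolerance = 1e-12)
})
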