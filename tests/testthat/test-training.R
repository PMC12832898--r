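## a micro slice dataset: n random 4x4 2-channel slices whose label is a
## thresholded linear function of the input, learnable by a tiny net
micro_dataset <- function(n = 8L, seed = 3L) {
  set.seed(seed)
  recs <- lapply(seq_len(n), function(i) {
    img <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
    lab <- (img[, , 1L] > 0) * 1L
    list(subject = "s1", view = 1L, index = i, image = img, label = lab)
  })
  list(train = recs, validation = list(), tract = "t", n_labels = 1L)
}

test_that("binary cross-entropy matches its closed forms", {
  y <- array(c(0, 1, 1, 0), c(2, 2))
  expect_lt(bce_loss(y, y), 1e-6)   # perfect prediction after clipping
  expect_equal(bce_loss(array(0.5, c(2, 2)), y), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(0.25, 1), -log(0.25), tolerance = 1e-12)
  expect_equal(bce_loss(0.25, 1), 1.386294, tolerance = 1e-6)
  expect_error(bce_loss(matrix(0.5, 2, 2), matrix(1, 3, 3)), "shape")
})

test_that("cosine annealing interpolates from lr0 to eta_min", {
  expect_equal(cosine_lr(0, 400), 0.002)
  expect_equal(cosine_lr(400, 400), 0)
  expect_equal(cosine_lr(200, 400), 0.001)
  lrs <- vapply(0:50, cosine_lr, numeric(1L), t_max = 50)
  expect_true(all(diff(lrs) <= 0))
  expect_error(cosine_lr(401, 400), "t_max")
  expect_error(train_config(patience = 500, max_epochs = 400), "patience")
})

test_that("early stopping halts after `patience` non-improving epochs", {
  ds <- micro_dataset()
  cfg <- train_config(batch_size = 8L, max_epochs = 50L, patience = 3L,
                      seed = 1L)
  stub <- function(model) 0.5   # validation Dice never improves after epoch 1
  st <- train(unet_spec(2L, 1L, depth = 1L, base_filters = 2L), ds, cfg,
              eval_fn = stub)
  expect_identical(st$epochs_run, 4L)  # 1 improving + 3 stale
  expect_identical(st$best_epoch, 1L)
  ## best-so-far validation Dice is monotone non-decreasing
  expect_true(all(diff(cummax(st$log$val_dice)) >= 0))
})

test_that("training is bit-reproducible under the seed", {
  ds <- micro_dataset()
  cfg <- train_config(batch_size = 4L, max_epochs = 2L, patience = 2L,
                      seed = 7L)
  stub <- function(model) 0.1
  s1 <- train(unet_spec(2L, 1L, depth = 1L, base_filters = 2L), ds, cfg,
              eval_fn = stub)
  s2 <- train(unet_spec(2L, 1L, depth = 1L, base_filters = 2L), ds, cfg,
              eval_fn = stub)
  expect_identical(s1$log$train_loss, s2$log$train_loss)
  expect_identical(s1$model$params, s2$model$params)
})

test_that("loss decreases over the first epochs of an overfit run", {
  ds <- micro_dataset(n = 8L)
  cfg <- train_config(batch_size = 8L, max_epochs = 12L, patience = 12L,
                      seed = 2L)
  st <- train(unet_spec(2L, 1L, depth = 2L, base_filters = 4L), ds, cfg,
              eval_fn = function(model) 0)
  expect_lt(st$log$train_loss[12L], st$log$train_loss[1L])
})

test_that("single-class labels keep voxels shared between tracts positive", {
  ph <- get_crossing_phantom(side = 16L)
  subj <- list(p = list(fodf = ph$fodf, masks = ph$masks))
  ov <- ph$overlap == 2L
  expect_gt(sum(ov), 0L)
  for (tr in names(ph$masks)) {
    ds <- build_slice_dataset(subj, tract = tr)
    ## the 3D validation label is the full tract mask, overlap included
    expect_true(all(ds$validation[[1L]]$label[ov] == 1L))
    ## and the 2D training slices carry the same positives
    v3 <- Filter(function(r) r$view == 3L, ds$train)
    v3 <- v3[order(vapply(v3, `[[`, 1L, "index"))]
    lab <- tractfodf:::stack_slices(lapply(v3, `[[`, "label"), 3L, 16L)
    expect_true(all(lab[ov] == 1L))
  }
})

test_that("multi-label datasets stack one channel per tract", {
  ph <- get_crossing_phantom(side = 16L)
  subj <- list(p = list(fodf = ph$fodf, masks = ph$masks))
  ds <- build_slice_dataset(subj, tract = NULL)
  expect_identical(ds$n_labels, 2L)
  expect_identical(dim(ds$train[[1L]]$label), c(16L, 16L, 2L))
  expect_identical(dim(ds$validation[[1L]]$label), c(16L, 16L, 16L, 2L))
})

test_that("degenerate training inputs are rejected", {
  ds <- micro_dataset()
  expect_error(train(unet_spec(2L, 1L, depth = 1L),
                     list(train = list(), validation = list()),
                     train_config()), "empty")
  expect_error(train(unet_spec(2L, 1L, depth = 1L),
                     list(train = ds$train, validation = list()),
                     train_config()), "validation")
})
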