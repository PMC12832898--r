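test_that("forward pass preserves spatial shape and stays in (0,1)", {
  spec <- unet_spec(in_channels = 5L, out_channels = 1L, depth = 2L,
                    base_filters = 4L)
  m <- unet_init(spec, seed = 2)
  set.seed(1)
  x <- array(rnorm(8 * 8 * 5), c(8, 8, 5))
  p <- unet_forward(m, x)
  expect_identical(dim(p), c(8L, 8L))
  expect_true(all(p > 0 & p < 1))
  ## batch and multi-channel output
  spec2 <- unet_spec(5L, 3L, depth = 2L, base_filters = 4L)
  m2 <- unet_init(spec2, seed = 2)
  xb <- array(rnorm(8 * 8 * 5 * 4), c(8, 8, 5, 4))
  pb <- unet_forward(m2, xb)
  expect_identical(dim(pb), c(8L, 8L, 3L, 4L))
  ## evaluation mode is deterministic
  expect_identical(unet_forward(m, x), unet_forward(m, x))
})

test_that("inputs not divisible by the downsampling factor are rejected", {
  m <- unet_init(unet_spec(depth = 5L, base_filters = 2L), seed = 1)
  expect_error(unet_forward(m, array(0, c(145, 145, 45))), "divisible")
  expect_error(unet_forward(m, array(0, c(144, 144, 9))), "channels")
})

test_that("parameter count matches layer-by-layer arithmetic", {
  ## hand count for the smallest net (depth 1, one filter, 1->1):
  ## conv1 9+1, conv2 9+1, head 1+1 = 22
  expect_identical(parameter_count(unet_spec(1L, 1L, depth = 1L,
                                             base_filters = 1L)), 22L)
  cases <- list(c(45, 1, 3, 8), c(9, 1, 3, 8), c(5, 3, 2, 4), c(45, 2, 4, 16))
  for (cs in cases) {
    sp <- unet_spec(cs[1], cs[2], depth = cs[3], base_filters = cs[4])
    expect_identical(parameter_count(sp),
                     as.integer(closed_form_param_count(cs[1], cs[2],
                                                        cs[3], cs[4])))
    ## the initialized model carries exactly that many values
    m <- unet_init(sp, seed = 1)
    expect_identical(sum(vapply(m$params,
                                function(p) length(p$W) + length(p$b), 1L)),
                     parameter_count(sp))
  }
  ## switching 9 -> 45 input channels only changes the first convolution
  d45 <- parameter_count(unet_spec(45L))
  d9 <- parameter_count(unet_spec(9L))
  expect_identical(d45 - d9, 9L * 64L * 36L)
  expect_identical(d45 - d9, 20736L)
  ## doubling the width roughly quadruples the parameters
  w1 <- parameter_count(unet_spec(45L, 1L, depth = 3L, base_filters = 8L))
  w2 <- parameter_count(unet_spec(45L, 1L, depth = 3L, base_filters = 16L))
  expect_gt(w2 / w1, 3)
  expect_lt(w2 / w1, 4.5)
})

test_that("backpropagation matches numerical gradients", {
  spec <- unet_spec(in_channels = 3L, out_channels = 2L, depth = 3L,
                    base_filters = 2L, dropout = 0)
  m <- unet_init(spec, seed = 4)
  set.seed(1)
  H <- W <- 8L; B <- 2L
  xm <- tractfodf:::slice_batch_matrix(array(rnorm(H * W * 3 * B),
                                             c(H, W, 3, B)))
  ym <- matrix(rbinom(H * W * B * 2, 1, 0.4), H * W * B, 2)
  fw <- tractfodf:::unet_fwd(m, xm, H, W, B)
  p <- stats::plogis(fw$logits)
  gr <- tractfodf:::unet_bwd(m, fw$cache, (p - ym) / length(ym))
  lossfn <- function(mm)
    bce_loss(stats::plogis(tractfodf:::unet_fwd(mm, xm, H, W, B)$logits), ym)
  eps <- 1e-5
  for (nm in c("enc1_conv1", "enc3_conv2", "up2", "dec1_conv2", "head")) {
    arr <- m$params[[nm]]$W
    for (i in sample(length(arr), 3L)) {
      m2 <- m; m2$params[[nm]]$W[i] <- arr[i] + eps
      m3 <- m; m3$params[[nm]]$W[i] <- arr[i] - eps
      num <- (lossfn(m2) - lossfn(m3)) / (2 * eps)
      ana <- gr[[nm]]$W[i]
      if (abs(ana) > 1e-6)
        expect_lt(abs(num - ana) / (abs(num) + abs(ana)), 1e-4)
    }
  }
})

test_that("dropout perturbs training-mode outputs but not evaluation mode", {
  spec <- unet_spec(3L, 1L, depth = 2L, base_filters = 4L, dropout = 0.4)
  m <- unet_init(spec, seed = 1)
  set.seed(2)
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  set.seed(10); a <- unet_forward(m, x, training = TRUE)
  set.seed(11); b <- unet_forward(m, x, training = TRUE)
  expect_false(identical(a, b))
  set.seed(10); a2 <- unet_forward(m, x, training = TRUE)
  expect_identical(a, a2)   # same RNG state, same dropout mask
  expect_identical(unet_forward(m, x), unet_forward(m, x))
})
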