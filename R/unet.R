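## 2D U-Net for per-slice tract segmentation, implemented on base matrix
## algebra: convolutions via im2col + GEMM, 2x2 max-pool downsampling,
## 2x2-stride-2 transposed-convolution upsampling, skip connections at
## equal resolution, LeakyReLU activations, dropout after encoder blocks,
## and a sigmoid 1x1 head.  Activations are carried as (H*W*B, C)
## matrices — pixels column-major (h fastest), batch folded into rows — so
## every layer is one or a few GEMMs plus index shuffles, with no
## higher-dimensional array permutations in the hot path.

#' 2D U-Net architecture specification
#'
#' Declarative, size-checkable description of the segmentation network:
#' 3x3 stride-1 convolutions (two per resolution block) with LeakyReLU,
#' 2x2 max-pool downsampling, a decoder mirroring the encoder with 2x2
#' transposed convolutions and skip connections, dropout after each
#' encoder block, and an element-wise sigmoid head.  Input height/width
#' must be divisible by `2^(depth - 1)`; output spatial shape equals input
#' spatial shape.
#'
#' @param in_channels Input channels: 45 for the full SH fODF
#'   representation, 9 for the 3-peak ablation input.
#' @param out_channels 1 for single-class (one model per tract), C for the
#'   multi-label variant.
#' @param depth Number of resolution levels (default 5).
#' @param base_filters Filters at the first level, doubling per level
#'   (default 64; the defaults land near 37M trainable parameters).
#' @param negative_slope LeakyReLU negative slope (default 0.01).
#' @param dropout Dropout rate applied after each encoder block during
#'   training (default 0.4).
#' @return An object of class `unet_spec`.
#' @export
unet_spec <- function(in_channels = 45L, out_channels = 1L, depth = 5L,
                      base_filters = 64L, negative_slope = 0.01,
                      dropout = 0.4) {
  if (depth < 1L) stop("'depth' must be >= 1", call. = FALSE)
  if (dropout < 0 || dropout >= 1) stop("'dropout' must be in [0, 1)", call. = FALSE)
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 negative_slope = negative_slope,
                 dropout = dropout),
            class = "unet_spec")
}

## Layer plan: list of (name, type, cin, cout) in forward order.  type is
## "conv3" (3x3), "up" (2x2 transposed), or "conv1" (1x1 head).
unet_plan <- function(spec) {
  f <- spec$base_filters * 2L^(seq_len(spec$depth) - 1L)
  plan <- list()
  add <- function(name, type, cin, cout)
    plan[[length(plan) + 1L]] <<- list(name = name, type = type,
                                       cin = cin, cout = cout)
  cin <- spec$in_channels
  for (i in seq_len(spec$depth)) {
    add(sprintf("enc%d_conv1", i), "conv3", cin, f[i])
    add(sprintf("enc%d_conv2", i), "conv3", f[i], f[i])
    cin <- f[i]
  }
  for (i in rev(seq_len(spec$depth - 1L))) {
    add(sprintf("up%d", i), "up", f[i + 1L], f[i])
    add(sprintf("dec%d_conv1", i), "conv3", 2L * f[i], f[i])
    add(sprintf("dec%d_conv2", i), "conv3", f[i], f[i])
  }
  add("head", "conv1", f[1L], spec$out_channels)
  plan
}

#' Initialize a U-Net model
#'
#' He-uniform weight initialization (fan-in scaled), zero biases,
#' reproducible under the given seed.
#'
#' @param spec A [unet_spec()].
#' @param seed Integer RNG seed.
#' @return A `unet_model`: list with `spec` and named `params`
#'   (each a list with `W` and `b`).
#' @export
unet_init <- function(spec, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  params <- list()
  for (ly in unet_plan(spec)) {
    k2 <- switch(ly$type, conv3 = 9L, up = 4L, conv1 = 1L)
    fan_in <- k2 * ly$cin
    lim <- sqrt(6 / fan_in)
    ## conv3 weight rows are ordered channel-fastest within each of the 9
    ## kernel offsets: row index = cin + Cin * (k - 1)
    W <- switch(ly$type,
      conv3 = matrix(stats::runif(9L * ly$cin * ly$cout, -lim, lim),
                     9L * ly$cin, ly$cout),
      up = array(stats::runif(ly$cin * ly$cout * 4L, -lim, lim),
                 c(ly$cin, ly$cout, 4L)),
      conv1 = matrix(stats::runif(ly$cin * ly$cout, -lim, lim),
                     ly$cin, ly$cout))
    params[[ly$name]] <- list(W = W, b = numeric(ly$cout))
  }
  structure(list(spec = spec, params = params), class = "unet_model")
}

#' Trainable parameter count
#'
#' Sum of all trainable tensor sizes (weights and biases), a pure function
#' of the architecture spec.  Changing `in_channels` only changes the
#' first convolution, by `9 * base_filters * delta_channels` weights.
#'
#' @param x A `unet_spec` or `unet_model`.
#' @return Integer parameter count.
#' @export
parameter_count <- function(x) {
  if (inherits(x, "unet_model")) x <- x$spec
  stopifnot(inherits(x, "unet_spec"))
  n <- 0
  for (ly in unet_plan(x)) {
    k2 <- switch(ly$type, conv3 = 9L, up = 4L, conv1 = 1L)
    n <- n + k2 * ly$cin * ly$cout + ly$cout
  }
  as.integer(n)
}

## ---- batched index tables (memoised per H, W, B) ------------------------

## conv: 9 row-index vectors into the zero-padded (H+2)(W+2) x B row space,
## one per 3x3 kernel offset, plus the interior rows
conv3_indices <- function(H, W, B) {
  key <- sprintf("cv_%d_%d_%d", H, W, B)
  if (!is.null(.tractfodf_cache[[key]])) return(.tractfodf_cache[[key]])
  P2 <- (H + 2L) * (W + 2L)
  hh <- rep(seq_len(H), times = W)
  ww <- rep(seq_len(W), each = H)
  boff <- rep(P2 * (seq_len(B) - 1L), each = H * W)
  tk <- vector("list", 9L)
  for (dx in 0:2) for (dy in 0:2)
    tk[[1L + dy + 3L * dx]] <-
      rep((hh + dy) + (H + 2L) * (ww + dx - 1L), B) + boff
  out <- list(tk = tk, inner = tk[[5L]], npad = P2 * B)
  .tractfodf_cache[[key]] <- out
  out
}

## pool: output-row -> 4 input-row indices (2x2 block corners)
pool_indices <- function(H, W, B) {
  key <- sprintf("pl_%d_%d_%d", H, W, B)
  if (!is.null(.tractfodf_cache[[key]])) return(.tractfodf_cache[[key]])
  i <- rep(seq_len(H / 2L), times = W / 2L)
  j <- rep(seq_len(W / 2L), each = H / 2L)
  boff <- rep(H * W * (seq_len(B) - 1L), each = length(i))
  q <- matrix(0L, length(i) * B, 4L)
  for (dx in 0:1) for (dy in 0:1)
    q[, 1L + dy + 2L * dx] <-
      rep((2L * i - 1L + dy) + H * (2L * j - 2L + dx), B) + boff
  .tractfodf_cache[[key]] <- q
  q
}

## transposed conv: input-row -> 4 output-row indices on the 2H x 2W grid
up_indices <- function(H, W, B) {
  key <- sprintf("up_%d_%d_%d", H, W, B)
  if (!is.null(.tractfodf_cache[[key]])) return(.tractfodf_cache[[key]])
  i <- rep(seq_len(H), times = W)
  j <- rep(seq_len(W), each = H)
  boff <- rep(4L * H * W * (seq_len(B) - 1L), each = H * W)
  s <- matrix(0L, H * W * B, 4L)
  for (dx in 0:1) for (dy in 0:1)
    s[, 1L + dy + 2L * dx] <-
      rep((2L * i - 1L + dy) + 2L * H * (2L * j - 2L + dx), B) + boff
  .tractfodf_cache[[key]] <- s
  s
}

## ---- layer primitives on (HW*B, C) activation matrices ------------------

conv3_forward <- function(A, W9, b, ci) {
  C <- ncol(A)
  Apad <- matrix(0, ci$npad, C)
  Apad[ci$inner, ] <- A
  Pm <- matrix(0, nrow(A), 9L * C)
  for (k in 1:9) Pm[, (k - 1L) * C + seq_len(C)] <- Apad[ci$tk[[k]], ]
  Y <- Pm %*% W9
  Y <- Y + rep(b, each = nrow(Y))
  list(out = Y, Pm = Pm)
}

## input gradient = same-padded convolution of dY with the 180-degree
## flipped, channel-transposed kernel (gather + GEMM, no scatter-add)
conv3_backward <- function(dY, Pm, W9, Cin, ci) {
  dW <- crossprod(Pm, dY)
  db <- colSums(dY)
  Cout <- ncol(dY)
  Wf <- matrix(aperm(array(W9, c(Cin, 9L, Cout))[, 9:1, , drop = FALSE],
                     c(3L, 2L, 1L)), 9L * Cout, Cin)
  dA <- conv3_forward(dY, Wf, numeric(Cin), ci)$out
  list(dA = dA, dW = dW, db = db)
}

maxpool_forward <- function(A, qmat) {
  C <- ncol(A)
  n <- nrow(qmat)
  Cand <- matrix(0, n * C, 4L)
  for (a in 1:4) Cand[, a] <- A[qmat[, a], ]
  amax <- max.col(Cand, ties.method = "first")
  y <- Cand[cbind(seq_len(n * C), amax)]
  list(out = matrix(y, n, C), amax = amax)
}

maxpool_backward <- function(dY, amax, qmat, nrow_in) {
  C <- ncol(dY)
  n <- nrow(qmat)
  dA <- matrix(0, nrow_in, C)
  rows <- seq_len(n * C)
  r <- ((rows - 1L) %% n) + 1L
  coff <- ((rows - 1L) %/% n) * nrow_in
  dA[qmat[cbind(r, amax)] + coff] <- dY
  dA
}

upconv_forward <- function(A, Warr, b, smat) {
  Cout <- dim(Warr)[2L]
  out <- matrix(0, 4L * nrow(A), Cout)
  for (a in 1:4) out[smat[, a], ] <- A %*% Warr[, , a]
  out <- out + rep(b, each = nrow(out))
  list(out = out)
}

upconv_backward <- function(dY, A, Warr, smat) {
  Cin <- dim(Warr)[1L]
  dW <- array(0, dim(Warr))
  dXm <- matrix(0, nrow(A), Cin)
  for (a in 1:4) {
    dYa <- dY[smat[, a], , drop = FALSE]
    dW[, , a] <- crossprod(A, dYa)
    dXm <- dXm + tcrossprod(dYa, Warr[, , a])
  }
  list(dA = dXm, dW = dW, db = colSums(dY))
}

leaky_forward <- function(x, slope) {
  pos <- x > 0
  list(out = x * (pos + slope * !pos), pos = pos)
}

leaky_backward <- function(dy, pos, slope) dy * (pos + slope * !pos)

## ---- full network forward / backward ------------------------------------

## xm: (H*W*B, Cin) activation matrix; returns logits (H*W*B, Cout)
unet_fwd <- function(model, xm, H, W, B, training = FALSE) {
  spec <- model$spec; P <- model$params
  if (H %% 2L^(spec$depth - 1L) != 0L || W %% 2L^(spec$depth - 1L) != 0L)
    stop(sprintf("input %dx%d not divisible by 2^(depth-1) = %d",
                 H, W, 2L^(spec$depth - 1L)), call. = FALSE)
  slope <- spec$negative_slope
  cache <- list(); skips <- list()
  A <- xm; h <- H; w <- W
  for (i in seq_len(spec$depth)) {
    ci <- conv3_indices(h, w, B)
    for (cc in 1:2) {
      nm <- sprintf("enc%d_conv%d", i, cc)
      cf <- conv3_forward(A, P[[nm]]$W, P[[nm]]$b, ci)
      lf <- leaky_forward(cf$out, slope)
      cache[[nm]] <- list(Pm = cf$Pm, pos = lf$pos, ci = ci, cin = ncol(A))
      A <- lf$out
    }
    if (training && spec$dropout > 0) {
      keep <- 1 - spec$dropout
      mask <- matrix((stats::runif(length(A)) < keep) / keep, nrow(A), ncol(A))
      A <- A * mask
      cache[[sprintf("drop%d", i)]] <- mask
    }
    if (i < spec$depth) {
      skips[[i]] <- A
      qm <- pool_indices(h, w, B)
      pf <- maxpool_forward(A, qm)
      cache[[sprintf("pool%d", i)]] <- list(amax = pf$amax, qm = qm,
                                            nrow_in = nrow(A))
      A <- pf$out
      h <- h %/% 2L; w <- w %/% 2L
    }
  }
  for (i in rev(seq_len(spec$depth - 1L))) {
    nm <- sprintf("up%d", i)
    sm <- up_indices(h, w, B)
    uf <- upconv_forward(A, P[[nm]]$W, P[[nm]]$b, sm)
    cache[[nm]] <- list(Xm = A, sm = sm)
    h <- 2L * h; w <- 2L * w
    A <- cbind(uf$out, skips[[i]])
    cache[[sprintf("cat%d", i)]] <- c(ncol(uf$out), ncol(skips[[i]]))
    ci <- conv3_indices(h, w, B)
    for (cc in 1:2) {
      nm <- sprintf("dec%d_conv%d", i, cc)
      cf <- conv3_forward(A, P[[nm]]$W, P[[nm]]$b, ci)
      lf <- leaky_forward(cf$out, slope)
      cache[[nm]] <- list(Pm = cf$Pm, pos = lf$pos, ci = ci, cin = ncol(A))
      A <- lf$out
    }
  }
  Z <- A %*% P$head$W + rep(P$head$b, each = nrow(A))
  cache$head <- list(Xh = A)
  list(logits = Z, cache = cache)
}

## dZ: gradient w.r.t. logits (H*W*B, Cout)
unet_bwd <- function(model, cache, dZ) {
  spec <- model$spec; P <- model$params
  grads <- list()
  grads$head <- list(W = crossprod(cache$head$Xh, dZ), b = colSums(dZ))
  dA <- tcrossprod(dZ, P$head$W)
  slope <- spec$negative_slope
  dskips <- list()
  for (i in seq_len(spec$depth - 1L)) {
    for (cc in 2:1) {
      nm <- sprintf("dec%d_conv%d", i, cc)
      cc_ <- cache[[nm]]
      dA <- leaky_backward(dA, cc_$pos, slope)
      bk <- conv3_backward(dA, cc_$Pm, P[[nm]]$W, cc_$cin, cc_$ci)
      grads[[nm]] <- list(W = bk$dW, b = bk$db)
      dA <- bk$dA
    }
    sp <- cache[[sprintf("cat%d", i)]]
    dup <- dA[, seq_len(sp[1L]), drop = FALSE]
    dskips[[i]] <- dA[, sp[1L] + seq_len(sp[2L]), drop = FALSE]
    nm <- sprintf("up%d", i)
    uc <- cache[[nm]]
    bk <- upconv_backward(dup, uc$Xm, P[[nm]]$W, uc$sm)
    grads[[nm]] <- list(W = bk$dW, b = bk$db)
    dA <- bk$dA
  }
  for (i in rev(seq_len(spec$depth))) {
    if (i < spec$depth) {
      pc <- cache[[sprintf("pool%d", i)]]
      dA <- maxpool_backward(dA, pc$amax, pc$qm, pc$nrow_in)
      dA <- dA + dskips[[i]]
    }
    dm <- cache[[sprintf("drop%d", i)]]
    if (!is.null(dm)) dA <- dA * dm
    for (cc in 2:1) {
      nm <- sprintf("enc%d_conv%d", i, cc)
      cc_ <- cache[[nm]]
      dA <- leaky_backward(dA, cc_$pos, slope)
      bk <- conv3_backward(dA, cc_$Pm, P[[nm]]$W, cc_$cin, cc_$ci)
      grads[[nm]] <- list(W = bk$dW, b = bk$db)
      dA <- bk$dA
    }
  }
  grads
}

## (H, W, C [, B]) array -> (H*W*B, C) matrix with batch folded into rows
slice_batch_matrix <- function(x) {
  dm <- dim(x)
  if (length(dm) == 3L) dm <- c(dm, 1L)
  matrix(aperm(array(x, dm), c(1L, 2L, 4L, 3L)), dm[1L] * dm[2L] * dm[4L], dm[3L])
}

#' Run the U-Net forward on a slice or batch of slices
#'
#' @param model A `unet_model`.
#' @param x Array (H x W x in_channels) or batch (H x W x in_channels x B).
#' @param training Logical; enables dropout (uses the current RNG stream).
#' @return Sigmoid probabilities in (0, 1) with the same spatial shape:
#'   (H x W) for a single slice with one output channel, otherwise
#'   (H x W x out_channels [x B]).
#' @export
unet_forward <- function(model, x, training = FALSE) {
  dm <- dim(x)
  single <- length(dm) == 3L
  if (single) dm <- c(dm, 1L)
  if (dm[3L] != model$spec$in_channels)
    stop(sprintf("input has %d channels but model expects %d",
                 dm[3L], model$spec$in_channels), call. = FALSE)
  f <- unet_fwd(model, slice_batch_matrix(x), dm[1L], dm[2L], dm[4L],
                training = training)
  cout <- model$spec$out_channels
  p <- aperm(array(stats::plogis(f$logits), c(dm[1L], dm[2L], dm[4L], cout)),
             c(1L, 2L, 4L, 3L))
  if (single && cout == 1L) array(p, dm[1:2])
  else if (single) array(p, c(dm[1L], dm[2L], cout))
  else p
}
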