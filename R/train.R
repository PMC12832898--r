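## Training recipe: binary cross-entropy, Adam, cosine-annealed learning
## rate from 0.002, early stopping on fused 3D validation Dice with
## patience 50, one independent binary model per tract (or one multi-label
## model over all tracts).

#' Binary cross-entropy loss
#'
#' Mean of \eqn{-[y \log p + (1-y)\log(1-p)]} over all elements (and
#' channels, in multi-label mode), with predictions clipped to
#' \eqn{[\epsilon, 1-\epsilon]}, \eqn{\epsilon = 10^{-7}}.
#'
#' @param predictions Array of probabilities in (0, 1).
#' @param labels Array of the same shape with values in \{0, 1\}.
#' @return Non-negative scalar loss.
#' @export
bce_loss <- function(predictions, labels) {
  if (!identical(dim(predictions), dim(labels)) &&
      length(predictions) != length(labels))
    stop("prediction and label shapes differ", call. = FALSE)
  eps <- 1e-7
  p <- pmin(pmax(predictions, eps), 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

#' Cosine-annealed learning rate
#'
#' \eqn{\eta_t = \eta_{min} + (\eta_0 - \eta_{min})(1 + \cos(\pi t / T))/2},
#' monotone non-increasing on \eqn{[0, T]}, starting at the initial rate
#' 0.002 and reaching `eta_min` at `t_max`.
#'
#' @param epoch Current epoch t, `0 <= t <= t_max`.
#' @param t_max Annealing horizon (no warm restarts).
#' @param lr0 Initial learning rate (default 0.002).
#' @param eta_min Final learning rate (default 0).
#' @return Learning rate.
#' @export
cosine_lr <- function(epoch, t_max, lr0 = 0.002, eta_min = 0) {
  if (epoch < 0 || epoch > t_max)
    stop("'epoch' must lie in [0, t_max]", call. = FALSE)
  eta_min + 0.5 * (lr0 - eta_min) * (1 + cos(pi * epoch / t_max))
}

#' Training configuration
#'
#' Defaults follow the full-scale recipe: Adam at initial learning rate
#' 0.002 with cosine annealing to 0, batch size 200, up to 400 epochs,
#' early stopping on validation Dice with patience 50, dropout 0.4.
#' Tests and desk-scale runs override `batch_size`/`max_epochs` downward.
#'
#' @param learning_rate0 Initial learning rate.
#' @param eta_min Cosine-annealing floor.
#' @param batch_size Slices per gradient step.
#' @param max_epochs Epoch cap (also the cosine horizon `t_max`).
#' @param patience Early-stop patience, in epochs without validation-Dice
#'   improvement; must be `<= max_epochs`.
#' @param seed RNG seed covering initialization, shuffling and dropout.
#' @param mode `"single_class"` (one tract) or `"multi_class"`
#'   (multi-label, per-channel sigmoid + BCE — tract masks overlap, so
#'   voxels may be positive in several channels at once).
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate0 = 0.002, eta_min = 0,
                         batch_size = 200L, max_epochs = 400L,
                         patience = 50L, seed = 1L,
                         mode = c("single_class", "multi_class")) {
  mode <- match.arg(mode)
  if (batch_size < 1L) stop("'batch_size' must be >= 1", call. = FALSE)
  if (patience > max_epochs) stop("'patience' must be <= max_epochs", call. = FALSE)
  structure(list(learning_rate0 = learning_rate0, eta_min = eta_min,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 mode = mode),
            class = "train_config")
}

#' Build a slice dataset from subject volumes
#'
#' Assembles the 2D training records and the 3D validation pairs for one
#' training run.  In single-class mode the label volume is the chosen
#' tract's mask; voxels shared with other tracts are retained in the
#' positive class (masks may overlap, and each tract's model sees the full
#' mask).  In multi-label mode all tract masks are stacked channel-wise.
#' Slices are drawn from all three orthogonal views for a single network;
#' empty-label slices are kept (negatives teach background suppression).
#'
#' @param subjects Named list; each element is `list(fodf = 4D array,
#'   masks = named list of 3D arrays)` (e.g. a `phantom_dataset`).
#' @param tract Tract name for single-class labels, or `NULL` for
#'   multi-label.
#' @param train_subjects,val_subjects Subject names per split (defaults:
#'   all subjects in both — the overfit configuration used for phantoms).
#' @param views Views to slice along (default all three).
#' @return List with `train` (slice records), `validation` (list of
#'   `list(fodf, label)`), `tract`, `n_labels`.
#' @export
build_slice_dataset <- function(subjects, tract = NULL,
                                train_subjects = names(subjects),
                                val_subjects = names(subjects),
                                views = 1:3) {
  label_of <- function(s) {
    if (!is.null(tract)) {
      if (is.null(s$masks[[tract]]))
        stop(sprintf("tract '%s' not found", tract), call. = FALSE)
      s$masks[[tract]]
    } else {
      ar <- array(0L, c(dim(s$masks[[1L]]), length(s$masks)))
      for (k in seq_along(s$masks)) ar[, , , k] <- s$masks[[k]]
      ar
    }
  }
  train <- list()
  for (nm in train_subjects) {
    s <- subjects[[nm]]
    train <- c(train, extract_slices(s$fodf, label_of(s), views, subject = nm))
  }
  validation <- lapply(val_subjects, function(nm) {
    s <- subjects[[nm]]
    list(fodf = s$fodf, label = label_of(s))
  })
  n_labels <- if (is.null(tract)) length(subjects[[1L]]$masks) else 1L
  list(train = train, validation = validation, tract = tract,
       n_labels = n_labels)
}

## Adam step on a nested params/grads structure
adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    for (fld in c("W", "b")) {
      g <- grads[[nm]][[fld]]
      m <- beta1 * state$m[[nm]][[fld]] + (1 - beta1) * g
      v <- beta2 * state$v[[nm]][[fld]] + (1 - beta2) * g^2
      state$m[[nm]][[fld]] <- m
      state$v[[nm]][[fld]] <- v
      params[[nm]][[fld]] <- params[[nm]][[fld]] -
        lr * (m / bc1) / (sqrt(v / bc2) + eps)
    }
  }
  list(params = params, state = state)
}

adam_init <- function(params) {
  zero <- lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))
  list(t = 0L, m = zero, v = zero)
}

#' Train a U-Net on a slice dataset
#'
#' Runs Adam with cosine-annealed learning rate and per-element BCE over
#' shuffled mini-batches of 2D slices, evaluates the fused 3D validation
#' Dice after every epoch, keeps the best-scoring parameters, and stops at
#' `max_epochs` or when the validation Dice has not improved for
#' `patience` consecutive epochs.  Bit-reproducible given the seed.
#'
#' @param net_spec A [unet_spec()] (or an initialized `unet_model` to
#'   continue training).
#' @param dataset Output of [build_slice_dataset()].
#' @param config A [train_config()].
#' @param verbose Print per-epoch progress.
#' @param eval_fn Validation scorer `function(model) -> Dice`; the default
#'   fuses tri-plane predictions per validation subject and averages their
#'   3D Dice.  Overridable for testing the early-stop contract.
#' @return A `train_state`: list with `model` (best checkpoint),
#'   `best_dice`, `log` (data.frame epoch/lr/train_loss/val_dice),
#'   `epochs_run`, `config`.
#' @export
train <- function(net_spec, dataset, config = train_config(),
                  verbose = FALSE, eval_fn = NULL) {
  if (length(dataset$train) == 0L) stop("empty training set", call. = FALSE)
  if (length(dataset$validation) == 0L && is.null(eval_fn))
    stop("empty validation set", call. = FALSE)
  model <- if (inherits(net_spec, "unet_model")) net_spec
  else unet_init(net_spec, seed = config$seed)
  spec <- model$spec
  if (is.null(eval_fn))
    eval_fn <- function(m) validation_dice(m, dataset$validation)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed + 1L)
  recs <- dataset$train
  H <- dim(recs[[1L]]$image)[1L]; W <- dim(recs[[1L]]$image)[2L]
  state <- adam_init(model$params)
  best <- list(dice = -Inf, params = model$params, epoch = 0L)
  since_improve <- 0L
  log <- data.frame(epoch = integer(), lr = numeric(),
                    train_loss = numeric(), val_dice = numeric())
  nb <- length(recs)
  for (epoch in seq_len(config$max_epochs)) {
    lr <- cosine_lr(epoch - 1L, config$max_epochs,
                    config$learning_rate0, config$eta_min)
    ord <- sample.int(nb)
    losses <- numeric()
    for (start in seq(1L, nb, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, nb)]
      hw <- H * W
      xm <- matrix(0, hw * length(idx), spec$in_channels)
      ym <- matrix(0, hw * length(idx), spec$out_channels)
      for (k in seq_along(idx)) {
        r <- recs[[idx[k]]]
        rows <- (k - 1L) * hw + seq_len(hw)
        xm[rows, ] <- matrix(r$image, hw, spec$in_channels)
        ym[rows, ] <- matrix(r$label, hw, spec$out_channels)
      }
      fw <- unet_fwd(model, xm, H, W, length(idx), training = TRUE)
      p <- stats::plogis(fw$logits)
      loss <- bce_loss(p, ym)
      if (!is.finite(loss))
        stop(sprintf("non-finite loss at epoch %d (lr %.2g)", epoch, lr),
             call. = FALSE)
      losses <- c(losses, loss)
      dZ <- (p - ym) / length(ym)
      grads <- unet_bwd(model, fw$cache, dZ)
      up <- adam_step(model$params, grads, state, lr)
      model$params <- up$params
      state <- up$state
    }
    vd <- eval_fn(model)
    log <- rbind(log, data.frame(epoch = epoch, lr = lr,
                                 train_loss = mean(losses), val_dice = vd))
    if (verbose)
      message(sprintf("epoch %3d  lr %.5f  loss %.5f  val dice %.4f",
                      epoch, lr, mean(losses), vd))
    if (vd > best$dice) {
      best <- list(dice = vd, params = model$params, epoch = epoch)
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
      if (since_improve >= config$patience) break
    }
  }
  model$params <- best$params
  structure(list(model = model, best_dice = best$dice,
                 best_epoch = best$epoch, log = log,
                 epochs_run = nrow(log), config = config),
            class = "train_state")
}

#' Fused 3D validation Dice
#'
#' Mean over validation subjects of the Dice between the tri-plane fused,
#' thresholded 3D prediction and the reference label (averaged over
#' channels in multi-label mode) — the quantity early stopping selects on.
#'
#' @param model A `unet_model`.
#' @param validation List of `list(fodf, label)` pairs.
#' @param tau Fusion threshold (default 0.5).
#' @return Mean Dice in [0, 1].
#' @export
validation_dice <- function(model, validation, tau = 0.5) {
  if (length(validation) == 0L) stop("need >= 1 validation subject", call. = FALSE)
  ds <- vapply(validation, function(v) {
    prob <- predict_volume(model, v$fodf)
    if (length(dim(prob)) == 3L) {
      m <- threshold_mask(prob, tau)
      dice_of(m, v$label)
    } else {
      mean(vapply(seq_len(dim(prob)[4L]), function(ch) {
        dice_of(threshold_mask(prob[, , , ch], tau), v$label[, , , ch])
      }, numeric(1L)))
    }
  }, numeric(1L))
  mean(ds)
}

## Dice with the all-empty edge case scored 0 (validation context only)
dice_of <- function(P, G) {
  cc <- confusion_counts(P, G)
  if (cc$TP + cc$FN + cc$FP == 0L) return(0)
  2 * cc$TP / (2 * cc$TP + cc$FP + cc$FN)
}
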