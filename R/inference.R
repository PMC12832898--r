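## Tri-plane inference: per-view 2D prediction over a whole volume,
## voxel-wise averaging of the three probability maps, thresholding at 0.5.

#' Predict a 3D probability volume along one view
#'
#' Slices the fODF volume along the given axis, runs the model on each 2D
#' slice in evaluation mode (dropout off), and stacks the per-slice
#' probability maps back into a 3D volume in the original orientation.
#'
#' @param model A `unet_model`.
#' @param volume 4D fODF array (X x Y x Z x in_channels).
#' @param view Axis to slice along: 1, 2 or 3.
#' @param batch_size Slices per forward pass (default 16).
#' @return Probability array in [0, 1]: 3D for one output channel, 4D
#'   (grid x channels) otherwise; attribute `view` records provenance.
#' @export
predict_view <- function(model, volume, view, batch_size = 16L) {
  dm <- dim(volume)
  if (length(dm) != 4L) stop("'volume' must be 4D", call. = FALSE)
  if (dm[4L] != model$spec$in_channels)
    stop(sprintf("volume has %d channels but model expects %d",
                 dm[4L], model$spec$in_channels), call. = FALSE)
  n <- dm[view]
  hw <- dm[setdiff(1:3, view)]
  cout <- model$spec$out_channels
  slices <- vector("list", n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    x <- array(0, c(hw[1L], hw[2L], dm[4L], length(idx)))
    for (k in seq_along(idx)) x[, , , k] <- slice_of(volume, view, idx[k])
    p <- unet_forward(model, x, training = FALSE)  # (H, W, cout, B)
    for (k in seq_along(idx)) {
      sl <- array(p[, , , k], c(hw[1L], hw[2L], cout))
      slices[[idx[k]]] <- if (cout == 1L) array(sl, hw) else sl
    }
  }
  out <- stack_slices(slices, view, n)
  attr(out, "view") <- view
  out
}

#' Fuse per-view probability volumes by voxel-wise averaging
#'
#' Arithmetic mean of the per-view probability maps at every voxel;
#' commutative in argument order, and bounded voxel-wise between the
#' minimum and maximum of the inputs.
#'
#' @param maps List of probability arrays on identical grids (normally the
#'   three per-view maps).
#' @return Fused probability array; attribute `view` set to `"fused"`.
#' @export
fuse_views <- function(maps) {
  if (length(maps) < 1L) stop("need at least one map", call. = FALSE)
  d0 <- dim(maps[[1L]])
  for (m in maps) if (!identical(dim(m), d0))
    stop("probability maps are on different grids", call. = FALSE)
  out <- Reduce(`+`, maps) / length(maps)
  attributes(out) <- list(dim = d0)
  attr(out, "view") <- "fused"
  out
}

#' Threshold a probability volume into a binary mask
#'
#' A voxel is positive iff its probability is strictly greater than `tau`
#' (exact ties are negative, a deliberate and bit-stable tie rule).
#'
#' @param map Probability array with values in [0, 1].
#' @param tau Threshold in [0, 1] (default 0.5).
#' @return Integer 0/1 array of the same shape.
#' @export
threshold_mask <- function(map, tau = 0.5) {
  if (tau < 0 || tau > 1) stop("'tau' must be in [0, 1]", call. = FALSE)
  out <- array(as.integer(map > tau), dim(map))
  out
}

#' Tri-plane fused prediction for a whole volume
#'
#' Convenience wrapper: predicts along all three views and averages.
#'
#' @param model A `unet_model`.
#' @param volume 4D fODF array (cubic grid).
#' @param views Views to predict and fuse (default all three).
#' @param batch_size Slices per forward pass.
#' @return Fused probability array (3D, or 4D for multi-label models).
#' @export
predict_volume <- function(model, volume, views = 1:3, batch_size = 16L) {
  maps <- lapply(views, function(v) predict_view(model, volume, v, batch_size))
  fuse_views(maps)
}
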