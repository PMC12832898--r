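## Deterministic preprocessing: central crop, fODF normalization,
## tri-plane slice extraction, subject-wise splits.

#' Central spatial crop of a 3D or 4D volume
#'
#' Crops each spatial axis to the target extent with offset
#' `floor((dim - target) / 2)` (the leftover voxel, if any, stays on the
#' high side), leaving any trailing channel axis untouched.  The standard
#' use is cropping 145 x 174 x 145 volumes to the uniform 144-cube input
#' grid.
#'
#' @param x 3D array (X x Y x Z) or 4D array (X x Y x Z x C).
#' @param target Length-3 integer target spatial shape (default
#'   `c(144, 144, 144)`).
#' @return Cropped array.
#' @export
central_crop <- function(x, target = c(144L, 144L, 144L)) {
  dm <- dim(x)
  if (!length(dm) %in% c(3L, 4L))
    stop("'x' must be a 3D or 4D array", call. = FALSE)
  sp <- dm[1:3]
  target <- as.integer(target)
  if (any(sp < target))
    stop(sprintf("spatial shape (%s) smaller than crop target (%s)",
                 paste(sp, collapse = ","), paste(target, collapse = ",")),
         call. = FALSE)
  off <- (sp - target) %/% 2L
  ix <- lapply(1:3, function(a) seq.int(off[a] + 1L, off[a] + target[a]))
  if (length(dm) == 3L) x[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  else x[ix[[1]], ix[[2]], ix[[3]], , drop = FALSE]
}

#' Normalize an fODF volume by its mean foreground amplitude
#'
#' Divides all SH channels by the mean order-0 coefficient over foreground
#' voxels (those with positive order-0 coefficient), making the input scale
#' invariant: `normalize_fodf(k * x)` equals `normalize_fodf(x)` for any
#' k > 0.
#'
#' @param volume 4D fODF array.
#' @return Normalized 4D array.
#' @export
normalize_fodf <- function(volume) {
  if (length(dim(volume)) != 4L) stop("'volume' must be 4D", call. = FALSE)
  c0 <- volume[, , , 1L]
  fg <- c0 > 0
  if (!any(fg)) stop("no foreground voxels to normalize by", call. = FALSE)
  m <- mean(c0[fg])
  if (!is.finite(m) || m <= 0) stop("non-positive foreground mean", call. = FALSE)
  volume / m
}

#' Extract tri-plane 2D slices from a volume and its labels
#'
#' Converts a cubic fODF volume (and aligned label volume) into per-slice
#' records along the requested orthogonal views.  Each record holds an
#' H x W x C coefficient image and the matching H x W (or H x W x C_tracts)
#' binary label; stacking the records of any single view reproduces the
#' volume exactly.
#'
#' @param fodf 4D array (S x S x S x n_coeffs), cubic spatial grid.
#' @param label 3D binary array (single tract) or 4D (multi-label,
#'   channels last), aligned to `fodf`; may be `NULL` for inference.
#' @param views Integer subset of `1:3` (axis along which slices are taken).
#' @param subject Subject identifier carried into the records.
#' @return List of slice records: `list(subject, view, index, image, label)`.
#' @export
extract_slices <- function(fodf, label = NULL, views = 1:3, subject = "s1") {
  dm <- dim(fodf)
  if (length(dm) != 4L) stop("'fodf' must be 4D", call. = FALSE)
  if (length(unique(dm[1:3])) != 1L && length(views) > 1L)
    stop("multiple views require a cubic spatial grid", call. = FALSE)
  if (!all(views %in% 1:3)) stop("'views' must be a subset of 1:3", call. = FALSE)
  if (!is.null(label)) {
    ldm <- dim(label)
    if (!all(ldm[1:3] == dm[1:3]))
      stop("label grid does not match fODF grid", call. = FALSE)
  }
  out <- list()
  for (v in views) {
    for (i in seq_len(dm[v])) {
      im <- slice_of(fodf, v, i)
      lb <- if (is.null(label)) NULL else slice_of(label, v, i)
      out[[length(out) + 1L]] <-
        list(subject = subject, view = v, index = i, image = im, label = lb)
    }
  }
  out
}

## take slice i along axis v of a 3D or 4D array (channels kept last)
slice_of <- function(x, v, i) {
  nd <- length(dim(x))
  if (nd == 3L) {
    switch(v, x[i, , ], x[, i, ], x[, , i])
  } else {
    switch(v,
           array(x[i, , , ], dim(x)[c(2, 3, 4)]),
           array(x[, i, , ], dim(x)[c(1, 3, 4)]),
           array(x[, , i, ], dim(x)[c(1, 2, 4)]))
  }
}

## inverse of slice_of over a full view: slices is a list in index order
stack_slices <- function(slices, view, side = length(slices)) {
  d2 <- dim(slices[[1L]])
  has_ch <- length(d2) == 3L
  if (has_ch) {
    dims <- switch(view,
                   c(side, d2[1L], d2[2L], d2[3L]),
                   c(d2[1L], side, d2[2L], d2[3L]),
                   c(d2[1L], d2[2L], side, d2[3L]))
    out <- array(0, dims)
    for (i in seq_len(side)) {
      if (view == 1L) out[i, , , ] <- slices[[i]]
      else if (view == 2L) out[, i, , ] <- slices[[i]]
      else out[, , i, ] <- slices[[i]]
    }
  } else {
    dims <- switch(view,
                   c(side, d2[1L], d2[2L]),
                   c(d2[1L], side, d2[2L]),
                   c(d2[1L], d2[2L], side))
    out <- array(0, dims)
    for (i in seq_len(side)) {
      if (view == 1L) out[i, , ] <- slices[[i]]
      else if (view == 2L) out[, i, ] <- slices[[i]]
      else out[, , i] <- slices[[i]]
    }
  }
  out
}

#' Subject-wise train/validation/test split
#'
#' Either passes through explicit disjoint id lists, or shuffles the ids
#' with the given seed and allocates them by the fractions (each non-empty
#' split receives at least one subject; validation and test sizes are
#' rounded, the remainder goes to training — 105 subjects at
#' 0.6/0.2/0.2 gives 63/21/21).  Splits are always pairwise disjoint and
#' exhaustive: no subject appears in more than one split.
#'
#' @param ids Character or integer vector of subject ids (>= 3).
#' @param fractions Length-3 positive fractions summing to 1.
#' @param seed Integer seed for the shuffle.
#' @param train,validation,test Optional explicit id lists (all three must
#'   be given together).
#' @return A `split_plan`: list with `train`, `validation`, `test`.
#' @export
make_splits <- function(ids, fractions = c(0.6, 0.2, 0.2), seed = 1L,
                        train = NULL, validation = NULL, test = NULL) {
  ids <- unique(ids)
  if (length(ids) < 3L) stop("need at least 3 subjects", call. = FALSE)
  explicit <- !is.null(train) || !is.null(validation) || !is.null(test)
  if (explicit) {
    parts <- list(train = train, validation = validation, test = test)
    all_ids <- unlist(parts)
    if (anyDuplicated(all_ids))
      stop("explicit split lists overlap", call. = FALSE)
    if (!setequal(all_ids, ids))
      stop("explicit split lists must cover all ids exactly", call. = FALSE)
    return(structure(parts, class = "split_plan"))
  }
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop("'fractions' must be 3 positive values summing to 1", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  ids <- sample(ids)
  n <- length(ids)
  n_val <- max(1L, as.integer(round(fractions[2L] * n)))
  n_test <- max(1L, as.integer(round(fractions[3L] * n)))
  n_train <- n - n_val - n_test
  if (n_train < 1L) stop("fractions leave no training subjects", call. = FALSE)
  structure(list(train = ids[seq_len(n_train)],
                 validation = ids[n_train + seq_len(n_val)],
                 test = ids[n_train + n_val + seq_len(n_test)]),
            class = "split_plan")
}
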