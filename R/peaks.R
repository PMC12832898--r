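## Peak extraction from SH fODFs: grid local maxima refined by projected
## gradient ascent on the sphere.  Used by the phantom validation path and
## by the peaks-input ablation.

.tractfodf_cache <- new.env(parent = emptyenv())

## basis matrix + antipodal k-nearest-neighbour table for a grid, memoised
peak_machinery <- function(grid, spec, k = 8L) {
  key <- sprintf("pk_%d_%d_%d", nrow(grid$directions), spec$lmax, k)
  if (!is.null(.tractfodf_cache[[key]])) return(.tractfodf_cache[[key]])
  D <- grid$directions
  B <- sh_basis_matrix(D, spec)
  A <- abs(tcrossprod(D))          # antipodal metric: |u . v|
  diag(A) <- -Inf
  nbrs <- t(apply(A, 1L, function(r) order(r, decreasing = TRUE)[seq_len(k)]))
  out <- list(B = B, nbrs = nbrs, dirs = D)
  .tractfodf_cache[[key]] <- out
  out
}

## canonical sign for an axial direction: last non-negligible coordinate > 0
canonicalize_axes <- function(U) {
  s <- sign(U[, 3L])
  z0 <- abs(U[, 3L]) < 1e-8
  s[z0] <- sign(U[z0, 2L])
  y0 <- z0 & abs(U[, 2L]) < 1e-8
  s[y0] <- sign(U[y0, 1L])
  s[s == 0] <- 1
  U * s
}

## Projected gradient ascent on the sphere for a batch of start directions.
## U: M x 3 starts; C: n_coeffs x M coefficient columns (one per start).
## Numerical tangent-plane gradient; per-point step halving on failure.
refine_peaks_batch <- function(U, C, spec, steps = 10L, step0 = 0.05) {
  M <- nrow(U)
  if (M == 0L) return(list(U = U, f = numeric(0)))
  ## value at point i is B[i, ] . C[, i]
  eval_f <- function(V) rowSums(sh_basis_matrix(V, spec) * t(C))
  ## orthonormal tangent basis per point
  tangent <- function(V) {
    a <- cbind(-V[, 2L], V[, 1L], 0)
    small <- rowSums(a^2) < 1e-12
    a[small, ] <- cbind(V[small, 3L], 0, -V[small, 1L])
    a <- a / sqrt(rowSums(a^2))
    b <- cbind(V[, 2L] * a[, 3L] - V[, 3L] * a[, 2L],
               V[, 3L] * a[, 1L] - V[, 1L] * a[, 3L],
               V[, 1L] * a[, 2L] - V[, 2L] * a[, 1L])
    list(t1 = a, t2 = b)
  }
  normalize <- function(V) V / sqrt(rowSums(V^2))
  f <- eval_f(U)
  step <- rep(step0, M)
  eps <- 1e-4
  for (it in seq_len(steps)) {
    tb <- tangent(U)
    g1 <- (eval_f(normalize(U + eps * tb$t1)) -
             eval_f(normalize(U - eps * tb$t1))) / (2 * eps)
    g2 <- (eval_f(normalize(U + eps * tb$t2)) -
             eval_f(normalize(U - eps * tb$t2))) / (2 * eps)
    gn <- sqrt(g1^2 + g2^2)
    act <- gn > 1e-10
    if (!any(act)) break
    dirs <- (tb$t1 * g1 + tb$t2 * g2) / pmax(gn, 1e-30)
    for (try in 1:4) {
      Unew <- normalize(U + step * dirs)
      fnew <- eval_f(Unew)
      ok <- act & (fnew > f)
      U[ok, ] <- Unew[ok, , drop = FALSE]
      f[ok] <- fnew[ok]
      step[!ok] <- step[!ok] / 2
      if (all(ok | !act)) break
    }
  }
  list(U = U, f = f)
}

#' Extract fODF peaks from an SH coefficient vector
#'
#' Finds local maxima of the (antipodally symmetric) fODF over a hemisphere
#' grid, refines each by projected gradient ascent on the sphere, merges
#' near-duplicate axes, discards peaks below a relative amplitude
#' threshold, and returns at most `max_peaks` peaks sorted by descending
#' amplitude.  A non-positive fODF yields an empty peak set (isotropic
#' profiles have no strict local maxima and also yield none).
#'
#' @param coeffs SH coefficient vector.
#' @param spec `sh_basis_spec`; inferred from `length(coeffs)` if `NULL`.
#' @param grid Hemisphere `sphere_grid` used for candidate search
#'   (default the 724-point Fibonacci hemisphere).
#' @param max_peaks Maximum number of peaks returned (default 3, the usual
#'   per-voxel peak budget of peak-based segmentation inputs).
#' @param rel_threshold Peaks with amplitude below this fraction of the
#'   strongest peak are discarded (default 0.1).
#' @param refine Logical; run gradient-ascent refinement (default `TRUE`).
#'   Grid-resolution peaks (about 3-5 degrees quantization at 724 points)
#'   are returned when `FALSE`.
#' @param merge_angle_deg Peaks closer than this angle are merged,
#'   keeping the stronger (default 10).
#' @return A `peak_set`: list with `directions` (K x 3, canonical-sign unit
#'   axes) and `amplitudes` (non-increasing, non-negative).
#' @export
extract_peaks <- function(coeffs, spec = NULL, grid = fibonacci_hemisphere(),
                          max_peaks = 3L, rel_threshold = 0.1,
                          refine = TRUE, merge_angle_deg = 10) {
  if (rel_threshold < 0 || rel_threshold >= 1)
    stop("'rel_threshold' must be in [0, 1)", call. = FALSE)
  if (is.null(spec)) spec <- sh_basis_spec(lmax_from_ncoeffs(length(coeffs)))
  mach <- peak_machinery(grid, spec)
  v <- drop(mach$B %*% coeffs)
  cand <- which(candidate_mask(v, mach$nbrs) & v > 0)
  empty <- structure(list(directions = matrix(0, 0L, 3L),
                          amplitudes = numeric(0)), class = "peak_set")
  if (length(cand) == 0L) return(empty)
  U <- mach$dirs[cand, , drop = FALSE]
  f <- v[cand]
  if (refine) {
    C <- matrix(coeffs, length(coeffs), length(cand))
    r <- refine_peaks_batch(U, C, spec)
    U <- r$U; f <- r$f
  }
  sel <- merge_and_rank(U, f, rel_threshold, merge_angle_deg, max_peaks)
  if (nrow(sel$U) == 0L) return(empty)
  structure(list(directions = sel$U, amplitudes = sel$f), class = "peak_set")
}

## strict grid local maxima: value greater than every neighbour value
candidate_mask <- function(v, nbrs) {
  nm <- v[nbrs[, 1L]]
  for (k in seq_len(ncol(nbrs))[-1L]) nm <- pmax(nm, v[nbrs[, k]])
  v > nm
}

## canonical signs, duplicate-axis merge (keep stronger), relative
## threshold, amplitude sort, cap at max_peaks
merge_and_rank <- function(U, f, rel_threshold, merge_angle_deg, max_peaks) {
  keepable <- f > 0
  U <- U[keepable, , drop = FALSE]; f <- f[keepable]
  if (length(f) == 0L) return(list(U = U, f = f))
  U <- canonicalize_axes(U)
  o <- order(f, decreasing = TRUE)
  U <- U[o, , drop = FALSE]; f <- f[o]
  cosmin <- cos(merge_angle_deg * pi / 180)
  keep <- rep(TRUE, length(f))
  for (i in seq_along(f)) {
    if (!keep[i]) next
    if (i < length(f)) {
      later <- (i + 1L):length(f)
      dup <- later[abs(U[later, , drop = FALSE] %*% U[i, ]) > cosmin]
      keep[dup] <- FALSE
    }
  }
  U <- U[keep, , drop = FALSE]; f <- f[keep]
  strong <- f >= rel_threshold * f[1L]
  U <- U[strong, , drop = FALSE]; f <- f[strong]
  if (length(f) > max_peaks) {
    U <- U[seq_len(max_peaks), , drop = FALSE]
    f <- f[seq_len(max_peaks)]
  }
  list(U = U, f = f)
}

#' Convert an fODF volume to a peak-vector image
#'
#' Per voxel, the K strongest fODF peaks scaled by their amplitudes,
#' zero-padded when fewer exist, laid out channel-wise as
#' (x1, y1, z1, x2, y2, z2, ...).  This is the input representation used by
#' peak-based tract segmentation (K = 3 gives the usual 9-channel image)
#' and serves here as the ablation input contrasting peak vectors with the
#' full SH representation.
#'
#' @param volume 4D array (X x Y x Z x n_coeffs) of SH coefficients.
#' @param K Number of peaks per voxel (default 3).
#' @param grid Hemisphere grid for the peak search.
#' @param refine Refine peaks by gradient ascent (default `FALSE`: grid
#'   resolution is adequate for a learning input and much faster over a
#'   whole volume).
#' @param rel_threshold Relative amplitude threshold, as in
#'   [extract_peaks()].
#' @return 4D array (X x Y x Z x 3K).
#' @export
fodf_to_peak_image <- function(volume, K = 3L, grid = fibonacci_hemisphere(),
                               refine = FALSE, rel_threshold = 0.1) {
  K <- as.integer(K)
  if (K < 1L) stop("'K' must be >= 1", call. = FALSE)
  dm <- dim(volume)
  if (length(dm) != 4L) stop("'volume' must be a 4D array", call. = FALSE)
  spec <- sh_basis_spec(lmax_from_ncoeffs(dm[4L]))
  mach <- peak_machinery(grid, spec)
  nvox <- prod(dm[1:3])
  Cmat <- t(matrix(volume, nvox, dm[4L]))          # n_coeffs x nvox
  V <- mach$B %*% Cmat                             # grid values, N x nvox
  ## strict local maxima, vectorized across voxels
  NM <- V[mach$nbrs[, 1L], , drop = FALSE]
  for (k in seq_len(ncol(mach$nbrs))[-1L])
    NM <- pmax(NM, V[mach$nbrs[, k], , drop = FALSE])
  cand <- which(V > NM & V > 0, arr.ind = TRUE)
  out <- array(0, c(nvox, 3L * K))
  if (nrow(cand) > 0L) {
    U <- mach$dirs[cand[, 1L], , drop = FALSE]
    f <- V[cand]
    vox <- cand[, 2L]
    if (refine) {
      r <- refine_peaks_batch(U, Cmat[, vox, drop = FALSE], spec)
      U <- r$U; f <- r$f
    }
    idx <- split(seq_along(vox), vox)
    for (vs in idx) {
      vi <- vox[vs[1L]]
      sel <- merge_and_rank(U[vs, , drop = FALSE], f[vs],
                            rel_threshold, 10, K)
      kf <- length(sel$f)
      if (kf > 0L)
        out[vi, seq_len(3L * kf)] <- as.vector(t(sel$U * sel$f))
    }
  }
  array(out, c(dm[1:3], 3L * K))
}
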