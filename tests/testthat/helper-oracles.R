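## Independent oracles used across tests: explicit voxel loops and
## hand-arithmetic formulas, deliberately naive so they share no code with
## the implementation they check.

## six volumetric metrics by explicit voxel loop
brute_force_metrics <- function(P, G) {
  p <- as.vector(P); g <- as.vector(G)
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(p)) {
    if (p[i] == 1 && g[i] == 1) tp <- tp + 1L
    else if (p[i] == 1 && g[i] == 0) fp <- fp + 1L
    else if (p[i] == 0 && g[i] == 1) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(
    TP = tp, FP = fp, FN = fn, TN = tn,
    dice = if (tp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_,
    vop = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    vor = if (tp + fn > 0) fp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    jaccard = if (tp + fp + fn > 0) tp / (tp + fp + fn) else NA_real_
  )
}

## voxel count of a discrete cylinder by explicit triple loop:
## voxels within `radius` of the segment a--b (voxel centers 1..S)
brute_force_cylinder_count <- function(S, a, b, radius) {
  ab <- b - a
  len2 <- sum(ab^2)
  count <- 0L
  for (x in 1:S) for (y in 1:S) for (z in 1:S) {
    p <- c(x, y, z)
    t <- max(0, min(1, sum((p - a) * ab) / len2))
    if (sqrt(sum((p - a - t * ab)^2)) <= radius) count <- count + 1L
  }
  count
}

## closed-form trainable-parameter count from the documented architecture:
## two 3x3 convs per level, 2x2 transposed conv + two 3x3 convs per
## decoder level (skip doubles the input channels), 1x1 head
closed_form_param_count <- function(in_ch, out_ch, depth, base) {
  f <- base * 2^(seq_len(depth) - 1)
  n <- 0
  cin <- in_ch
  for (i in seq_len(depth)) {
    n <- n + 9 * cin * f[i] + f[i] + 9 * f[i] * f[i] + f[i]
    cin <- f[i]
  }
  for (i in rev(seq_len(depth - 1))) {
    n <- n + 4 * f[i + 1] * f[i] + f[i] +
      9 * (2 * f[i]) * f[i] + f[i] + 9 * f[i] * f[i] + f[i]
  }
  n + f[1] * out_ch + out_ch
}

## random binary mask pair on an S^3 grid
random_mask_pair <- function(S, prob_g = 0.1, prob_flip = 0.05) {
  g <- array(rbinom(S^3, 1L, prob_g), c(S, S, S))
  flip <- array(rbinom(S^3, 1L, prob_flip), c(S, S, S))
  p <- abs(g - flip)   # g with a fraction of voxels toggled
  list(P = p, G = g)
}

## angle in degrees between two axes (antipodally symmetric)
axis_angle_deg <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  acos(min(1, abs(sum(u * v)))) * 180 / pi
}

## small crossing phantom reused by several tests (memoised per session)
.test_env <- new.env()
get_crossing_phantom <- function(side = 16L, seed = 21L, noise = 0.02) {
  key <- sprintf("cp_%d_%d_%g", side, seed, noise)
  if (is.null(.test_env[[key]]))
    .test_env[[key]] <- generate_phantom(
      phantom_spec(side = side, scenario = "crossing", seed = seed,
                   noise_sigma = noise, radius = 2))
  .test_env[[key]]
}
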