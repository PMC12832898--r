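test_that("coefficient count follows (lmax+1)(lmax+2)/2 for even orders", {
  ## independent enumeration of (l, m) pairs
  enumerate <- function(lmax) {
    n <- 0L
    for (l in seq(0L, lmax, by = 2L)) n <- n + 2L * l + 1L
    n
  }
  expect_identical(count_coefficients(0L), 1L)
  expect_identical(count_coefficients(4L), enumerate(4L))
  expect_identical(count_coefficients(4L), 15L)
  expect_identical(count_coefficients(8L), 45L)
  expect_error(count_coefficients(7), "even")
  expect_error(count_coefficients(-2), "even")
})

test_that("basis matrix has the right shape, Y00 value and antipodal symmetry", {
  spec <- sh_basis_spec(8L)
  set.seed(3)
  d <- matrix(rnorm(30), 10, 3)
  d <- d / sqrt(rowSums(d^2))
  B <- sh_basis_matrix(d, spec)
  expect_identical(dim(B), c(10L, 45L))
  expect_equal(B[, 1L], rep(1 / (2 * sqrt(pi)), 10), tolerance = 1e-12)
  Banti <- sh_basis_matrix(-d, spec)
  expect_equal(B, Banti, tolerance = 1e-12)
})

test_that("basis is orthonormal under exact sphere quadrature", {
  g <- gauss_sphere_grid(40L, 105L)  # 4200 points
  expect_gte(nrow(g$directions), 4000L)
  B <- sh_basis_matrix(g, sh_basis_spec(8L))
  G <- crossprod(B, B * g$weights)
  expect_lt(max(abs(G - diag(45L))), 1e-6)
})

test_that("projection recovers band-limited functions and constants", {
  spec <- sh_basis_spec(8L)
  grid <- fibonacci_hemisphere(724L)
  ## constant c on the sphere -> only the order-0 coefficient, 2c*sqrt(pi)
  co <- project_to_sh(rep(2.5, 724), spec, grid)
  expect_equal(co[1L], 2.5 * 2 * sqrt(pi), tolerance = 1e-10)
  expect_lt(max(abs(co[-1L])), 1e-10)
  ## round trip on random band-limited input
  set.seed(11)
  for (rep in 1:3) {
    c0 <- rnorm(45)
    vals <- evaluate_sh(c0, grid$directions, spec)
    expect_lt(max(abs(project_to_sh(vals, spec, grid) - c0)), 1e-8)
  }
  ## too few samples for the basis
  expect_error(project_to_sh(rep(1, 10), spec, fibonacci_hemisphere(10L)),
               "at least")
})

test_that("truncation residual of a sharp lobe decreases with order", {
  grid <- fibonacci_hemisphere(724L)
  f <- exp(20 * grid$directions[, 3L]^2)
  resid <- vapply(c(0L, 4L, 8L), function(lmax) {
    spec <- sh_basis_spec(lmax)
    co <- project_to_sh(f, spec, grid)
    sqrt(mean((evaluate_sh(co, grid$directions, spec) - f)^2))
  }, numeric(1L))
  expect_true(resid[2L] < resid[1L])
  expect_true(resid[3L] < resid[2L])
})

test_that("evaluation is linear, symmetric and validates input length", {
  spec <- sh_basis_spec(4L)
  d <- fibonacci_hemisphere(64L)$directions
  expect_equal(evaluate_sh(numeric(15L), d, spec), rep(0, 64))
  co <- c(2 * sqrt(pi), rep(0, 14))
  expect_equal(evaluate_sh(co, d, spec), rep(1, 64), tolerance = 1e-12)
  expect_error(evaluate_sh(numeric(10L), d, spec), "match")
})

test_that("peaks recover generator directions and respect thresholding", {
  spec <- sh_basis_spec(8L)
  lobe <- make_single_fiber_lobe(c(0, 0, 1), 20, spec)
  pk <- extract_peaks(lobe)
  expect_identical(nrow(pk$directions), 1L)
  expect_lt(axis_angle_deg(pk$directions[1L, ], c(0, 0, 1)), 2)
  ## two equal lobes 90 degrees apart
  cross <- 0.5 * make_single_fiber_lobe(c(1, 0, 0), 20, spec) +
    0.5 * make_single_fiber_lobe(c(0, 1, 0), 20, spec)
  pk2 <- extract_peaks(cross)
  expect_gte(nrow(pk2$directions), 2L)
  ang <- axis_angle_deg(pk2$directions[1L, ], pk2$directions[2L, ])
  expect_lt(abs(ang - 90), 2)
  ## amplitudes sorted non-increasing
  expect_true(all(diff(pk2$amplitudes) <= 0))
  ## isotropic profile has no strict local maxima
  iso <- c(2 * sqrt(pi), rep(0, 44))
  expect_identical(length(extract_peaks(iso)$amplitudes), 0L)
  ## non-positive fODF -> empty set, not an error
  expect_identical(length(extract_peaks(-iso)$amplitudes), 0L)
  expect_error(extract_peaks(lobe, rel_threshold = 1), "rel_threshold")
})

test_that("peak image has 3K channels with amplitude-scaled directions", {
  spec <- sh_basis_spec(8L)
  vol <- array(0, c(3, 2, 2, 45))
  lobe <- make_single_fiber_lobe(c(0, 0, 1), 25, spec)
  vol[1, 1, 1, ] <- lobe
  vol[2, 1, 1, ] <- c(2 * sqrt(pi), rep(0, 44))   # isotropic
  img <- fodf_to_peak_image(vol, K = 3L)
  expect_identical(dim(img), c(3L, 2L, 2L, 9L))
  ## single-lobe voxel: first three channels = amplitude * axis, rest 0
  pk <- extract_peaks(lobe, refine = FALSE)
  expect_equal(as.numeric(img[1, 1, 1, 1:3]),
               as.numeric(pk$directions[1L, ] * pk$amplitudes[1L]),
               tolerance = 1e-8)
  expect_equal(as.numeric(img[1, 1, 1, 4:9]), rep(0, 6))
  ## isotropic voxel: all zero
  expect_equal(as.numeric(img[2, 1, 1, ]), rep(0, 9))
})
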