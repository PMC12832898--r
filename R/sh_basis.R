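#' Real even-order spherical-harmonic basis specification
#'
#' Antipodally symmetric spherical functions (such as fiber orientation
#' distributions) are represented in the real, orthonormal, symmetric
#' spherical-harmonic (SH) basis: even orders \eqn{l = 0, 2, \dots, l_{max}}
#' only, with the flat coefficient ordering \eqn{j(l,m) = l(l+1)/2 + m},
#' \eqn{m \in [-l, l]}.  This is the ordering used by MRtrix-style fODF
#' files, so 45-channel volumes (\eqn{l_{max} = 8}) read from disk are
#' interpreted consistently.
#'
#' @param lmax Maximum (even, non-negative) spherical-harmonic order.
#' @return An object of class `sh_basis_spec` with fields `lmax`,
#'   `n_coeffs`, `ordering` and `convention`.
#' @examples
#' sh_basis_spec(8)$n_coeffs  # 45
#' @export
sh_basis_spec <- function(lmax = 8L) {
  lmax <- as.integer(lmax)
  structure(list(
    lmax = lmax,
    n_coeffs = count_coefficients(lmax),
    ordering = "j(l,m) = l(l+1)/2 + m, even l",
    convention = "orthonormal real symmetric SH"
  ), class = "sh_basis_spec")
}

#' Number of real even-order SH coefficients up to a maximum order
#'
#' For a symmetric function on the sphere expanded in real spherical
#' harmonics of even order up to `lmax`, the number of coefficients is
#' \eqn{(l_{max}+1)(l_{max}+2)/2}; at `lmax = 8` this gives the 45
#' coefficients per voxel of a standard fODF volume.
#'
#' @param lmax Even, non-negative integer order.
#' @return Integer coefficient count.
#' @examples
#' count_coefficients(8)  # 45
#' @export
count_coefficients <- function(lmax) {
  if (length(lmax) != 1L || !is.finite(lmax) || lmax < 0 || lmax %% 2 != 0)
    stop("'lmax' must be a single even non-negative integer", call. = FALSE)
  lmax <- as.integer(lmax)
  as.integer((lmax + 1L) * (lmax + 2L) / 2L)
}

## (l, m) pairs in flat-index order for even l <= lmax
sh_index_table <- function(lmax) {
  l <- unlist(lapply(seq(0L, lmax, by = 2L), function(li) rep(li, 2L * li + 1L)))
  m <- unlist(lapply(seq(0L, lmax, by = 2L), function(li) seq(-li, li)))
  data.frame(j = l * (l + 1L) / 2L + m, l = l, m = m)
}

#' Spherical sampling grid
#'
#' A set of unit directions, optionally with quadrature weights.  Because
#' the functions represented are antipodally symmetric, hemisphere sampling
#' (no antipodal duplicates) is permitted.
#'
#' @param directions Numeric N x 3 matrix of unit vectors.
#' @param weights Optional quadrature weights (length N, summing to the
#'   measure of the sampled domain).
#' @return An object of class `sphere_grid`.
#' @export
sphere_grid <- function(directions, weights = NULL) {
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L) stop("'directions' must be an N x 3 matrix", call. = FALSE)
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-10))
    stop("all directions must have unit norm (tolerance 1e-10)", call. = FALSE)
  if (!is.null(weights) && length(weights) != nrow(directions))
    stop("'weights' length must match number of directions", call. = FALSE)
  structure(list(directions = directions, weights = weights), class = "sphere_grid")
}

#' Fibonacci hemisphere grid
#'
#' Deterministic, near-uniform hemisphere sampling used as the default
#' design for least-squares SH projection and for peak finding.  Points
#' follow the spherical Fibonacci spiral restricted to z > 0.
#'
#' @param n Number of directions (default 724).
#' @return A `sphere_grid` without weights.
#' @export
fibonacci_hemisphere <- function(n = 724L) {
  n <- as.integer(n)
  if (n < 1L) stop("'n' must be positive", call. = FALSE)
  k <- seq_len(n) - 0.5
  z <- k / n                       # z in (0, 1): upper hemisphere
  phi <- 2 * pi * k * (sqrt(5) - 1) / 2
  s <- sqrt(pmax(0, 1 - z^2))
  d <- cbind(s * cos(phi), s * sin(phi), z)
  d <- d / sqrt(rowSums(d^2))
  sphere_grid(d)
}

#' Gauss-Legendre product quadrature grid on the sphere
#'
#' Product of Gauss-Legendre nodes in \eqn{\cos\theta} and uniform nodes in
#' \eqn{\phi}, with weights summing to \eqn{4\pi}.  Integrates spherical
#' polynomials exactly up to degree \eqn{\min(2 n_\theta - 1, n_\phi - 1)},
#' so it serves as an exact-orthonormality oracle for band-limited bases.
#'
#' @param n_theta Number of Gauss-Legendre nodes in \eqn{\cos\theta}.
#' @param n_phi Number of uniform azimuthal nodes.
#' @return A `sphere_grid` with quadrature weights.
#' @export
gauss_sphere_grid <- function(n_theta = 40L, n_phi = 100L) {
  gl <- pracma::gaussLegendre(as.integer(n_theta), -1, 1)
  phi <- 2 * pi * (seq_len(n_phi) - 1L) / n_phi
  ct <- rep(gl$x, times = n_phi)
  ph <- rep(phi, each = n_theta)
  st <- sqrt(pmax(0, 1 - ct^2))
  d <- cbind(st * cos(ph), st * sin(ph), ct)
  d <- d / sqrt(rowSums(d^2))
  w <- rep(gl$w, times = n_phi) * (2 * pi / n_phi)
  sphere_grid(d, weights = w)
}

#' Evaluate the real symmetric SH basis on a set of directions
#'
#' Entry (i, j) is basis function j (flat ordering \eqn{j = l(l+1)/2 + m},
#' even l only) evaluated at direction i.  Only even orders appear, so the
#' row for a direction and its antipode are identical.
#'
#' The convention is: \eqn{m = 0} gives the zonal harmonic
#' \eqn{N_{l0} P_l^0(\cos\theta)}; \eqn{m > 0} gives
#' \eqn{\sqrt{2} N_{lm} P_l^m(\cos\theta)\cos(m\phi)}; \eqn{m < 0} gives
#' \eqn{\sqrt{2} N_{l|m|} P_l^{|m|}(\cos\theta)\sin(|m|\phi)}, with
#' \eqn{N_{lm} = \sqrt{(2l+1)/(4\pi)\,(l-m)!/(l+m)!}} and associated
#' Legendre functions carrying the Condon-Shortley phase.
#'
#' @param grid A `sphere_grid` or an N x 3 matrix of unit directions.
#' @param spec An `sh_basis_spec`.
#' @return Numeric N x n_coeffs matrix.
#' @export
sh_basis_matrix <- function(grid, spec = sh_basis_spec(8L)) {
  dirs <- if (inherits(grid, "sphere_grid")) grid$directions else as.matrix(grid)
  if (is.null(dim(dirs))) dirs <- matrix(dirs, ncol = 3L)
  if (nrow(dirs) == 0L) stop("grid must be non-empty", call. = FALSE)
  ct <- pmin(1, pmax(-1, dirs[, 3L]))
  phi <- atan2(dirs[, 2L], dirs[, 1L])
  n <- nrow(dirs)
  B <- matrix(0, n, spec$n_coeffs)
  for (l in seq(0L, spec$lmax, by = 2L)) {
    if (l == 0L) {
      B[, 1L] <- 1 / (2 * sqrt(pi))
      next
    }
    P <- pracma::legendre(l, ct)          # (l+1) x n, rows m = 0..l, CS phase
    if (is.null(dim(P))) P <- matrix(P, ncol = 1L)
    j0 <- l * (l + 1L) / 2L               # flat index of (l, 0)
    for (m in 0:l) {
      Nlm <- sqrt((2 * l + 1) / (4 * pi) *
                    exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
      if (m == 0L) {
        B[, j0 + 1L] <- Nlm * P[1L, ]
      } else {
        B[, j0 + m + 1L] <- sqrt(2) * Nlm * P[m + 1L, ] * cos(m * phi)
        B[, j0 - m + 1L] <- sqrt(2) * Nlm * P[m + 1L, ] * sin(m * phi)
      }
    }
  }
  B
}

#' Project sampled spherical function values onto the SH basis
#'
#' Weighted least squares when the grid carries quadrature weights,
#' ordinary least squares otherwise.  Recovers band-limited functions
#' exactly (up to numerical precision) whenever the basis matrix has full
#' column rank on the grid.
#'
#' @param samples Numeric vector of function values on the grid (or an
#'   N x K matrix: one column per function).
#' @param spec An `sh_basis_spec`.
#' @param grid A `sphere_grid` with at least `n_coeffs` directions.
#' @return Coefficient vector of length `n_coeffs` (or n_coeffs x K matrix).
#' @export
project_to_sh <- function(samples, spec = sh_basis_spec(8L),
                          grid = fibonacci_hemisphere()) {
  B <- sh_basis_matrix(grid, spec)
  samples <- if (is.matrix(samples)) samples else matrix(samples, ncol = 1L)
  if (nrow(samples) != nrow(B))
    stop("'samples' must have one value per grid direction", call. = FALSE)
  if (nrow(B) < ncol(B))
    stop("grid must have at least n_coeffs directions", call. = FALSE)
  w <- if (inherits(grid, "sphere_grid")) grid$weights else NULL
  if (!is.null(w)) {
    sw <- sqrt(w)
    B <- B * sw
    samples <- samples * sw
  }
  qrB <- qr(B)
  if (qrB$rank < ncol(B))
    stop("basis matrix is rank-deficient on this grid", call. = FALSE)
  co <- qr.coef(qrB, samples)
  if (ncol(co) == 1L) drop(co) else co
}

#' Evaluate an SH coefficient vector at arbitrary directions
#'
#' The adjoint of [project_to_sh()]: linear in the coefficients, and equal
#' at antipodal direction pairs because only even orders are present.
#'
#' @param coeffs Coefficient vector of length `n_coeffs` (or a matrix
#'   n_coeffs x K for several functions).
#' @param directions N x 3 matrix of unit directions (or `sphere_grid`).
#' @param spec An `sh_basis_spec`; inferred from `length(coeffs)` if `NULL`.
#' @return Numeric vector of length N (or N x K matrix).
#' @export
evaluate_sh <- function(coeffs, directions, spec = NULL) {
  nc <- if (is.matrix(coeffs)) nrow(coeffs) else length(coeffs)
  if (is.null(spec)) spec <- sh_basis_spec(lmax_from_ncoeffs(nc))
  if (nc != spec$n_coeffs)
    stop(sprintf("coefficient length %d does not match n_coeffs %d",
                 nc, spec$n_coeffs), call. = FALSE)
  B <- sh_basis_matrix(directions, spec)
  out <- B %*% (if (is.matrix(coeffs)) coeffs else matrix(coeffs, ncol = 1L))
  if (ncol(out) == 1L) drop(out) else out
}

## invert n = (l+1)(l+2)/2 for even l
lmax_from_ncoeffs <- function(n) {
  l <- (-3 + sqrt(1 + 8 * n)) / 2
  li <- as.integer(round(l))
  if (li < 0 || li %% 2L != 0L || count_coefficients(li) != n)
    stop(sprintf("%d is not a valid even-order SH coefficient count", n),
         call. = FALSE)
  li
}
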