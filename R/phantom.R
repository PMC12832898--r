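## Synthetic fODF phantom generator: tube-shaped "tracts" with Watson-lobe
## fODFs, reproducing the two geometries that make voxel-wise tract
## segmentation hard — crossings (several differently oriented populations
## in one voxel) and bottlenecks (distinct tracts merged along one shared
## orientation before diverging).

#' Single-fiber Watson lobe in SH coefficients
#'
#' SH projection of the normalized Watson kernel
#' \eqn{f(u) \propto \exp(\kappa (u\cdot\mu)^2)} (unit integral over the
#' sphere).  Axially and antipodally symmetric, with its fODF maximum at
#' \eqn{\pm\mu}; at `lmax = 8` the truncation error is small for the
#' moderate concentrations used here.
#'
#' @param direction Mean axis \eqn{\mu} (any non-zero 3-vector; normalized).
#' @param kappa Watson concentration, > 0 (larger = sharper lobe).
#' @param spec `sh_basis_spec` (default order 8).
#' @param grid Projection grid (default 724-point Fibonacci hemisphere).
#' @return SH coefficient vector of length `spec$n_coeffs`.
#' @export
make_single_fiber_lobe <- function(direction, kappa, spec = sh_basis_spec(8L),
                                   grid = fibonacci_hemisphere()) {
  if (kappa <= 0) stop("'kappa' must be positive", call. = FALSE)
  mu <- direction / sqrt(sum(direction^2))
  t2 <- drop(grid$directions %*% mu)^2
  z <- 2 * pi * stats::integrate(function(s) exp(kappa * s^2), -1, 1,
                                 rel.tol = 1e-10)$value
  project_to_sh(exp(kappa * t2) / z, spec, grid)
}

#' Tube-shaped tract geometry
#'
#' A tract is realized as the set of voxels within `radius` of a 3D
#' polyline; the local fiber orientation is the tangent of the nearest
#' polyline segment.
#'
#' @param name Tract name.
#' @param path n x 3 matrix of polyline points in voxel coordinates
#'   (voxel centers at 1..S); at least two points.
#' @param radius Tube radius in voxels, >= 1.
#' @param kappa Watson concentration of the tract's fiber lobe.
#' @return An object of class `tract_geometry`.
#' @export
tract_geometry <- function(name, path, radius = 3, kappa = 20) {
  path <- as.matrix(path)
  if (nrow(path) < 2L || ncol(path) != 3L)
    stop("'path' must be an n x 3 matrix with n >= 2", call. = FALSE)
  if (radius < 1) stop("'radius' must be >= 1", call. = FALSE)
  if (kappa <= 0) stop("'kappa' must be positive", call. = FALSE)
  structure(list(name = name, path = path, radius = radius, kappa = kappa),
            class = "tract_geometry")
}

#' Phantom specification
#'
#' Declarative description of a synthetic fODF dataset: volume side,
#' scenario geometry, per-coefficient Gaussian noise, isotropic background
#' level, SH order, and the seed that makes generation bit-reproducible.
#' When `tracts` is `NULL`, default geometries for the chosen scenario are
#' built: `crossing` is two orthogonal straight tubes meeting at the
#' volume center; `bottleneck` is two bent tubes whose middle segments
#' coincide along a shared corridor before diverging; `single` is one
#' straight tube.
#'
#' @param side Volume side length S (cubic grid), >= 16; the default 48 is
#'   the desk-scale size, and 144 mirrors full-resolution fODF volumes.
#' @param scenario One of "crossing", "bottleneck", "single".
#' @param tracts Optional list of [tract_geometry()] overriding the
#'   scenario defaults.
#' @param radius Tube radius used for default geometries.
#' @param kappa Watson concentration used for default geometries.
#' @param corridor_length Shared-corridor length for the bottleneck
#'   scenario (default `side / 3`).
#' @param noise_sigma Standard deviation of i.i.d. Gaussian noise added to
#'   every SH coefficient (default 0.02).
#' @param background_iso_amplitude Constant value of the isotropic
#'   background fODF added everywhere (default 0.1).
#' @param lmax SH order (default 8).
#' @param seed Integer RNG seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(side = 48L,
                         scenario = c("crossing", "bottleneck", "single"),
                         tracts = NULL, radius = 3, kappa = 20,
                         corridor_length = NULL,
                         noise_sigma = 0.02, background_iso_amplitude = 0.1,
                         lmax = 8L, seed = 1L) {
  scenario <- match.arg(scenario)
  side <- as.integer(side)
  if (side < 16L) stop("'side' must be >= 16", call. = FALSE)
  if (noise_sigma < 0) stop("'noise_sigma' must be >= 0", call. = FALSE)
  if (background_iso_amplitude < 0)
    stop("'background_iso_amplitude' must be >= 0", call. = FALSE)
  if (is.null(tracts))
    tracts <- default_tracts(side, scenario, radius, kappa, corridor_length)
  for (tr in tracts) {
    if (any(tr$path < 1 | tr$path > side))
      stop(sprintf("tract '%s' path leaves the volume", tr$name), call. = FALSE)
  }
  structure(list(side = side, scenario = scenario, tracts = tracts,
                 noise_sigma = noise_sigma,
                 background_iso_amplitude = background_iso_amplitude,
                 lmax = as.integer(lmax), seed = as.integer(seed)),
            class = "phantom_spec")
}

default_tracts <- function(side, scenario, radius, kappa, corridor_length) {
  ce <- (side + 1) / 2
  m <- 2
  switch(scenario,
    single = list(
      tract_geometry("tube_x", rbind(c(m, ce, ce), c(side - m, ce, ce)),
                     radius, kappa)
    ),
    crossing = list(
      tract_geometry("tube_x", rbind(c(m, ce, ce), c(side - m, ce, ce)),
                     radius, kappa),
      tract_geometry("tube_y", rbind(c(ce, m, ce), c(ce, side - m, ce)),
                     radius, kappa)
    ),
    bottleneck = {
      lc <- if (is.null(corridor_length)) side / 3 else corridor_length
      x1 <- ce - lc / 2; x2 <- ce + lc / 2
      d <- min(x1 - m, side - m - x2, side / 5)
      list(
        tract_geometry("bend_a",
                       rbind(c(x1 - d, ce - d, ce), c(x1, ce, ce),
                             c(x2, ce, ce), c(x2 + d, ce + d, ce)),
                       radius, kappa),
        tract_geometry("bend_b",
                       rbind(c(x1 - d, ce + d, ce), c(x1, ce, ce),
                             c(x2, ce, ce), c(x2 + d, ce - d, ce)),
                       radius, kappa)
      )
    })
}

## distance from every voxel center to each segment of a polyline, plus
## the nearest segment index; pts is nvox x 3
polyline_distance <- function(pts, path) {
  nseg <- nrow(path) - 1L
  dmin <- rep(Inf, nrow(pts))
  seg <- rep(1L, nrow(pts))
  for (s in seq_len(nseg)) {
    a <- path[s, ]; b <- path[s + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    ap <- sweep(pts, 2L, a)
    t <- if (len2 > 0) pmin(1, pmax(0, drop(ap %*% ab) / len2)) else 0
    dx <- ap - outer(t, ab)
    d <- sqrt(rowSums(dx^2))
    upd <- d < dmin
    dmin[upd] <- d[upd]
    seg[upd] <- s
  }
  list(dist = dmin, segment = seg)
}

#' Generate a synthetic fODF phantom dataset
#'
#' For each tract, the mask is the set of voxels within the tube radius of
#' its path.  The per-voxel fODF is the volume-fraction-weighted sum of
#' the Watson lobes of every tract covering the voxel (fractions 1/k for k
#' covering tracts), oriented along the local path tangent, plus a
#' constant isotropic background; i.i.d. Gaussian noise of standard
#' deviation `noise_sigma` is then added to every coefficient under the
#' spec's seed.  In a bottleneck corridor both tracts contribute lobes
#' along the corridor axis, so the local orientation is ambiguous even
#' though the masks extend to distinct endpoints.  Identical specs give
#' bit-identical outputs.
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom_dataset`: list with `fodf` (S x S x S x n_coeffs
#'   array), `masks` (named list of S x S x S 0/1 integer arrays),
#'   `overlap` (integer array counting covering tracts per voxel), and
#'   `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  S <- spec$side
  bspec <- sh_basis_spec(spec$lmax)
  nc <- bspec$n_coeffs
  nvox <- S^3
  pts <- as.matrix(expand.grid(x = seq_len(S), y = seq_len(S), z = seq_len(S)))
  masks <- list(); covers <- list(); tangents <- list()
  for (tr in spec$tracts) {
    pd <- polyline_distance(pts, tr$path)
    inside <- pd$dist <= tr$radius
    masks[[tr$name]] <- array(as.integer(inside), c(S, S, S))
    covers[[tr$name]] <- inside
    tg <- diff(tr$path)
    tg <- tg / sqrt(rowSums(tg^2))
    tangents[[tr$name]] <- tg[pd$segment, , drop = FALSE]
  }
  ncover <- Reduce(`+`, lapply(covers, as.integer))
  frac <- ifelse(ncover > 0, 1 / ncover, 0)
  coefmat <- matrix(0, nvox, nc)
  for (tr in spec$tracts) {
    inside <- covers[[tr$name]]
    if (!any(inside)) next
    tg <- tangents[[tr$name]][inside, , drop = FALSE]
    ## one lobe per distinct orientation (few: one per path segment)
    key <- apply(round(tg, 10), 1L, paste, collapse = ",")
    for (k in unique(key)) {
      rows <- which(inside)[key == k]
      lobe <- make_single_fiber_lobe(tg[match(k, key), ], tr$kappa, bspec)
      coefmat[rows, ] <- coefmat[rows, ] +
        outer(frac[rows], lobe)
    }
  }
  ## constant isotropic background value b has SH coefficient b * 2 sqrt(pi)
  coefmat[, 1L] <- coefmat[, 1L] + spec$background_iso_amplitude * 2 * sqrt(pi)
  fodf <- array(coefmat, c(S, S, S, nc))
  if (spec$noise_sigma > 0)
    fodf <- add_noise(fodf, spec$noise_sigma, spec$seed)
  structure(list(fodf = fodf, masks = masks,
                 overlap = array(ncover, c(S, S, S)), spec = spec),
            class = "phantom_dataset")
}

#' Add Gaussian coefficient noise to an fODF volume
#'
#' i.i.d. zero-mean Gaussian noise applied to every SH coefficient — the
#' degradation knob emulating lower-quality acquisitions in the domain
#' where the model lives (coefficient space, since the pipeline consumes
#' fODFs, not raw diffusion signal).  `sigma = 0` returns the input
#' unchanged; a fixed seed gives a reproducible result.
#'
#' @param volume 4D fODF array.
#' @param sigma Noise standard deviation, >= 0.
#' @param seed Integer RNG seed.
#' @return Noisy 4D array of the same shape.
#' @export
add_noise <- function(volume, sigma, seed = 1L) {
  if (sigma < 0) stop("'sigma' must be >= 0", call. = FALSE)
  if (sigma == 0) return(volume)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  volume + array(stats::rnorm(length(volume), sd = sigma), dim(volume))
}
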