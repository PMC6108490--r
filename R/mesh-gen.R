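#' Configuration for the synthetic porous-mesh generator
#'
#' The generator emulates trabecular-like porous structure by thresholding a
#' smooth random field (a sum of random plane waves) on a voxel grid. The
#' threshold is set at the requested quantile, so the solid fraction of the
#' voxel field matches `fill_fraction` up to grid granularity, independently
#' of `complexity_scale`, which only sets the spatial frequency (strut
#' fineness) of the porosity.
#'
#' @param bbox_extent Length-3 extents of the generated block, mm.
#' @param fill_fraction Target solid fraction in `[0, 1]`.
#' @param complexity_scale Spatial frequency of the porous field, cycles/mm.
#' @param seed Integer seed (generators never touch global RNG state).
#' @param voxel_pitch Voxel edge length, mm.
#' @param n_waves Number of random plane waves summed into the field.
#' @return A `mesh_gen_config` list.
#' @export
mesh_gen_config <- function(bbox_extent = c(8, 8, 10), fill_fraction = 0.6,
                            complexity_scale = 0.6, seed = 1L,
                            voxel_pitch = 0.2, n_waves = 24L) {
  stopifnot(length(bbox_extent) == 3, all(bbox_extent > 0),
            is.numeric(fill_fraction), length(fill_fraction) == 1)
  if (fill_fraction < 0 || fill_fraction > 1)
    stop("fill_fraction must be in [0, 1]")
  if (voxel_pitch <= 0) stop("voxel_pitch must be > 0")
  stopifnot(complexity_scale > 0, n_waves >= 4)
  structure(list(bbox_extent = as.numeric(bbox_extent),
                 fill_fraction = fill_fraction,
                 complexity_scale = complexity_scale,
                 seed = as.integer(seed),
                 voxel_pitch = voxel_pitch,
                 n_waves = as.integer(n_waves)),
            class = "mesh_gen_config")
}

#' Generate a synthetic trabecular-like porous mesh
#'
#' Builds the thresholded random field described in [mesh_gen_config()],
#' checks that a connected solid exists, and extracts the closed voxel
#' boundary surface. With `fill_fraction = 1` the result is the solid block.
#'
#' @param cfg A `mesh_gen_config`.
#' @return A `trabecular_mesh` with attributes `solid_fraction` (voxel-count
#'   solid fraction of the bounding box), `occupancy` (the logical voxel
#'   field), `origin`, `pitch`, and `config`.
#' @export
generate_trabecular_mesh <- function(cfg) {
  stopifnot(inherits(cfg, "mesh_gen_config"))
  dims <- pmax(1L, as.integer(round(cfg$bbox_extent / cfg$voxel_pitch)))
  occ <- trabecular_field(cfg, dims)
  nsolid <- sum(occ)
  if (nsolid == 0L)
    stop("degenerate structure: fill_fraction too low, no solid voxels")
  lab <- label_components(occ)
  sizes <- attr(lab, "sizes")
  # disconnected dust (largest component under 1% of the grid) is not a
  # mechanically meaningful structure
  if (max(sizes) < max(2, 0.01 * prod(dims)))
    stop("degenerate structure: no connected solid exists at this ",
         "fill_fraction (largest component ", max(sizes), " of ", nsolid,
         " voxels)")
  mesh <- voxel_surface_mesh(occ, origin = c(0, 0, 0), pitch = cfg$voxel_pitch,
                             axis_dv = c(0, 0, 1))
  attr(mesh, "solid_fraction") <- nsolid / prod(dims)
  attr(mesh, "occupancy") <- occ
  attr(mesh, "origin") <- c(0, 0, 0)
  attr(mesh, "pitch") <- cfg$voxel_pitch
  attr(mesh, "config") <- cfg
  mesh
}

# threshold a smooth random plane-wave field at the fill_fraction quantile
trabecular_field <- function(cfg, dims) {
  if (cfg$fill_fraction == 1) return(array(TRUE, dim = dims))
  if (cfg$fill_fraction == 0)
    stop("degenerate structure: fill_fraction too low, no solid voxels")
  xc <- (seq_len(dims[1]) - 0.5) * cfg$voxel_pitch
  yc <- (seq_len(dims[2]) - 0.5) * cfg$voxel_pitch
  zc <- (seq_len(dims[3]) - 0.5) * cfg$voxel_pitch
  with_seed(cfg$seed, {
    K <- cfg$n_waves
    dir <- matrix(stats::rnorm(3 * K), K, 3)
    dir <- dir / sqrt(rowSums(dir^2))
    mag <- 2 * pi * cfg$complexity_scale * stats::runif(K, 0.6, 1.4)
    phase <- stats::runif(K, 0, 2 * pi)
    amp <- stats::rnorm(K)
    f <- array(0, dim = dims)
    for (k in seq_len(K)) {
      kx <- mag[k] * dir[k, 1] * xc
      ky <- mag[k] * dir[k, 2] * yc
      kz <- mag[k] * dir[k, 3] * zc
      f <- f + amp[k] * cos(outer(outer(kx, ky, "+"), kz, "+") + phase[k])
    }
    n <- length(f)
    nsolid <- max(0L, min(n, as.integer(round(cfg$fill_fraction * n))))
    if (nsolid == 0L)
      stop("degenerate structure: fill_fraction too low, no solid voxels")
    thr <- sort(as.vector(f), partial = nsolid)[nsolid]
    array(f <= thr, dim = dims)
  })
}
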