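# Virtual core sampling: cylinder definition along the dorso-ventral axis,
# voxel Boolean extraction, standardization to the 10 mm x 5 mm specimen, and
# fill-volume / surface-area morphometrics.

#' Define the core-sampling cylinder through an anchor point
#'
#' The cylinder height is the extent of the mesh along its dorso-ventral axis
#' through the anchor (the articular-surface height at the sampling site);
#' the diameter is fixed at 50% of the height, which standardizes specimen
#' shape to a 2:1 aspect.
#'
#' @param mesh A `trabecular_mesh`.
#' @param anchor Length-3 point (mm) inside the mesh bounding box.
#' @return A `core_cylinder`: `center` (axis midpoint), `axis` (unit vector),
#'   `height`, `diameter` (mm).
#' @export
define_core_cylinder <- function(mesh, anchor) {
  stopifnot(inherits(mesh, "trabecular_mesh"), length(anchor) == 3)
  bb <- apply(mesh$vertices, 2, range)
  if (any(anchor < bb[1, ] - 1e-9) || any(anchor > bb[2, ] + 1e-9))
    stop("anchor lies outside the mesh bounding box")
  hits <- line_mesh_intersections(mesh, anchor, mesh$axis_dv)
  if (length(hits) == 0)
    stop("no intersection: the dorso-ventral line through the anchor misses the mesh")
  h <- max(hits) - min(hits)
  if (h <= 0) stop("no intersection: degenerate grazing contact")
  center <- anchor + mesh$axis_dv * (max(hits) + min(hits)) / 2
  core_cylinder(center = center, axis = mesh$axis_dv,
                height = h, diameter = h / 2)
}

#' @rdname define_core_cylinder
#' @param center Axis midpoint (mm).
#' @param axis Unit axis vector.
#' @param height,diameter Cylinder dimensions (mm); `diameter` must equal
#'   `height / 2`.
#' @export
core_cylinder <- function(center, axis, height, diameter) {
  stopifnot(length(center) == 3, length(axis) == 3, height > 0)
  if (abs(diameter - height / 2) > 1e-9 * height)
    stop("core cylinder must have diameter = height / 2")
  axis <- axis / sqrt(sum(axis^2))
  structure(list(center = as.numeric(center), axis = axis,
                 height = height, diameter = diameter),
            class = "core_cylinder")
}

# signed distances t along (origin + t * dir) of all transversal triangle
# crossings (Moller-Trumbore, both directions)
line_mesh_intersections <- function(mesh, origin, dir) {
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - p1
  e2 <- v[f[, 3], , drop = FALSE] - p1
  dxe2 <- cbind(dir[2] * e2[, 3] - dir[3] * e2[, 2],
                dir[3] * e2[, 1] - dir[1] * e2[, 3],
                dir[1] * e2[, 2] - dir[2] * e2[, 1])
  det <- rowSums(e1 * dxe2)
  ok <- abs(det) > 1e-12
  tvec <- sweep(-p1, 2, origin, "+")
  u <- rowSums(tvec * dxe2) / det
  qv <- cbind(tvec[, 2] * e1[, 3] - tvec[, 3] * e1[, 2],
              tvec[, 3] * e1[, 1] - tvec[, 1] * e1[, 3],
              tvec[, 1] * e1[, 2] - tvec[, 2] * e1[, 1])
  vv <- (qv[, 1] * dir[1] + qv[, 2] * dir[2] + qv[, 3] * dir[3]) / det
  tt <- rowSums(e2 * qv) / det
  hit <- ok & u >= 0 & vv >= 0 & (u + vv) <= 1
  tt[hit]
}

#' Boolean-extract a core sample from a trabecular mesh
#'
#' Voxelizes the mesh on a grid aligned with the cylinder axis and keeps
#' voxels whose centers fall inside both the trabecular solid and the
#' cylinder — the voxel Boolean intersection. The result is returned in
#' canonical cylinder coordinates (axis along +z, centered at the origin) as
#' a closed voxel-boundary mesh, flat-capped wherever trabeculae meet the
#' cylinder surface.
#'
#' @param mesh A watertight `trabecular_mesh`.
#' @param cyl A `core_cylinder` overlapping the mesh.
#' @param voxel_pitch Grid pitch (mm); default `height / 200`.
#' @return A `core_sample`: `mesh`, `height`, `diameter`, `fill_volume`
#'   (mm^3), `surface_area` (mm^2), `scale_factor`, `standardized`,
#'   `voxel_pitch`.
#' @export
extract_core <- function(mesh, cyl, voxel_pitch = cyl$height / 200) {
  stopifnot(inherits(mesh, "trabecular_mesh"), inherits(cyl, "core_cylinder"),
            voxel_pitch > 0)
  if (!is_closed_mesh(mesh))
    stop("input mesh is not watertight; cannot core a non-closed surface")
  u <- cyl$axis
  ref <- diag(3)[, which.min(abs(u))]
  vv <- c(u[2] * ref[3] - u[3] * ref[2],
          u[3] * ref[1] - u[1] * ref[3],
          u[1] * ref[2] - u[2] * ref[1])
  vv <- vv / sqrt(sum(vv^2))
  ww <- c(u[2] * vv[3] - u[3] * vv[2],
          u[3] * vv[1] - u[1] * vv[3],
          u[1] * vv[2] - u[2] * vv[1])
  R <- cbind(vv, ww, u)  # world -> local: L = (P - center) %*% R
  r <- cyl$diameter / 2
  h <- cyl$height
  local <- list(vertices = sweep(mesh$vertices, 2, cyl$center) %*% R,
                faces = mesh$faces)
  dims <- pmax(1L, as.integer(ceiling(c(2 * r, 2 * r, h) / voxel_pitch)))
  origin <- -c(dims[1], dims[2], dims[3]) * voxel_pitch / 2
  occ <- voxelize_mesh(local, origin, dims, voxel_pitch)
  # cylinder mask on voxel centers
  xc <- origin[1] + (seq_len(dims[1]) - 0.5) * voxel_pitch
  yc <- origin[2] + (seq_len(dims[2]) - 0.5) * voxel_pitch
  zc <- origin[3] + (seq_len(dims[3]) - 0.5) * voxel_pitch
  in_r <- outer(xc^2, yc^2, "+") <= r^2
  in_z <- abs(zc) <= h / 2
  mask <- array(rep(as.vector(in_r), times = dims[3]), dim = dims)
  mask[, , !in_z] <- FALSE
  occ <- occ & mask
  if (!any(occ))
    stop("empty intersection: cylinder does not overlap the trabecular solid")
  core_mesh <- voxel_surface_mesh(occ, origin, voxel_pitch,
                                  axis_dv = c(0, 0, 1))
  mm <- mesh_volume_area(core_mesh)
  structure(list(mesh = core_mesh, height = h, diameter = cyl$diameter,
                 fill_volume = mm$volume, surface_area = mm$area,
                 scale_factor = 1, standardized = FALSE,
                 voxel_pitch = voxel_pitch),
            class = "core_sample")
}

#' Wrap an existing mesh as a core sample
#'
#' For cores built analytically (e.g. a triangulated solid cylinder) rather
#' than by Boolean extraction. Fill volume and surface area are measured from
#' the mesh.
#'
#' @param mesh A `trabecular_mesh` in canonical cylinder coordinates.
#' @param height,diameter Specimen dimensions, mm (diameter = height / 2).
#' @param voxel_pitch Pitch if voxel-derived, else `NA`.
#' @return A `core_sample`.
#' @export
core_sample <- function(mesh, height, diameter = height / 2,
                        voxel_pitch = NA_real_) {
  stopifnot(inherits(mesh, "trabecular_mesh"))
  mm <- mesh_volume_area(mesh)
  structure(list(mesh = mesh, height = height, diameter = diameter,
                 fill_volume = mm$volume, surface_area = mm$area,
                 scale_factor = 1,
                 standardized = abs(height - STD_CORE_HEIGHT) < 1e-9,
                 voxel_pitch = voxel_pitch),
            class = "core_sample")
}

is_closed_mesh <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  nv <- nrow(mesh$vertices)
  key <- pmin(e[, 1], e[, 2]) * (nv + 1) + pmax(e[, 1], e[, 2])
  # closed iff every undirected edge occurs an even number of times
  all(tabulate(match(key, unique(key))) %% 2L == 0L)
}

#' @export
print.core_sample <- function(x, ...) {
  cat(sprintf(
    "core_sample: h = %.4g mm, d = %.4g mm%s\n  fill volume %.4g mm^3, surface area %.4g mm^2 (pitch %.4g mm)\n",
    x$height, x$diameter, if (x$standardized) " (standardized)" else "",
    x$fill_volume, x$surface_area, x$voxel_pitch))
  invisible(x)
}

#' Scale a core sample to the standardized 10 mm x 5 mm specimen
#'
#' Uniform similarity scaling by `s = 10 / height`; volumes scale by `s^3`
#' and areas by `s^2`. Requires the 2:1 height:diameter aspect, which makes
#' the scaling uniform. Idempotent on already-standardized cores.
#'
#' @param core A `core_sample`.
#' @param tol Relative tolerance on the 2:1 aspect check.
#' @return The standardized `core_sample` (height 10 mm, diameter 5 mm).
#' @export
standardize_core <- function(core, tol = 1e-3) {
  stopifnot(inherits(core, "core_sample"))
  if (abs(core$diameter - core$height / 2) > tol * core$height)
    stop("core aspect ratio is not 2:1 (height ", core$height,
         ", diameter ", core$diameter, "); cannot scale uniformly")
  s <- STD_CORE_HEIGHT / core$height
  core$mesh$vertices <- core$mesh$vertices * s
  core$height <- STD_CORE_HEIGHT
  core$diameter <- STD_CORE_DIAMETER
  core$fill_volume <- core$fill_volume * s^3
  core$surface_area <- core$surface_area * s^2
  core$scale_factor <- core$scale_factor * s
  core$voxel_pitch <- core$voxel_pitch * s
  core$standardized <- TRUE
  core
}

#' Measure fill volume and structural complexity of a standardized core
#'
#' Fill volume is the signed-tetrahedron enclosed volume; structural
#' complexity is the total surface area (including the flat cut faces and
#' caps where trabeculae meet the cylinder surface — the headline value). An
#' estimate excluding those cut faces is returned as `surface_area_internal`.
#' Meshes with inverted (inward) orientation are flipped with a warning.
#'
#' @param core A standardized `core_sample`.
#' @return List with `fill_volume` (mm^3), `surface_area` (mm^2), and
#'   `surface_area_internal` (mm^2).
#' @export
measure_morphometrics <- function(core) {
  stopifnot(inherits(core, "core_sample"))
  m <- mesh_volume_area(core$mesh)
  if (m$volume < 0) {
    warning("mesh orientation inverted (negative signed volume); flipping faces")
    core$mesh$faces <- core$mesh$faces[, c(1, 3, 2)]
    m <- mesh_volume_area(core$mesh)
  }
  if (m$volume <= 0) stop("core mesh has non-positive enclosed volume")
  vmax <- pi * (core$diameter / 2)^2 * core$height
  # voxel staircase can overshoot the smooth envelope by O(pitch/r)
  slack <- if (is.finite(core$voxel_pitch))
    2 * core$voxel_pitch / (core$diameter / 2) else 1e-6
  if (m$volume > vmax * (1 + slack))
    warning("measured volume exceeds the cylinder envelope; check extraction")
  list(fill_volume = m$volume,
       surface_area = m$area,
       surface_area_internal = m$area - cut_face_area(core))
}

# approximate area of triangles lying on the cylinder envelope (lateral
# staircase band within one pitch of the radius, and the two end planes)
cut_face_area <- function(core) {
  v <- core$mesh$vertices
  f <- core$mesh$faces
  cen <- (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
            v[f[, 3], , drop = FALSE]) / 3
  r <- core$diameter / 2
  p <- core$voxel_pitch
  if (!is.finite(p)) p <- 1e-6 * core$height  # analytic core: no voxel band
  on_cut <- sqrt(cen[, 1]^2 + cen[, 2]^2) > r - p |
    abs(cen[, 3]) > core$height / 2 - p / 2
  if (!any(on_cut)) return(0)
  sub <- list(vertices = v, faces = f[on_cut, , drop = FALSE])
  mesh_volume_area(sub)$area
}
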