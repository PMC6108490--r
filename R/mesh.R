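#' Triangle-mesh container for trabecular bone structure
#'
#' A `trabecular_mesh` is a closed triangle mesh in millimetre coordinates,
#' with an attached dorso-ventral unit vector (`axis_dv`) giving the loading
#' direction along which core samples are taken.
#'
#' @param vertices Numeric matrix, n x 3, vertex coordinates in mm.
#' @param faces Integer matrix, m x 3, 1-based vertex indices per triangle,
#'   wound so triangle normals point outward.
#' @param axis_dv Length-3 unit vector, dorso-ventral direction
#'   (default `c(0, 0, 1)`).
#' @param validate Check watertightness, degenerate faces, and enclosed
#'   volume (default TRUE). Skipping is only sensible for meshes built by
#'   trusted internal constructors.
#' @return An object of class `trabecular_mesh` with elements `vertices`,
#'   `faces`, `axis_dv`.
#' @export
trabecular_mesh <- function(vertices, faces, axis_dv = c(0, 0, 1),
                            validate = TRUE) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face indices out of range")
  axis_dv <- as.numeric(axis_dv)
  stopifnot(length(axis_dv) == 3)
  nrm <- sqrt(sum(axis_dv^2))
  if (nrm < .Machine$double.eps) stop("axis_dv must be a non-zero vector")
  axis_dv <- axis_dv / nrm
  m <- structure(list(vertices = vertices, faces = faces, axis_dv = axis_dv),
                 class = "trabecular_mesh")
  if (validate) assert_watertight(m)
  m
}

#' @export
print.trabecular_mesh <- function(x, ...) {
  cat(sprintf("trabecular_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bbox [%.3g, %.3g] x [%.3g, %.3g] x [%.3g, %.3g] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

# Every edge must be shared by exactly two faces and no triangle degenerate.
assert_watertight <- function(mesh) {
  f <- mesh$faces
  if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
    stop("mesh has degenerate triangles (repeated vertex in a face)")
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  if (any(cnt != 2L))
    stop("mesh is not watertight: ", sum(cnt != 2L),
         " edges not shared by exactly 2 faces")
  invisible(TRUE)
}

is_watertight <- function(mesh) {
  ok <- TRUE
  tryCatch(assert_watertight(mesh), error = function(e) ok <<- FALSE)
  ok
}

#' Signed enclosed volume and total surface area of a triangle mesh
#'
#' Volume is the signed tetrahedron sum \eqn{\sum v_1 \cdot (v_2 \times
#' v_3)/6} over faces; positive for outward-wound closed meshes. Surface area
#' is the sum of triangle areas.
#'
#' @param mesh A `trabecular_mesh` or any list with `vertices` and `faces`.
#' @return Named list `volume` (mm^3, signed) and `area` (mm^2).
#' @export
mesh_volume_area <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  cx <- p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]
  cy <- p2[, 3] * p3[, 1] - p2[, 1] * p3[, 3]
  cz <- p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1]
  vol <- sum(p1[, 1] * cx + p1[, 2] * cy + p1[, 3] * cz) / 6
  e1 <- p2 - p1
  e2 <- p3 - p1
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  area <- sum(sqrt(nx^2 + ny^2 + nz^2)) / 2
  list(volume = vol, area = area)
}

#' Axis-aligned block mesh
#'
#' @param extent Length-3 vector of edge lengths (mm).
#' @param origin Length-3 minimum corner (default the origin).
#' @inheritParams trabecular_mesh
#' @return A `trabecular_mesh` of the solid box (12 triangles).
#' @export
mesh_block <- function(extent, origin = c(0, 0, 0), axis_dv = c(0, 0, 1)) {
  stopifnot(length(extent) == 3, all(extent > 0))
  x <- c(origin[1], origin[1] + extent[1])
  y <- c(origin[2], origin[2] + extent[2])
  z <- c(origin[3], origin[3] + extent[3])
  v <- as.matrix(expand.grid(x = x, y = y, z = z))
  # corner order from expand.grid: index = 1 + ix + 2*iy + 4*iz (ix,iy,iz in 0:1)
  idx <- function(ix, iy, iz) 1L + ix + 2L * iy + 4L * iz
  quads <- rbind(
    c(idx(1, 0, 0), idx(1, 1, 0), idx(1, 1, 1), idx(1, 0, 1)), # +x
    c(idx(0, 0, 0), idx(0, 0, 1), idx(0, 1, 1), idx(0, 1, 0)), # -x
    c(idx(0, 1, 0), idx(0, 1, 1), idx(1, 1, 1), idx(1, 1, 0)), # +y
    c(idx(0, 0, 0), idx(1, 0, 0), idx(1, 0, 1), idx(0, 0, 1)), # -y
    c(idx(0, 0, 1), idx(1, 0, 1), idx(1, 1, 1), idx(0, 1, 1)), # +z
    c(idx(0, 0, 0), idx(0, 1, 0), idx(1, 1, 0), idx(1, 0, 0))  # -z
  )
  f <- rbind(quads[, c(1, 2, 3)], quads[, c(1, 3, 4)])
  trabecular_mesh(v, f, axis_dv = axis_dv)
}

#' Triangulated solid cylinder mesh
#'
#' Closed cylinder with axis along +z, centered at the origin, caps
#' triangulated as fans around central vertices. With `n_seg = 96` segments
#' the polygonal volume and area are within 0.1% of the analytic values.
#'
#' @param height Height (mm).
#' @param diameter Diameter (mm).
#' @param n_seg Number of circumferential segments.
#' @return A `trabecular_mesh`.
#' @export
mesh_cylinder <- function(height, diameter, n_seg = 96) {
  stopifnot(height > 0, diameter > 0, n_seg >= 8)
  r <- diameter / 2
  th <- 2 * pi * (seq_len(n_seg) - 1) / n_seg
  ring <- cbind(r * cos(th), r * sin(th))
  zb <- -height / 2
  zt <- height / 2
  v <- rbind(cbind(ring, zb), cbind(ring, zt),
             c(0, 0, zb), c(0, 0, zt))
  bot <- seq_len(n_seg)
  top <- n_seg + seq_len(n_seg)
  cb <- 2L * n_seg + 1L
  ct <- 2L * n_seg + 2L
  nxt <- c(seq_len(n_seg - 1) + 1L, 1L)
  side <- rbind(cbind(bot, bot[nxt], top[nxt]),
                cbind(bot, top[nxt], top))
  caps <- rbind(cbind(cb, bot[nxt], bot),       # bottom cap, outward -z
                cbind(ct, top, top[nxt]))       # top cap, outward +z
  trabecular_mesh(v, rbind(side, caps))
}

#' Latitude-longitude sphere mesh
#'
#' Poles are exact mesh vertices, so the extent along any axis through the
#' center equals the diameter exactly.
#'
#' @param radius Radius (mm).
#' @param center Length-3 center (default origin).
#' @param n_lat,n_lon Latitude bands / longitude segments.
#' @return A `trabecular_mesh`.
#' @export
mesh_sphere <- function(radius, center = c(0, 0, 0), n_lat = 24, n_lon = 48) {
  stopifnot(radius > 0, n_lat >= 4, n_lon >= 6)
  phi <- pi * seq_len(n_lat - 1) / n_lat          # interior latitudes
  th <- 2 * pi * (seq_len(n_lon) - 1) / n_lon
  rings <- do.call(rbind, lapply(phi, function(p) {
    cbind(radius * sin(p) * cos(th),
          radius * sin(p) * sin(th),
          radius * cos(p))
  }))
  v <- rbind(c(0, 0, radius), rings, c(0, 0, -radius))
  v <- sweep(v, 2, center, "+")
  np <- 1L
  sp <- nrow(v)
  ring_idx <- function(i) 1L + (i - 1L) * n_lon + seq_len(n_lon)
  nxt <- c(seq_len(n_lon - 1) + 1L, 1L)
  f <- cbind(np, ring_idx(1L), ring_idx(1L)[nxt])  # north fan
  for (i in seq_len(n_lat - 2)) {
    a <- ring_idx(i); b <- ring_idx(i + 1L)
    f <- rbind(f, cbind(a, b, b[nxt]), cbind(a, b[nxt], a[nxt]))
  }
  last <- ring_idx(n_lat - 1L)
  f <- rbind(f, cbind(sp, last[nxt], last))        # south fan
  trabecular_mesh(v, f)
}

#' Midpoint-subdivide every triangle into four
#'
#' Refinement leaves enclosed volume and surface area unchanged (the surface
#' itself is unchanged); used to verify measurement consistency.
#'
#' @param mesh A `trabecular_mesh`.
#' @return A refined `trabecular_mesh` with 4x the faces.
#' @export
mesh_subdivide <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  ek <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  keys <- ek(edges[, 1], edges[, 2])
  uk <- unique(keys)
  mididx <- match(keys, uk) + nrow(v)
  ue <- edges[!duplicated(keys), , drop = FALSE]
  mids <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
  nf <- nrow(f)
  m12 <- mididx[seq_len(nf)]
  m23 <- mididx[nf + seq_len(nf)]
  m31 <- mididx[2L * nf + seq_len(nf)]
  f2 <- rbind(cbind(f[, 1], m12, m31),
              cbind(m12, f[, 2], m23),
              cbind(m31, m23, f[, 3]),
              cbind(m12, m23, m31))
  trabecular_mesh(rbind(v, mids), f2, axis_dv = mesh$axis_dv)
}
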