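# Voxel machinery behind the Boolean core extraction and the porous-mesh
# generator. Occupancy arrays hold TRUE at voxel centers inside the solid;
# voxel (i,j,k) spans [origin + (ijk-1)*pitch, origin + ijk*pitch].

#' Voxelize a closed triangle mesh by parity ray casting
#'
#' Casts a +z ray through every (x, y) voxel-column center, collects
#' transversal surface crossings, and fills by parity. Column centers carry a
#' sub-voxel offset so rays never graze vertices or axis-aligned edges.
#'
#' @param mesh List with `vertices` (n x 3) and `faces` (m x 3).
#' @param origin Length-3 minimum corner of the grid (same units as mesh).
#' @param dims Length-3 integer voxel counts.
#' @param pitch Voxel edge length.
#' @return Logical array of dimension `dims`.
#' @export
voxelize_mesh <- function(mesh, origin, dims, pitch) {
  stopifnot(pitch > 0, length(dims) == 3, all(dims >= 1))
  dims <- as.integer(dims)
  eps <- pitch * 1e-6
  xc <- origin[1] + (seq_len(dims[1]) - 0.5) * pitch + eps
  yc <- origin[2] + (seq_len(dims[2]) - 0.5) * pitch + eps * 1.37
  zc <- origin[3] + (seq_len(dims[3]) - 0.5) * pitch
  v <- mesh$vertices
  f <- mesh$faces
  col_id <- integer(0)
  col_z <- numeric(0)
  acc_id <- vector("list", nrow(f))
  acc_z <- vector("list", nrow(f))
  for (t in seq_len(nrow(f))) {
    p1 <- v[f[t, 1], ]; p2 <- v[f[t, 2], ]; p3 <- v[f[t, 3], ]
    xr <- range(p1[1], p2[1], p3[1])
    yr <- range(p1[2], p2[2], p3[2])
    i0 <- max(1L, ceiling((xr[1] - origin[1]) / pitch - 0.5))
    i1 <- min(dims[1], floor((xr[2] - origin[1]) / pitch + 0.5))
    j0 <- max(1L, ceiling((yr[1] - origin[2]) / pitch - 0.5))
    j1 <- min(dims[2], floor((yr[2] - origin[2]) / pitch + 0.5))
    if (i0 > i1 || j0 > j1) next
    px <- xc[i0:i1]
    py <- yc[j0:j1]
    gx <- rep(px, times = length(py))
    gy <- rep(py, each = length(px))
    inside <- rep(FALSE, length(gx))
    tx <- c(p1[1], p2[1], p3[1]); ty <- c(p1[2], p2[2], p3[2])
    jprev <- 3L
    for (e in 1:3) {
      yi <- ty[e]; yj <- ty[jprev]; xi <- tx[e]; xj <- tx[jprev]
      cond <- ((yi > gy) != (yj > gy))
      if (any(cond)) {
        xcrit <- (xj - xi) * (gy[cond] - yi) / (yj - yi) + xi
        hit <- gx[cond] < xcrit
        idx <- which(cond)[hit]
        inside[idx] <- !inside[idx]
      }
      jprev <- e
    }
    if (!any(inside)) next
    # plane z at the covered column centers
    e1 <- p2 - p1; e2 <- p3 - p1
    nz <- e1[1] * e2[2] - e1[2] * e2[1]
    if (abs(nz) < .Machine$double.eps) next  # vertical triangle: no transversal crossing
    nx <- e1[2] * e2[3] - e1[3] * e2[2]
    ny <- e1[3] * e2[1] - e1[1] * e2[3]
    zc_hit <- p1[3] - (nx * (gx[inside] - p1[1]) + ny * (gy[inside] - p1[2])) / nz
    ii <- (i0:i1)[(which(inside) - 1L) %% length(px) + 1L]
    jj <- (j0:j1)[(which(inside) - 1L) %/% length(px) + 1L]
    acc_id[[t]] <- ii + dims[1] * (jj - 1L)
    acc_z[[t]] <- zc_hit
  }
  col_id <- unlist(acc_id, use.names = FALSE)
  col_z <- unlist(acc_z, use.names = FALSE)
  occ <- array(FALSE, dim = dims)
  if (length(col_id) == 0) return(occ)
  sp <- split(col_z, col_id)
  cols <- as.integer(names(sp))
  for (q in seq_along(sp)) {
    zs <- sort(sp[[q]])
    ins <- findInterval(zc, zs) %% 2L == 1L
    if (any(ins)) {
      cid <- cols[q] - 1L
      i <- cid %% dims[1] + 1L
      j <- cid %/% dims[1] + 1L
      occ[i, j, ins] <- TRUE
    }
  }
  occ
}

# logical shift of a 3D array by one voxel along axis (+1/-1), FALSE padded
shift_occ <- function(occ, axis, dir) {
  d <- dim(occ)
  out <- array(FALSE, dim = d)
  src <- dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  n <- d[axis]
  if (n == 1L && dir != 0L) return(out)
  if (dir > 0) { src[[axis]] <- 1:(n - 1); dst[[axis]] <- 2:n }
  else { src[[axis]] <- 2:n; dst[[axis]] <- 1:(n - 1) }
  out[dst[[1]], dst[[2]], dst[[3]]] <- occ[src[[1]], src[[2]], src[[3]]]
  out
}

#' Extract the boundary surface of a voxel solid as a triangle mesh
#'
#' Emits two outward-wound triangles for every voxel face adjacent to empty
#' space. The signed-tetrahedron volume of the result equals
#' `sum(occ) * pitch^3` exactly, and the area is the exposed voxel-face area.
#'
#' @param occ Logical occupancy array.
#' @param origin Length-3 minimum corner of the grid.
#' @param pitch Voxel edge length.
#' @param axis_dv Dorso-ventral axis attached to the mesh.
#' @return A `trabecular_mesh` (validation skipped; voxel surfaces are closed
#'   by construction but may contain non-manifold diagonal contacts).
#' @export
voxel_surface_mesh <- function(occ, origin, pitch, axis_dv = c(0, 0, 1)) {
  d <- dim(occ)
  if (!any(occ)) stop("empty voxel set: no surface to extract")
  corner <- function(ix, iy, iz) cbind(ix, iy, iz)  # corner-grid indices 0..d
  quads <- list()
  add_quads <- function(ijk, a, b, cc, dd) {
    quads[[length(quads) + 1L]] <<- list(a = a, b = b, c = cc, d = dd)
  }
  for (side in list(list(ax = 1L, dir = +1L), list(ax = 1L, dir = -1L),
                    list(ax = 2L, dir = +1L), list(ax = 2L, dir = -1L),
                    list(ax = 3L, dir = +1L), list(ax = 3L, dir = -1L))) {
    nb <- shift_occ(occ, side$ax, -side$dir)  # neighbor in +dir sits at shift by -dir
    face <- occ & !nb
    if (!any(face)) next
    ijk <- arrayInd(which(face), d)
    i <- ijk[, 1]; j <- ijk[, 2]; k <- ijk[, 3]
    q <- switch(paste0(side$ax, ifelse(side$dir > 0, "+", "-")),
      "1+" = list(corner(i, j - 1, k - 1), corner(i, j, k - 1),
                  corner(i, j, k),         corner(i, j - 1, k)),
      "1-" = list(corner(i - 1, j - 1, k - 1), corner(i - 1, j - 1, k),
                  corner(i - 1, j, k),         corner(i - 1, j, k - 1)),
      "2+" = list(corner(i - 1, j, k - 1), corner(i - 1, j, k),
                  corner(i, j, k),         corner(i, j, k - 1)),
      "2-" = list(corner(i - 1, j - 1, k - 1), corner(i, j - 1, k - 1),
                  corner(i, j - 1, k),         corner(i - 1, j - 1, k)),
      "3+" = list(corner(i - 1, j - 1, k), corner(i, j - 1, k),
                  corner(i, j, k),         corner(i - 1, j, k)),
      "3-" = list(corner(i - 1, j - 1, k - 1), corner(i - 1, j, k - 1),
                  corner(i, j, k - 1),         corner(i, j - 1, k - 1))
    )
    quads[[length(quads) + 1L]] <- q
  }
  A <- do.call(rbind, lapply(quads, `[[`, 1))
  B <- do.call(rbind, lapply(quads, `[[`, 2))
  C <- do.call(rbind, lapply(quads, `[[`, 3))
  D <- do.call(rbind, lapply(quads, `[[`, 4))
  corners <- rbind(A, B, C, D)
  key <- corners[, 1] + (d[1] + 1) * (corners[, 2] + (d[2] + 1) * corners[, 3])
  uk <- !duplicated(key)
  vid <- match(key, key[uk])
  nq <- nrow(A)
  ia <- vid[seq_len(nq)]
  ib <- vid[nq + seq_len(nq)]
  ic <- vid[2L * nq + seq_len(nq)]
  id <- vid[3L * nq + seq_len(nq)]
  faces <- rbind(cbind(ia, ib, ic), cbind(ia, ic, id))
  verts <- sweep(corners[uk, , drop = FALSE] * pitch, 2, origin, "+")
  trabecular_mesh(verts, faces, axis_dv = axis_dv, validate = FALSE)
}

# sizes of 6-connected components of a voxel solid; returns integer label
# array with attribute "sizes" (descending order not guaranteed)
label_components <- function(occ) {
  d <- dim(occ)
  n <- prod(d)
  lab <- integer(n)
  solid <- which(occ)
  if (length(solid) == 0) {
    return(structure(array(lab, d), sizes = integer(0)))
  }
  remaining <- logical(n)
  remaining[solid] <- TRUE
  nxy <- d[1] * d[2]
  cur <- 0L
  sizes <- integer(0)
  # precompute index arithmetic guards
  ii <- function(idx) (idx - 1L) %% d[1] + 1L
  jj <- function(idx) ((idx - 1L) %/% d[1]) %% d[2] + 1L
  kk <- function(idx) (idx - 1L) %/% nxy + 1L
  while (any(remaining)) {
    seed <- which.max(remaining)
    cur <- cur + 1L
    frontier <- seed
    remaining[seed] <- FALSE
    lab[seed] <- cur
    size <- 1L
    while (length(frontier)) {
      cand <- c(frontier[ii(frontier) > 1L] - 1L,
                frontier[ii(frontier) < d[1]] + 1L,
                frontier[jj(frontier) > 1L] - d[1],
                frontier[jj(frontier) < d[2]] + d[1],
                frontier[kk(frontier) > 1L] - nxy,
                frontier[kk(frontier) < d[3]] + nxy)
      cand <- unique(cand[remaining[cand]])
      remaining[cand] <- FALSE
      lab[cand] <- cur
      size <- size + length(cand)
      frontier <- cand
    }
    sizes <- c(sizes, size)
  }
  structure(array(lab, d), sizes = sizes)
}
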