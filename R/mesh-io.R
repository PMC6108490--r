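#' Write a mesh to STL
#'
#' Binary STL by default (the interchange format used for print-ready core
#' samples); `ascii = TRUE` writes the text variant.
#'
#' @param mesh A `trabecular_mesh` (or list with `vertices`, `faces`).
#' @param path Output file path.
#' @param ascii Write ASCII STL instead of binary.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, ascii = FALSE) {
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  e1 <- p2 - p1
  e2 <- p3 - p1
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n <- n / len
  nf <- nrow(f)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid condylocore", con)
    for (i in seq_len(nf)) {
      writeLines(c(
        sprintf("facet normal %.9g %.9g %.9g", n[i, 1], n[i, 2], n[i, 3]),
        "  outer loop",
        sprintf("    vertex %.9g %.9g %.9g", p1[i, 1], p1[i, 2], p1[i, 3]),
        sprintf("    vertex %.9g %.9g %.9g", p2[i, 1], p2[i, 2], p2[i, 3]),
        sprintf("    vertex %.9g %.9g %.9g", p3[i, 1], p3[i, 2], p3[i, 3]),
        "  endloop",
        "endfacet"), con)
    }
    writeLines("endsolid condylocore", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(formatC("condylocore binary STL", width = -80))
    writeBin(hdr[seq_len(80)], con)
    writeBin(as.integer(nf), con, size = 4, endian = "little")
    # 12 floats + uint16 attribute per facet
    dat <- rbind(t(n), t(p1), t(p2), t(p3))  # 12 x nf column-per-facet
    for (i in seq_len(nf)) {
      writeBin(as.numeric(dat[, i]), con, size = 4, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  }
  invisible(path)
}

#' Read a triangle mesh from STL, OBJ, or ASCII PLY
#'
#' Format is chosen by file extension (`.stl`, `.obj`, `.ply`); binary and
#' ASCII STL are auto-detected. STL facets are welded into shared vertices by
#' exact coordinate match.
#'
#' @param path Input file.
#' @param axis_dv Dorso-ventral axis to attach (default +z).
#' @param validate Passed to [trabecular_mesh()].
#' @return A `trabecular_mesh`.
#' @export
read_mesh <- function(path, axis_dv = c(0, 0, 1), validate = TRUE) {
  ext <- tolower(tools::file_ext(path))
  vf <- switch(ext,
    stl = read_stl_raw(path),
    obj = read_obj_raw(path),
    ply = read_ply_raw(path),
    stop("unsupported mesh format: .", ext, " (use STL, OBJ, or ASCII PLY)")
  )
  trabecular_mesh(vf$vertices, vf$faces, axis_dv = axis_dv,
                  validate = validate)
}

weld_facets <- function(tri) {
  # tri: (3*nf) x 3 matrix of facet corner coordinates in face order
  key <- paste(tri[, 1], tri[, 2], tri[, 3], sep = "|")
  uk <- !duplicated(key)
  idx <- match(key, key[uk])
  list(vertices = tri[uk, , drop = FALSE],
       faces = matrix(idx, ncol = 3, byrow = TRUE))
}

read_stl_raw <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  head <- readBin(con, "raw", 80)
  nf <- readBin(con, "integer", 1, size = 4, endian = "little")
  is_bin <- is.finite(sz) && length(nf) == 1 && sz == 84 + 50 * nf
  close(con)
  if (is_bin) {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 84)
    tri <- matrix(NA_real_, 3 * nf, 3)
    for (i in seq_len(nf)) {
      vals <- readBin(con, "numeric", 12, size = 4, endian = "little")
      readBin(con, "raw", 2)
      tri[3 * i - 2:0, ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
    }
    return(weld_facets(tri))
  }
  ln <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", ln, value = TRUE)
  parts <- strsplit(trimws(vl), "\\s+")
  tri <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  if (nrow(tri) %% 3 != 0) stop("malformed ASCII STL: vertex count not a multiple of 3")
  weld_facets(tri)
}

read_obj_raw <- function(path) {
  ln <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", ln, value = TRUE)
  fl <- grep("^f\\s", ln, value = TRUE)
  v <- t(vapply(strsplit(trimws(vl), "\\s+"),
                function(p) as.numeric(p[2:4]), numeric(3)))
  f <- t(vapply(strsplit(trimws(fl), "\\s+"), function(p) {
    ix <- vapply(p[-1], function(tok) as.integer(strsplit(tok, "/")[[1]][1]),
                 integer(1))
    if (length(ix) != 3) stop("non-triangular OBJ face; triangulate first")
    ix
  }, integer(3)))
  list(vertices = v, faces = f)
}

read_ply_raw <- function(path) {
  ln <- readLines(path, warn = FALSE)
  if (!grepl("^ply", ln[1])) stop("not a PLY file")
  if (!any(grepl("format ascii", ln))) stop("only ASCII PLY is supported")
  nv <- as.integer(sub(".*element vertex\\s+", "",
                       grep("element vertex", ln, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face\\s+", "",
                       grep("element face", ln, value = TRUE)[1]))
  hdr_end <- grep("^end_header", ln)[1]
  body <- ln[(hdr_end + 1):length(ln)]
  vparts <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  v <- t(vapply(vparts, function(p) as.numeric(p[1:3]), numeric(3)))
  fparts <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  f <- t(vapply(fparts, function(p) {
    if (as.integer(p[1]) != 3) stop("non-triangular PLY face; triangulate first")
    as.integer(p[2:4]) + 1L
  }, integer(3)))
  list(vertices = v, faces = f)
}
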