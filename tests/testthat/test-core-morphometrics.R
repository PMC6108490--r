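test_that("core cylinder height follows the mesh extent with d = h/2", {
  slab <- mesh_block(c(30, 30, 20), origin = c(-15, -15, -10))
  cyl <- define_core_cylinder(slab, c(0, 0, 0))
  expect_equal(cyl$height, 20)
  expect_equal(cyl$diameter, 10)
  expect_equal(cyl$axis, c(0, 0, 1))

  # chord through a sphere's center equals its diameter
  sph <- mesh_sphere(5)
  cyl2 <- define_core_cylinder(sph, c(0, 0, 0))
  expect_equal(cyl2$height, 10, tolerance = 1e-9)
  expect_equal(cyl2$diameter, 5, tolerance = 1e-9)
})

test_that("anchors outside the mesh and non-intersecting rays error", {
  slab <- mesh_block(c(10, 10, 10))
  expect_error(define_core_cylinder(slab, c(20, 20, 20)), "outside")
  expect_error(core_cylinder(c(0, 0, 0), c(0, 0, 1), height = 10,
                             diameter = 4), "diameter = height / 2",
               fixed = TRUE)
})

test_that("Boolean core of a covering block reproduces the cylinder volume", {
  block <- mesh_block(c(20, 20, 14), origin = c(-10, -10, -7))
  cyl <- core_cylinder(c(0, 0, 0), c(0, 0, 1), height = 10, diameter = 5)
  core <- extract_core(block, cyl, voxel_pitch = 10 / 100)
  expect_equal(core$fill_volume, pi * 2.5^2 * 10, tolerance = 0.01)
  expect_lte(core$fill_volume, pi * 2.5^2 * 10 * 1.01)
})

test_that("half-space covering half the cylinder gives half its volume", {
  lower <- mesh_block(c(20, 20, 10), origin = c(-10, -10, -10))
  cyl <- core_cylinder(c(0, 0, 0), c(0, 0, 1), height = 10, diameter = 5)
  core <- extract_core(lower, cyl, voxel_pitch = 10 / 100)
  expect_equal(core$fill_volume, pi * 2.5^2 * 10 / 2, tolerance = 0.01)
})

test_that("disjoint mesh and cylinder raise an empty-intersection error", {
  far <- mesh_block(c(5, 5, 5), origin = c(50, 50, 50))
  cyl <- core_cylinder(c(0, 0, 0), c(0, 0, 1), height = 10, diameter = 5)
  expect_error(extract_core(far, cyl), "empty intersection")
})

test_that("standardization scales a 20 mm core by s = 0.5 (V x1/8, SA x1/4)", {
  block <- mesh_block(c(30, 30, 24), origin = c(-15, -15, -12))
  cyl <- core_cylinder(c(0, 0, 0), c(0, 0, 1), height = 20, diameter = 10)
  core <- extract_core(block, cyl, voxel_pitch = 20 / 100)
  std <- standardize_core(core)
  expect_equal(std$height, 10)
  expect_equal(std$diameter, 5)
  expect_equal(std$scale_factor, 0.5)
  expect_equal(std$fill_volume, core$fill_volume * 0.125, tolerance = 1e-12)
  expect_equal(std$surface_area, core$surface_area * 0.25, tolerance = 1e-12)
  # idempotent
  std2 <- standardize_core(std)
  expect_equal(std2$mesh$vertices, std$mesh$vertices)
  expect_equal(std2$fill_volume, std$fill_volume)
})

test_that("geometrically similar cores standardize to identical morphometrics", {
  small <- core_sample(mesh_cylinder(8, 4, n_seg = 64), height = 8)
  large <- core_sample(mesh_cylinder(16, 8, n_seg = 64), height = 16)
  s1 <- standardize_core(small)
  s2 <- standardize_core(large)
  expect_equal(s1$fill_volume, s2$fill_volume, tolerance = 0.005)
  expect_equal(s1$surface_area, s2$surface_area, tolerance = 0.005)
})

test_that("aspect ratios away from 2:1 are rejected", {
  core <- solid_cylinder_core(height = 10)
  core$diameter <- 6
  expect_error(standardize_core(core), "aspect")
})

test_that("volume and area measurement match analytic values", {
  cube <- mesh_block(c(1, 1, 1))
  m <- mesh_volume_area(cube)
  expect_equal(m$volume, 1)
  expect_equal(m$area, 6)

  std <- solid_cylinder_core()
  mm <- measure_morphometrics(std)
  expect_equal(mm$fill_volume, 196.35, tolerance = 0.01)
  expect_equal(mm$surface_area, 196.35, tolerance = 0.01)
})

test_that("inverted orientation is auto-fixed with a warning", {
  core <- solid_cylinder_core()
  core$mesh$faces <- core$mesh$faces[, c(1, 3, 2)]
  expect_warning(mm <- measure_morphometrics(core), "orientation")
  expect_gt(mm$fill_volume, 0)
})

test_that("subdividing triangles leaves volume and area unchanged", {
  sph <- mesh_sphere(3, n_lat = 8, n_lon = 12)
  m0 <- mesh_volume_area(sph)
  m1 <- mesh_volume_area(mesh_subdivide(sph))
  expect_equal(m1$volume, m0$volume, tolerance = 1e-9)
  expect_equal(m1$area, m0$area, tolerance = 1e-9)
})

test_that("Boolean volume converges toward the analytic value as pitch shrinks", {
  block <- mesh_block(c(20, 20, 14), origin = c(-10, -10, -7))
  cyl <- core_cylinder(c(0, 0, 0), c(0, 0, 1), height = 10, diameter = 5)
  target <- pi * 2.5^2 * 10
  err <- vapply(c(25, 50, 100), function(div) {
    abs(extract_core(block, cyl, voxel_pitch = 10 / div)$fill_volume - target)
  }, numeric(1))
  expect_lt(err[3] / target, 0.01)
  expect_lt(err[3], err[1])
})

test_that("non-watertight input meshes are rejected", {
  open_mesh <- mesh_block(c(10, 10, 10), origin = c(-5, -5, -5))
  open_mesh$faces <- open_mesh$faces[-1, ]  # puncture it
  cyl <- core_cylinder(c(0, 0, 0), c(0, 0, 1), height = 8, diameter = 4)
  expect_error(extract_core(open_mesh, cyl), "watertight")
})

test_that("STL round trip preserves geometry (binary and ASCII)", {
  mesh <- mesh_cylinder(10, 5, n_seg = 24)
  for (ascii in c(FALSE, TRUE)) {
    path <- tempfile(fileext = ".stl")
    write_stl(mesh, path, ascii = ascii)
    back <- read_mesh(path)
    m0 <- mesh_volume_area(mesh)
    m1 <- mesh_volume_area(back)
    expect_equal(m1$volume, m0$volume, tolerance = 1e-5)
    expect_equal(m1$area, m0$area, tolerance = 1e-5)
    unlink(path)
  }
})

test_that("OBJ and ASCII PLY readers parse simple meshes", {
  cube <- mesh_block(c(1, 1, 1))
  obj <- tempfile(fileext = ".obj")
  writeLines(c(apply(cube$vertices, 1, function(p)
    sprintf("v %g %g %g", p[1], p[2], p[3])),
    apply(cube$faces, 1, function(f)
      sprintf("f %d %d %d", f[1], f[2], f[3]))), obj)
  m <- read_mesh(obj)
  expect_equal(mesh_volume_area(m)$volume, 1)

  ply <- tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(cube$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(cube$faces)),
               "property list uchar int vertex_indices", "end_header",
               apply(cube$vertices, 1, paste, collapse = " "),
               apply(cube$faces - 1L, 1, function(f)
                 paste(c(3, f), collapse = " "))), ply)
  m2 <- read_mesh(ply)
  expect_equal(mesh_volume_area(m2)$volume, 1)
  unlink(c(obj, ply))
})
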