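test_that("mesh center is the vertex mean and is translation-equivariant", {
  tet <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                       rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4)))
  expect_equal(mesh_center(tet), c(0.25, 0.25, 0.25))
  expect_equal(mesh_center(cube_mesh()), c(x = 0.5, y = 0.5, z = 0.5))
  shift <- c(-3, 2, 7.5)
  tet2 <- triangle_mesh(sweep(tet$vertices, 2, shift, "+"), tet$faces)
  expect_equal(mesh_center(tet2), c(0.25, 0.25, 0.25) + shift)
  expect_error(mesh_center(list(vertices = matrix(numeric(0), 0, 3))))
})

test_that("enclosed volume matches known solids and scales cubically", {
  expect_equal(enclosed_volume(cube_mesh()), 1.0)
  ic <- icosphere(1, 3)
  expect_lt(abs(enclosed_volume(ic) - 4 * pi / 3) / (4 * pi / 3), 0.01)
  s <- 2.3
  ics <- triangle_mesh(ic$vertices * s, ic$faces)
  expect_equal(enclosed_volume(ics), s^3 * enclosed_volume(ic),
               tolerance = 1e-10)
  # rigid invariance
  tr <- rigid_transform(rot_z(33), c(4, -1, 2))
  expect_equal(enclosed_volume(apply_transform(ic, tr)),
               enclosed_volume(ic), tolerance = 1e-9)
})

test_that("non-watertight meshes are rejected with a boundary diagnostic", {
  ic <- icosphere(1, 1)
  open_mesh <- triangle_mesh(ic$vertices, ic$faces[-1, , drop = FALSE])
  expect_false(is_watertight(open_mesh))
  expect_length(boundary_edges(open_mesh), 3L)
  expect_error(enclosed_volume(open_mesh), "watertight")
  expect_error(classify_inner_outer(open_mesh), "watertight")
})

test_that("a closed sphere has no lumen-visible vertices", {
  # center lies in the enclosed material, so every vertex is outer
  ic <- icosphere(2, 2)
  expect_true(all(classify_inner_outer(ic) == 1L))
})

test_that("a degenerate zero-thickness shell is all inner", {
  # two coincident triangles enclose nothing: the interior is empty
  flat <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                        rbind(c(1, 2, 3), c(1, 3, 2)))
  expect_true(is_watertight(flat))
  expect_true(all(classify_inner_outer(flat) == 0L))
})

test_that("bowl phantom vertices classify into lumen-facing and exterior", {
  ph <- generate_dome_phantom(5, 0.5, 0.5, mesh_resolution = 24L)
  lab <- classify_inner_outer(ph$dome)
  expect_equal(lab, ph$labels)
})

test_that("majority refinement respects fixed points, majorities and ties", {
  ic <- icosphere(1, 1)
  n <- nrow(ic$vertices)
  expect_equal(refine_labels(ic, rep(0L, n)), rep(0L, n))
  # single dissenting vertex flips to its neighbourhood label
  lab <- rep(0L, n); lab[7] <- 1L
  expect_equal(refine_labels(ic, lab), rep(0L, n))
  # 2-2 tie keeps the current label: square pyramid apex with 4 neighbours
  pyr <- triangle_mesh(
    rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0)),
    rbind(c(1, 2, 3), c(1, 3, 4), c(1, 4, 5), c(1, 5, 2),
          c(2, 5, 4), c(2, 4, 3)))
  lab <- c(1L, 0L, 0L, 1L, 1L)  # apex sees 0,0,1,1 -> tie
  expect_equal(refine_labels(pyr, lab, single_pass = TRUE)[1], 1L)
})

test_that("refinement does not increase neighbour label disagreements", {
  ph <- generate_dome_phantom(5, 0.5, 0.4, mesh_resolution = 20L)
  mesh <- ph$dome
  f <- mesh$faces
  edges <- unique(cbind(pmin(c(f[, 1], f[, 2], f[, 3]),
                             c(f[, 2], f[, 3], f[, 1])),
                        pmax(c(f[, 1], f[, 2], f[, 3]),
                             c(f[, 2], f[, 3], f[, 1]))))
  disagreements <- function(lab) sum(lab[edges[, 1]] != lab[edges[, 2]])
  set.seed(42)
  for (k in 1:5) {
    lab <- as.integer(stats::runif(nrow(mesh$vertices)) < 0.5)
    ref <- refine_labels(mesh, lab)
    expect_lte(disagreements(ref), disagreements(lab))
  }
})

test_that("wall thickness recovers the phantom's known thickness", {
  ph <- generate_dome_phantom(4, 1, 0, mesh_resolution = 40L)
  th <- wall_thickness(ph$dome, ph$labels)
  expect_true(all(th >= 0))
  # nearest-opposite-vertex distance is an upper-biased estimate bounded by
  # the true thickness from below only up to mesh resolution
  expect_lt(abs(mean(th) - 1), 0.1)
  expect_error(wall_thickness(ph$dome, rep(1L, nrow(ph$dome$vertices))),
               "both")
  # planting an opposite-class vertex at distance d bounds thickness by d
  m2 <- triangle_mesh(rbind(ph$dome$vertices, ph$dome$vertices[1, ] +
                              c(0.05, 0, 0)), ph$dome$faces)
  lab2 <- c(ph$labels, 1L - ph$labels[1])
  th2 <- wall_thickness(m2, lab2)
  expect_lte(th2[1], 0.05 + 1e-12)
})

test_that("meshes round-trip through STL, PLY and OBJ", {
  m <- bumpy_mesh(2, 2L)
  vol <- enclosed_volume(m)
  for (fmt in c("stl", "ply", "obj")) {
    p <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_mesh(m, p)
    m2 <- read_mesh(p)
    expect_equal(nrow(m2$vertices), nrow(m$vertices))
    expect_equal(enclosed_volume(m2), vol, tolerance = 1e-5)
  }
  # binary STL written independently of the package's ASCII writer
  p <- withr::local_tempfile(fileext = ".stl")
  write_stl_binary(m, p)
  m3 <- read_mesh(p)
  expect_true(is_watertight(m3))
  expect_equal(enclosed_volume(m3), vol, tolerance = 1e-5)
})

test_that("scalar fields round-trip through CSV and PLY attributes", {
  m <- icosphere(1, 1)
  f <- generate_wss_field(m, "gradient")
  p <- withr::local_tempfile(fileext = ".csv")
  write_scalar_field(f, p)
  expect_equal(read_scalar_field(p, m), f)
  expect_error(read_scalar_field(p, icosphere(1, 2)), "match")
  p2 <- withr::local_tempfile(fileext = ".ply")
  write_mesh(m, p2, vertex_attr = list(wss = f))
  expect_equal(nrow(read_mesh(p2)$vertices), nrow(m$vertices))
})
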