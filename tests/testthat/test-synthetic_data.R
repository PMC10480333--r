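test_that("the dome phantom is watertight with exact ground truth", {
  ph <- generate_dome_phantom(5, 0.5, 0.8, mesh_resolution = 32L, seed = 1)
  expect_true(is_watertight(ph$dome))
  expect_true(is_watertight(ph$undeformed))
  expect_true(is_watertight(ph$target))
  expect_equal(length(ph$labels), nrow(ph$dome$vertices))
  expect_true(all(ph$thickness == 0.5))
  # near-isometric collapse: deflation preserves the shell volume closely
  expect_lt(abs(enclosed_volume(ph$dome) -
                  enclosed_volume(ph$undeformed)) /
              enclosed_volume(ph$undeformed), 0.05)
  expect_error(generate_dome_phantom(5, 6, 0.5))
  expect_error(generate_dome_phantom(5, 0.5, 1.2))
})

test_that("zero deflation reproduces the undeformed shell", {
  ph <- generate_dome_phantom(4, 0.6, 0, mesh_resolution = 24L)
  expect_equal(ph$dome$vertices, ph$undeformed$vertices)
  # vanishing deflation converges to the undeformed shell
  ph2 <- generate_dome_phantom(4, 0.6, 1e-4, mesh_resolution = 24L)
  expect_lt(max(abs(ph2$dome$vertices - ph$undeformed$vertices)), 0.01)
})

test_that("phantom ground-truth labels agree with the classifier", {
  ph <- generate_dome_phantom(5, 0.5, 0.7, mesh_resolution = 28L)
  expect_equal(classify_inner_outer(ph$dome), ph$labels)
})

test_that("phantom generators are deterministic under a fixed seed", {
  a <- generate_dome_phantom(5, 0.5, 0.6, mesh_resolution = 20L, seed = 3,
                             noise_mm = 0.02)
  b <- generate_dome_phantom(5, 0.5, 0.6, mesh_resolution = 20L, seed = 3,
                             noise_mm = 0.02)
  expect_identical(a$dome$vertices, b$dome$vertices)
  g1 <- generate_histology_image("ASMA", size = 200L, seed = 11)
  g2 <- generate_histology_image("ASMA", size = 200L, seed = 11)
  expect_identical(g1$image, g2$image)
  expect_identical(unclass(g1$mask)[, ], unclass(g2$mask)[, ])
})

test_that("the histology phantom is a single u-band with distinct palettes", {
  g <- generate_histology_image("HE", size = 300L, seed = 2)
  lab <- EBImage::bwlabel(EBImage::Image(t(unclass(g$mask)[, ])))
  expect_equal(max(lab), 1)
  # simply connected: hole filling changes nothing
  filled <- EBImage::fillHull(EBImage::Image(t(unclass(g$mask)[, ] != 0)))
  expect_equal(sum(filled), sum(g$mask != 0))
  # palette separation between stains inside the tissue
  he <- generate_histology_image("HE", size = 300L, seed = 2)
  oro <- generate_histology_image("ORO", size = 300L, seed = 2)
  sel <- he$mask != 0
  delta <- vapply(1:3, function(ch)
    abs(mean(he$image[, , ch][sel]) - mean(oro$image[, , ch][sel])),
    numeric(1))
  expect_gt(max(delta), 30 / 255)
})

test_that("synthetic WSS fields are positive with the requested shape", {
  m <- icosphere(4, 2)
  g <- generate_wss_field(m, "gradient")
  expect_true(all(g > 0))
  # monotone along the axis: ordering by z matches ordering by value
  expect_gt(stats::cor(m$vertices[, 3], g), 0.999)
  s <- generate_wss_field(m, "spot", spot_vertex = 17L)
  expect_true(all(s > 0))
  expect_equal(unname(which.max(s)), 17L)
})

test_that("micro-CT stacks agree with plane slicing and nest calcifications", {
  ph <- generate_dome_phantom(5, 0.5, 0.4, mesh_resolution = 24L)
  st <- generate_microct_stack(ph$dome, n_slices = 3L, px_per_mm = 8,
                               seed = 4)
  expect_length(st$masks, 3L)
  ref <- slice_mesh_at_plane(ph$dome, st$offsets[2], c(0, 0, 1), 8)
  expect_equal(unclass(st$masks[[2]])[, ], unclass(ref)[, ])
  for (k in 1:3) {
    calc <- st$calc_masks[[k]] != 0
    wall <- st$masks[[k]] != 0
    expect_true(all(wall[calc]))
  }
  st2 <- generate_microct_stack(ph$dome, n_slices = 3L, px_per_mm = 8,
                                seed = 4)
  expect_identical(lapply(st$calc_masks, as.vector),
                   lapply(st2$calc_masks, as.vector))
})
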