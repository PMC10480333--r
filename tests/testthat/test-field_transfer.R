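test_that("rigid transforms compose and preserve distances", {
  m <- bumpy_mesh(2, 2L)
  expect_equal(apply_transform(m, rigid_transform())$vertices, m$vertices)
  t1 <- rigid_transform(rot_z(25), c(1, 0, -2))
  t2 <- rigid_transform(rot_z(-40), c(0, 3, 1))
  seq_applied <- apply_transform(apply_transform(m, t1), t2)
  composed <- apply_transform(m, rigid_transform(
    t2[1:3, 1:3] %*% t1[1:3, 1:3],
    t2[1:3, 1:3] %*% t1[1:3, 4] + t2[1:3, 4]))
  expect_equal(seq_applied$vertices, composed$vertices, tolerance = 1e-12)
  # pairwise distances preserved
  idx <- cbind(c(1, 5, 9), c(20, 40, 60))
  d0 <- sqrt(rowSums((m$vertices[idx[, 1], ] - m$vertices[idx[, 2], ])^2))
  mt <- apply_transform(m, t1)
  d1 <- sqrt(rowSums((mt$vertices[idx[, 1], ] - mt$vertices[idx[, 2], ])^2))
  expect_equal(d1, d0, tolerance = 1e-9)
})

test_that("ICP on identical meshes returns the identity", {
  m <- bumpy_mesh(3, 2L)
  res <- icp_register(m, m)
  expect_lt(res$rms, 1e-9)
  expect_lt(rotation_angle_deg(res$transform[1:3, 1:3]), 1e-4)
  expect_lt(sqrt(sum(res$transform[1:3, 4]^2)), 1e-6)
  expect_true(all(diff(res$rms_history) <= 1e-12))
})

test_that("ICP recovers a known rigid transform", {
  m <- bumpy_mesh(5, 3L)
  tr <- rigid_transform(rot_z(10), c(1, 2, 3))
  moved <- apply_transform(m, tr)
  res <- icp_register(m, moved)
  expect_lt(rotation_angle_deg(res$transform[1:3, 1:3], tr[1:3, 1:3]), 0.5)
  expect_lt(sqrt(sum((res$transform[1:3, 4] - tr[1:3, 4])^2)), 0.1)
})

test_that("voxel assignment equals exhaustive nearest-neighbour search", {
  grid <- voxel_grid(c(-1, -1, -1), 0.35, c(20, 20, 20))
  two <- triangle_mesh(rbind(c(0, 0, 0), c(3, 2, 1)),
                       matrix(c(1L, 2L, 1L), 1, 3))
  vol <- assign_field_to_voxels(two, c(10, 20), grid)
  centers <- as.matrix(expand.grid(
    x = -1 + (0:19) * 0.35, y = -1 + (0:19) * 0.35, z = -1 + (0:19) * 0.35))
  d1 <- rowSums(sweep(centers, 2, c(0, 0, 0))^2)
  d2 <- rowSums(sweep(centers, 2, c(3, 2, 1))^2)
  expect_equal(as.vector(vol), ifelse(d1 <= d2, 10, 20))
  # range is a subset of the field range and constants stay constant
  expect_true(all(vol %in% c(10, 20)))
  vol2 <- assign_field_to_voxels(two, c(7, 7), grid)
  expect_true(all(vol2 == 7))
  one <- triangle_mesh(matrix(c(5, 5, 5), 1, 3), matrix(c(1L, 1L, 1L), 1, 3))
  expect_true(all(assign_field_to_voxels(one, 3.14, grid) == 3.14))
  expect_error(voxel_grid(c(0, 0, 0), 0.1, c(0, 5, 5)))
})

test_that("planar slices resample the volume faithfully", {
  grid <- voxel_grid(c(0, 0, 0), 0.5, c(12, 12, 12))
  two <- triangle_mesh(rbind(c(1, 2.75, 2.75), c(4.5, 2.75, 2.75)),
                       matrix(c(1L, 2L, 1L), 1, 3))
  vol <- assign_field_to_voxels(two, c(1, 2), grid)
  sl <- field_to_slice(vol, 2.5, c(0, 0, 1), px_per_mm = 10)
  vals <- sl[!is.na(sl)]
  expect_setequal(unique(vals), c(1, 2))
  # bisector plane: exactly one left-right transition per row
  trans <- apply(sl, 1, function(r) {
    r <- r[!is.na(r)]
    sum(diff(r) != 0)
  })
  expect_true(all(trans <= 1))
  # constant volume gives a constant slice
  volc <- assign_field_to_voxels(two, c(5, 5), grid)
  slc <- field_to_slice(volc, 2.5, c(0, 0, 1), px_per_mm = 5)
  expect_true(all(slc[!is.na(slc)] == 5))
})

test_that("transforms and volumes persist to disk", {
  tr <- rigid_transform(rot_z(12), c(0.5, -1, 2))
  p <- withr::local_tempfile(fileext = ".json")
  write_transform(tr, p)
  expect_equal(unclass(read_transform(p))[, ], unclass(tr)[, ],
               tolerance = 1e-12)
  skip_if_not_installed("tiff")
  vol <- array(seq_len(27) / 27, c(3, 3, 3))
  pv <- withr::local_tempfile(fileext = ".tif")
  write_volume(vol, pv)
  expect_true(file.exists(pv))
  expect_true(file.exists(paste0(pv, ".json")))
})
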