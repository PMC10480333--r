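disk_mask <- function(size, r, cx = size / 2, cy = size / 2) {
  xs <- matrix(seq_len(size), size, size, byrow = TRUE)
  ys <- matrix(seq_len(size), size, size)
  tissue_mask((xs - cx)^2 + (ys - cy)^2 <= r^2)
}

test_that("contour extraction traces a counter-clockwise boundary", {
  m <- disk_mask(140, 50)
  ct <- extract_contour(m)
  expect_gt(polygon_area(ct), 0)
  radii <- sqrt((ct[, 1] - 70)^2 + (ct[, 2] - 70)^2)
  expect_true(all(abs(radii - 50) <= 1.5))
  expect_error(extract_contour(m * 0L), "empty")
  # two components: largest wins with a warning
  m2 <- m
  m2[5:8, 5:8] <- 1L
  expect_warning(ct2 <- extract_contour(m2), "largest")
  expect_equal(nrow(ct2), nrow(ct))
})

test_that("a convex contour is entirely inner", {
  ct <- extract_contour(disk_mask(120, 40))
  sp <- split_contour(ct)
  expect_true(all(sp$labels == 0L))
})

test_that("the u-shape split matches the brute-force intersection oracle", {
  g <- generate_histology_image("HE", size = 300L, seed = 4)
  ct <- extract_contour(g$mask)
  sp <- split_contour(ct)
  expect_true(any(sp$labels == 0L) && any(sp$labels == 1L))
  expect_equal(sp$labels, oracle_split(unclass(ct)))
  # symmetric u-shape: center sits on the vertical symmetry axis
  expect_lt(abs(sp$center[1] - ncol(g$mask) / 2), 2.5)
})

test_that("sectioning yields the configured overlapping sections", {
  g <- generate_histology_image("MT", size = 400L, seed = 2)
  sp <- split_contour(extract_contour(g$mask))
  sec <- build_sections(sp, 5000L, 50L)
  expect_equal(sec$n_sections, 5000L)
  expect_equal(dim(sec$outer_windows), c(5000L, 50L))
  expect_equal(nrow(sec$inner), 5000L)
  # consecutive sections overlap in their outer windows
  ov <- vapply(seq_len(4999L), function(i)
    length(intersect(sec$outer_windows[i, ], sec$outer_windows[i + 1, ])),
    integer(1))
  expect_true(all(ov > 0))
  # first and last sections sit at the u-tips: minimal inner-outer distance
  d_sec <- vapply(c(1L, 2500L, 5000L), function(i)
    min(sqrt(rowSums(sweep(sec$outer_pts[sec$outer_windows[i, ], ,
                                         drop = FALSE],
                           2, sec$inner[i, ])^2))), numeric(1))
  expect_lt(d_sec[1], d_sec[2])
  expect_lt(d_sec[3], d_sec[2])
  expect_error(build_sections(sp, 100L, 10000L), "outer")
})

test_that("mapping a constant image yields a constant masked image", {
  g <- generate_histology_image("ORO", size = 300L, seed = 6)
  img <- array(0.42, c(300, 300, 3))
  sec <- build_sections(split_contour(extract_contour(g$mask)), 800L, 30L)
  mp <- map_image(img, sec, sec, g$mask, 5L)
  inside <- mp$count > 0
  expect_true(all(abs(mp$image[, , 1][inside] - 0.42) < 1e-9))
  expect_lte(max(mp$count), 5L)
  # mismatched section sets are rejected
  sec2 <- build_sections(split_contour(extract_contour(g$mask)), 400L, 30L)
  expect_error(map_image(img, sec, sec2, g$mask), "match")
})

test_that("self-mapping preserves the image and its dominant colours", {
  # fidelity grows with resolution: the 50-point outer windows span a
  # smaller tissue fraction, so use a moderately sized phantom here
  g <- generate_histology_image("MT", size = 800L, seed = 8)
  sec <- build_sections(split_contour(extract_contour(g$mask)), 5000L, 50L)
  mp <- map_image(g$image, sec, sec, g$mask, 5L)
  expect_gt(masked_correlation(mp$image, g$image, g$mask), 0.8)
  sel <- g$mask != 0
  for (ch in 1:3) {
    src_mean <- mean(g$image[, , ch][sel])
    out_mean <- mean(mp$image[, , ch][sel])
    expect_lt(abs(out_mean - src_mean) / src_mean, 0.05)
  }
})

test_that("masked correlation follows the product-moment formula", {
  a <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9) / 10, 3, 3)
  b <- matrix(c(2, 1, 4, 3, 7, 5, 6, 9, 8) / 10, 3, 3)
  mask <- matrix(1L, 3, 3)
  # hand-computed product-moment coefficient
  xm <- a - mean(a); ym <- b - mean(b)
  manual <- sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
  expect_equal(masked_correlation(a, b, mask), manual)
  expect_equal(masked_correlation(a, a, mask), 1.0)
  expect_equal(masked_correlation(a, max(a) + min(a) - a, mask), -1.0)
  expect_error(masked_correlation(a, matrix(0.5, 3, 3), mask), "constant")
})

test_that("mask dilation degrades the mapping monotonically", {
  g <- generate_histology_image("HE", size = 400L, seed = 12)
  tab <- dilation_robustness_experiment(g$image, g$mask, c(0L, 4L, 10L),
                                        n_sections = 1500L)
  expect_equal(nrow(tab), 3L)
  expect_true(all(tab$ok))
  expect_true(all(diff(tab$correlation) <= 0))
  # radius zero equals the plain self-mapping correlation
  sec <- build_sections(split_contour(extract_contour(g$mask)), 1500L, 50L)
  self_corr <- masked_correlation(
    map_image(g$image, sec, sec, g$mask, 5L)$image, g$image, g$mask)
  expect_equal(tab$correlation[1], self_corr, tolerance = 1e-12)
})
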