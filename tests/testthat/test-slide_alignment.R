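test_that("stack length sums all slides including placeholders", {
  st <- slide_stack(rep("HE", 10), 10)
  expect_equal(stack_length(st), 100)
  st2 <- slide_stack(c(rep("HE", 4), "PLACEHOLDER", rep("MT", 4),
                       "PLACEHOLDER"), 10)
  expect_equal(stack_length(st2), 100)
  # permutation invariant
  st3 <- slide_stack(c("HE", "MT", "ORO"), c(5, 10, 15))
  st4 <- slide_stack(c("ORO", "HE", "MT"), c(15, 5, 10))
  expect_equal(stack_length(st3), stack_length(st4))
  expect_error(stack_length(st3[0, ]), "empty")
  expect_error(slide_stack("HE", -1))
  expect_error(slide_stack("XX", 10))
})

test_that("slide positions follow the mid-slice convention", {
  st <- slide_stack(rep("HE", 3), 10)
  pos <- slide_positions(st)          # mm
  expect_equal(pos, c(5, 15, 25) / 1000)
  # order matters: positions are not permutation invariant
  st2 <- slide_stack(c("HE", "MT"), c(10, 30))
  expect_equal(slide_positions(st2), c(5, 25) / 1000)
  expect_equal(slide_positions(slide_stack(c("MT", "HE"), c(30, 10))),
               c(15, 35) / 1000)
  expect_true(all(diff(pos) > 0))
  # total span equals the stack length
  expect_equal(pos[3] + 10 / 2000, stack_length(st) / 1000)
  expect_error(slide_positions(st, axis_direction = c(1, 1, 0)), "unit")
})

test_that("length report flags discrepancies and shrinkage", {
  st <- slide_stack(rep("HE", 10), 10)
  r0 <- length_report(st, 100)
  expect_equal(r0$discrepancy_um, 0)
  expect_equal(r0$estimated_missing_slides, 0)
  r1 <- length_report(slide_stack(rep("HE", 9), 10), 100)
  expect_equal(r1$estimated_missing_slides, 1)
  r2 <- length_report(st, 90)
  expect_true(r2$shrinkage_warning)
  expect_lt(r2$discrepancy_um, 0)
  expect_error(length_report(st, -5), "positive")
})

test_that("slide stack configs round-trip from YAML and JSON", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("slides:",
               "- {stain: HE, thickness_um: 10, file: a.png}",
               "- {stain: PLACEHOLDER, thickness_um: 10}",
               "- {stain: MT, thickness_um: 20}"), yml)
  st <- read_slide_stack(yml)
  expect_equal(nrow(st), 3L)
  expect_equal(stack_length(st), 40)
  expect_true(st$placeholder[2])
  jsn <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(slides = list(
    list(stain = "ORO", thickness_um = 5),
    list(stain = "ASMA", thickness_um = 5))), jsn, auto_unbox = TRUE)
  expect_equal(stack_length(read_slide_stack(jsn)), 10)
})

test_that("mesh cross-sections match the analytic circle", {
  ic <- icosphere(3, 3)
  m <- slice_mesh_at_plane(ic, 0, c(0, 0, 1), px_per_mm = 15)
  area_mm2 <- sum(m) / 15^2
  expect_lt(abs(area_mm2 - pi * 9) / (pi * 9), 0.04)
  # off-center slice: radius sqrt(9 - 4)
  m2 <- slice_mesh_at_plane(ic, 2, c(0, 0, 1), px_per_mm = 15)
  expect_lt(abs(sum(m2) / 15^2 - pi * 5) / (pi * 5), 0.06)
  # plane outside the mesh
  m3 <- slice_mesh_at_plane(ic, 5, c(0, 0, 1), px_per_mm = 15)
  expect_equal(sum(m3), 0)
})

test_that("slice areas of a convex phantom are unimodal along the axis", {
  ic <- icosphere(2, 3)
  offs <- seq(-1.8, 1.8, by = 0.3)
  areas <- vapply(offs, function(o)
    sum(slice_mesh_at_plane(ic, o, c(0, 0, 1), px_per_mm = 8)), numeric(1))
  peak <- which.max(areas)
  expect_true(all(diff(areas[seq_len(peak)]) >= 0))
  expect_true(all(diff(areas[peak:length(areas)]) <= 0))
})
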