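#' Histologic slide stack
#'
#' An ordered description of the cut slides, including placeholder entries
#' for removed or failed sections, which occupy thickness but carry no
#' image. The order is the cutting order.
#'
#' @param stain character vector: one of `STAIN_LABELS` or `"PLACEHOLDER"`.
#' @param thickness_um per-slide thickness in micrometres (> 0).
#' @param file optional source filename per slide (`NA` for placeholders).
#' @return data.frame of class `slide_stack`.
#' @export
slide_stack <- function(stain, thickness_um, file = NA_character_) {
  stain <- toupper(as.character(stain))
  ok <- stain %in% c(STAIN_LABELS, "PLACEHOLDER")
  if (!all(ok)) stop("unknown stain label(s): ",
                     paste(unique(stain[!ok]), collapse = ", "))
  if (length(thickness_um) == 1L)
    thickness_um <- rep(thickness_um, length(stain))
  if (any(!is.finite(thickness_um)) || any(thickness_um <= 0))
    stop("slide thickness must be positive")
  df <- data.frame(index = seq_along(stain), stain = stain,
                   thickness_um = as.numeric(thickness_um),
                   file = rep_len(file, length(stain)),
                   placeholder = stain == "PLACEHOLDER",
                   stringsAsFactors = FALSE)
  class(df) <- c("slide_stack", class(df))
  df
}

#' Read a slide stack description from YAML or JSON
#'
#' The config is a list of slide entries with fields `stain`,
#' `thickness_um` and optionally `file`.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A [slide_stack()].
#' @export
read_slide_stack <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- switch(ext,
                yaml = ,
                yml = yaml::read_yaml(path),
                json = jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
                stop("unsupported stack config format: ", ext))
  if (!is.null(lst$slides)) lst <- lst$slides
  slide_stack(
    stain = vapply(lst, function(s) as.character(s$stain), character(1)),
    thickness_um = vapply(lst, function(s) as.numeric(s$thickness_um),
                          numeric(1)),
    file = vapply(lst, function(s)
      if (is.null(s$file)) NA_character_ else as.character(s$file),
      character(1)))
}

#' Total length of the slide stack
#'
#' Sum of all slide thicknesses, placeholders included; comparable to the
#' measured length of the tissue sample.
#'
#' @param stack a [slide_stack()].
#' @return Length in micrometres.
#' @export
stack_length <- function(stack) {
  if (nrow(stack) == 0L) stop("empty slide stack")
  sum(stack$thickness_um)
}

#' Slide plane positions along the cutting axis
#'
#' Mid-slice convention: slide i sits at the cumulative thickness of the
#' preceding slides plus half its own thickness, measured from
#' `axis_origin` along `axis_direction`.
#'
#' @param stack a [slide_stack()].
#' @param axis_origin scalar offset of the first cut (mm).
#' @param axis_direction unit 3-vector of the cutting axis (checked, not
#'   otherwise used for the scalar offsets).
#' @return Numeric vector of strictly increasing plane offsets in mm.
#' @export
slide_positions <- function(stack, axis_origin = 0,
                            axis_direction = c(0, 0, 1)) {
  if (abs(sqrt(sum(axis_direction^2)) - 1) > 1e-6)
    stop("axis_direction must be a unit vector")
  th_mm <- stack$thickness_um / 1000
  axis_origin + cumsum(th_mm) - th_mm / 2
}

#' Compare stack length with the expected sample length
#'
#' Reports the discrepancy between the summed slide thicknesses and the
#' expected tissue length (e.g. measured on the micro-CT model) and a
#' rough estimate of the number of missing slides. A stack longer than the
#' sample is flagged: tissue shrinkage during fixation can shorten the
#' sample relative to the cut thicknesses.
#'
#' @param stack a [slide_stack()].
#' @param expected_length_um expected sample length (micrometres, > 0).
#' @return List of class `length_report` with `stack_length_um`,
#'   `expected_length_um`, `discrepancy_um`, `relative_discrepancy`,
#'   `estimated_missing_slides`, `shrinkage_warning`.
#' @export
length_report <- function(stack, expected_length_um) {
  if (expected_length_um <= 0) stop("expected length must be positive")
  sl <- stack_length(stack)
  disc <- expected_length_um - sl
  med <- stats::median(stack$thickness_um)
  structure(list(
    stack_length_um = sl,
    expected_length_um = expected_length_um,
    discrepancy_um = disc,
    relative_discrepancy = disc / expected_length_um,
    estimated_missing_slides = round(disc / med),
    shrinkage_warning = disc < 0), class = "length_report")
}

#' @export
print.length_report <- function(x, ...) {
  cat(sprintf("stack %.1f um vs expected %.1f um (discrepancy %.1f um, %.1f%%)\n",
              x$stack_length_um, x$expected_length_um, x$discrepancy_um,
              100 * x$relative_discrepancy))
  cat(sprintf("estimated missing slides: %d\n", x$estimated_missing_slides))
  if (x$shrinkage_warning)
    cat("warning: stack longer than sample - possible tissue shrinkage\n")
  invisible(x)
}

plane_basis <- function(axis_direction) {
  a <- axis_direction / sqrt(sum(axis_direction^2))
  ref <- if (abs(a[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- c(a[2] * ref[3] - a[3] * ref[2],
         a[3] * ref[1] - a[1] * ref[3],
         a[1] * ref[2] - a[2] * ref[1])
  u <- u / sqrt(sum(u^2))
  v <- c(a[2] * u[3] - a[3] * u[2],
         a[3] * u[1] - a[1] * u[3],
         a[1] * u[2] - a[2] * u[1])
  list(axis = a, u = u, v = v)
}

#' Rasterized cross-section of a watertight mesh at a cutting plane
#'
#' Fills the interior of the mesh on a pixel grid spanning the mesh
#' bounding box in the cutting plane at `offset` along `axis_direction`
#' (plane through `offset * axis_direction`). Inside/outside is decided by
#' ray parity, so the mesh must be watertight.
#'
#' @param mesh a watertight [triangle_mesh].
#' @param offset plane offset along the axis (mm).
#' @param axis_direction unit 3-vector.
#' @param px_per_mm raster resolution.
#' @param margin_mm extra margin around the projected bounding box.
#' @return A [tissue_mask()] with attributes `origin_mm` (2-vector: plane
#'   coordinates of pixel (1,1)), `px_per_mm`, `basis`.
#' @export
slice_mesh_at_plane <- function(mesh, offset, axis_direction = c(0, 0, 1),
                                px_per_mm = 20, margin_mm = 0.2) {
  stop_if_not_watertight(mesh, "slice_mesh_at_plane")
  b <- plane_basis(axis_direction)
  pu <- mesh$vertices %*% b$u
  pv <- mesh$vertices %*% b$v
  ur <- range(pu) + c(-margin_mm, margin_mm)
  vr <- range(pv) + c(-margin_mm, margin_mm)
  xs <- seq(ur[1], ur[2], by = 1 / px_per_mm)
  ys <- seq(vr[1], vr[2], by = 1 / px_per_mm)
  grid <- expand.grid(u = xs, v = ys)
  pts <- offset * matrix(b$axis, nrow(grid), 3, byrow = TRUE) +
    outer(grid$u, b$u) + outer(grid$v, b$v)
  inside <- cpp_points_in_mesh(pts, mesh$vertices, mesh$faces)
  m <- matrix(as.integer(inside), nrow = length(ys), ncol = length(xs),
              byrow = TRUE)  # rows = v (y), cols = u (x)
  out <- tissue_mask(m)
  attr(out, "origin_mm") <- c(ur[1], vr[1])
  attr(out, "px_per_mm") <- px_per_mm
  attr(out, "basis") <- b
  out
}
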