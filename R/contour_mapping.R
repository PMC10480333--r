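#' Extract the closed boundary contour of a tissue mask
#'
#' Traces the boundary of the largest foreground component as an ordered,
#' counter-clockwise closed polygon (signed area > 0 in (x = col, y = row)
#' coordinates).
#'
#' @param mask a [tissue_mask()] / 0-1 matrix with one foreground component
#'   (the largest is used, with a warning, if there are several).
#' @return `n x 2` matrix of (x, y) pixel coordinates of class `contour`.
#' @export
extract_contour <- function(mask) {
  if (!any(mask != 0)) stop("empty mask: no contour")
  lc <- largest_component(mask)
  if (lc$n_components > 1L)
    warning(sprintf("mask has %d components; tracing the largest",
                    lc$n_components))
  oc <- EBImage::ocontour(as_ebimage(lc$mask))[[1]]
  # ocontour coordinates are 0-based in EBImage's (x=our col, y=our row)
  pts <- cbind(x = oc[, 1] + 1, y = oc[, 2] + 1)
  if (polygon_area(pts) < 0) pts <- pts[rev(seq_len(nrow(pts))), ]
  structure(pts, class = c("contour", class(pts)))
}

#' Signed polygon area (shoelace)
#' @param pts `n x 2` matrix of polygon vertices (closed implicitly).
#' @return Signed area; positive for counter-clockwise orientation.
#' @export
polygon_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

#' Split a contour into inner and outer points
#'
#' The 2D analogue of the mesh vertex classification: the contour center is
#' the mean of the contour points; for each contour point the segment from
#' the center to the point is intersected with the contour polygon. If no
#' intersection besides the point itself exists, the point is directly
#' visible from the center and belongs to the inner contour; otherwise it
#' is an outer point. On a u-shaped tissue band the concave (lumen-facing)
#' arc becomes inner and the far side outer; the center may legitimately
#' lie outside the polygon.
#'
#' @param contour a `contour` matrix from [extract_contour()].
#' @param excl_radius exclusion radius (px) around each point within which
#'   boundary edges do not count as occluders (the point's own location).
#' @return List of class `contour_split`: `contour`, `center`,
#'   `labels` (0 inner / 1 outer per contour point), `inner`, `outer`
#'   (coordinate matrices in contour order).
#' @export
split_contour <- function(contour, excl_radius = 2) {
  pts <- unclass(contour)
  if (nrow(pts) < 3L) stop("contour needs at least 3 points")
  ctr <- colMeans(pts)
  cross <- cpp_center_crossings(ctr, pts, pts, excl_radius)
  labels <- as.integer(cross > 0L)
  structure(list(contour = pts, center = ctr, labels = labels,
                 inner = pts[labels == 0L, , drop = FALSE],
                 outer = pts[labels == 1L, , drop = FALSE]),
            class = "contour_split")
}

# Longest contiguous cyclic run of TRUE; returns ordered indices.
cyclic_runs <- function(flag) {
  n <- length(flag)
  if (all(flag)) return(seq_len(n))
  if (!any(flag)) return(integer(0))
  # rotate so position 1 is FALSE, find runs, map back
  start <- which(!flag)[1]
  rot <- ((seq_len(n) + start - 2L) %% n) + 1L
  f <- flag[rot]
  r <- rle(f)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  true_runs <- which(r$values)
  best <- true_runs[which.max(r$lengths[true_runs])]
  rot[starts[best]:ends[best]]
}

arc_lengths <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  d <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                       pts[-nrow(pts), , drop = FALSE])^2))
  c(0, cumsum(d))
}

# Linear interpolation of an open polyline at arc-length positions s.
interp_polyline <- function(pts, s) {
  al <- arc_lengths(pts)
  x <- stats::approx(al, pts[, 1], xout = s, rule = 2)$y
  y <- stats::approx(al, pts[, 2], xout = s, rule = 2)$y
  cbind(x = x, y = y)
}

#' Build overlapping sections from a contour split
#'
#' The u-shaped tissue outline is divided into `n_sections` overlapping
#' sections, each holding one inner contour point and `outer_per_section`
#' outer contour points. The inner chain is resampled uniformly by arc
#' length to `n_sections` positions; each is paired with the window of
#' `outer_per_section` consecutive outer points centred at the matching
#' relative arc-length position of the outer chain (traversed in the
#' opposite contour direction, so inner and outer run side by side along
#' the tissue). The first and last sections sit at the two u-ends, where
#' the inner-to-outer distance is minimal.
#'
#' @param split a `contour_split`.
#' @param n_sections number of sections (default 5000).
#' @param outer_per_section outer points per section (default 50).
#' @return List of class `section_set`: `inner` (`n_sections x 2` matrix),
#'   `outer_windows` (integer `n_sections x outer_per_section` indices into
#'   `outer_pts`), `outer_pts`, plus the parameters.
#' @export
build_sections <- function(split, n_sections = 5000L,
                           outer_per_section = 50L) {
  inner_run <- cyclic_runs(split$labels == 0L)
  outer_run <- cyclic_runs(split$labels == 1L)
  if (length(inner_run) < 2L) stop("contour split has no usable inner chain")
  if (length(outer_run) < outer_per_section)
    stop("fewer outer contour points than outer_per_section")
  inner_pts <- split$contour[inner_run, , drop = FALSE]
  outer_pts <- split$contour[outer_run, , drop = FALSE]
  # traverse the outer chain opposite to the inner chain so both start at
  # the same u-end (the contour goes inner tip->tip then back along outer)
  outer_pts <- outer_pts[rev(seq_len(nrow(outer_pts))), , drop = FALSE]
  # anchor: section 1 at the u-end with the smaller inner-outer distance
  d_start <- sqrt(sum((inner_pts[1, ] - outer_pts[1, ])^2))
  d_end <- sqrt(sum((inner_pts[nrow(inner_pts), ] -
                       outer_pts[nrow(outer_pts), ])^2))
  if (d_end < d_start) {
    inner_pts <- inner_pts[rev(seq_len(nrow(inner_pts))), , drop = FALSE]
    outer_pts <- outer_pts[rev(seq_len(nrow(outer_pts))), , drop = FALSE]
  }
  al_in <- arc_lengths(inner_pts)
  s_in <- seq(0, al_in[length(al_in)], length.out = n_sections)
  inner_res <- interp_polyline(inner_pts, s_in)
  n_out <- nrow(outer_pts)
  al_out <- arc_lengths(outer_pts)
  total_out <- al_out[n_out]
  # center index of each window at the matching relative arc position
  frac <- if (n_sections > 1L) (seq_len(n_sections) - 1) / (n_sections - 1)
          else 0
  center_s <- frac * total_out
  center_idx <- vapply(center_s, function(s) which.min(abs(al_out - s)),
                       integer(1))
  half <- outer_per_section %/% 2L
  first <- pmin(pmax(center_idx - half, 1L), n_out - outer_per_section + 1L)
  windows <- t(vapply(first, function(f) seq.int(f, f + outer_per_section - 1L),
                      integer(outer_per_section)))
  structure(list(inner = inner_res, outer_windows = windows,
                 outer_pts = outer_pts, n_sections = as.integer(n_sections),
                 outer_per_section = as.integer(outer_per_section)),
            class = "section_set")
}

section_segments <- function(sections) {
  n <- sections$n_sections
  k <- sections$outer_per_section
  idx <- as.vector(t(sections$outer_windows))      # section-major order
  starts <- sections$outer_pts[idx, , drop = FALSE]
  ends <- sections$inner[rep(seq_len(n), each = k), , drop = FALSE]
  list(start = starts, end = ends)
}

#' Transfer image values between two sectioned shapes
#'
#' For each pair of matched sections (same index in the source and target
#' section sets) and each matched line segment (outer point -> inner
#' point), pixel values sampled along the source segment are written along
#' the target segment with arc-length reparameterization, so the value at
#' relative position x along the target segment comes from the same
#' relative position along the source segment. Pixels reached by several
#' overlapping sections store the average of at most `update_cap`
#' contributions, which limits blurring. Pixels outside the target mask are
#' untouched; mask pixels missed by every segment can optionally be filled
#' from their nearest mapped neighbour.
#'
#' @param source RGB raster the values are read from.
#' @param source_sections `section_set` of the source shape.
#' @param target_sections `section_set` of the target shape (same
#'   `n_sections` and `outer_per_section`).
#' @param target_mask [tissue_mask()] of the target shape.
#' @param update_cap maximum contributions per target pixel (default 5).
#' @param fill_gaps fill unmapped mask pixels by nearest mapped value.
#' @return List of class `mapped_image`: `image` (RGB array on the target
#'   grid), `count` (per-pixel contribution count), `n_unmapped`.
#' @export
map_image <- function(source, source_sections, target_sections, target_mask,
                      update_cap = 5L, fill_gaps = TRUE) {
  if (source_sections$n_sections != target_sections$n_sections ||
      source_sections$outer_per_section != target_sections$outer_per_section)
    stop("source and target section sets do not match")
  if (length(dim(source)) == 2L)
    source <- array(rep(source, 3L), c(dim(source), 3L))
  seg_a <- section_segments(source_sections)
  seg_b <- section_segments(target_sections)
  chans <- lapply(1:3, function(c) source[, , c])
  res <- cpp_map_segments(chans, seg_a$start, seg_a$end,
                          seg_b$start, seg_b$end,
                          matrix(as.integer(target_mask != 0),
                                 nrow(target_mask)),
                          as.integer(update_cap), oversample = 2)
  cnt <- res$count
  out <- array(1, c(nrow(target_mask), ncol(target_mask), 3L))
  for (c in 1:3) {
    ch <- res$sums[[c]]
    ch[cnt > 0] <- ch[cnt > 0] / cnt[cnt > 0]
    ch[cnt == 0] <- 1
    out[, , c] <- ch
  }
  unmapped <- which(target_mask != 0 & cnt == 0, arr.ind = TRUE)
  if (fill_gaps && nrow(unmapped) > 0) {
    mapped <- which(cnt > 0, arr.ind = TRUE)
    if (nrow(mapped) > 0) {
      nn <- cpp_nn1(matrix(as.numeric(unmapped), ncol = 2L),
                    matrix(as.numeric(mapped), ncol = 2L))
      for (c in 1:3)
        out[cbind(unmapped, c)] <- out[cbind(mapped[nn, , drop = FALSE], c)]
    }
  }
  structure(list(image = out, count = cnt, n_unmapped = nrow(unmapped)),
            class = "mapped_image")
}

#' Pearson correlation of two images over a mask
#'
#' Product-moment correlation of the luminance values at mask pixels.
#'
#' @param a,b raster arrays on the same grid.
#' @param mask 0/1 matrix on the same grid.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
masked_correlation <- function(a, b, mask) {
  la <- luminance(a); lb <- luminance(b)
  if (!all(dim(la) == dim(lb)) || !all(dim(la) == dim(mask)))
    stop("images and mask must share one pixel grid")
  sel <- mask != 0
  x <- la[sel]; y <- lb[sel]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant image inside mask: correlation undefined")
  stats::cor(x, y)
}

#' Mapping robustness under mask dilation
#'
#' Systematically decreases the similarity between the source shape and the
#' target mask by dilating the mask with disks of increasing radius, maps
#' the source image into each dilated mask and reports the masked
#' correlation against the original image. Radius 0 is the plain
#' self-mapping.
#'
#' @param source RGB raster.
#' @param mask [tissue_mask()] of `source`.
#' @param disk_sizes integer dilation radii (px).
#' @param n_sections,outer_per_section,update_cap see [build_sections()]
#'   and [map_image()].
#' @return data.frame with columns `radius`, `correlation`, `ok` (FALSE
#'   when the dilated mask no longer yields a usable u-shaped split).
#' @export
dilation_robustness_experiment <- function(source, mask,
                                           disk_sizes = c(0L, 5L, 15L, 50L),
                                           n_sections = 5000L,
                                           outer_per_section = 50L,
                                           update_cap = 5L) {
  src_split <- split_contour(extract_contour(mask))
  src_sections <- build_sections(src_split, n_sections, outer_per_section)
  res <- lapply(disk_sizes, function(r) {
    tryCatch({
      dm <- dilate_mask(mask, r)
      tgt_sections <- if (r == 0) src_sections else
        build_sections(split_contour(extract_contour(dm)),
                       n_sections, outer_per_section)
      mapped <- map_image(source, src_sections, tgt_sections, dm, update_cap)
      data.frame(radius = r,
                 correlation = masked_correlation(mapped$image, source, mask),
                 ok = TRUE)
    }, error = function(e) {
      warning(sprintf("radius %d: %s", r, conditionMessage(e)))
      data.frame(radius = r, correlation = NA_real_, ok = FALSE)
    })
  })
  do.call(rbind, res)
}
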