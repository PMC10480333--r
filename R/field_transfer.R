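#' Rigid transform container
#'
#' A 4x4 homogeneous matrix with a pure rotation block (det = +1).
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 vector (mm).
#' @return 4x4 matrix of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  m <- diag(4)
  m[1:3, 1:3] <- rotation
  m[1:3, 4] <- translation
  class(m) <- c("rigid_transform", class(m))
  m
}

#' Apply a rigid transform to a mesh
#'
#' Vertices are mapped by the transform, faces are unchanged, pairwise
#' distances are preserved.
#'
#' @param mesh a [triangle_mesh].
#' @param transform a 4x4 [rigid_transform()] matrix.
#' @return Transformed [triangle_mesh].
#' @export
apply_transform <- function(mesh, transform) {
  R <- transform[1:3, 1:3]
  t3 <- transform[1:3, 4]
  v <- mesh$vertices %*% t(R) + matrix(t3, nrow(mesh$vertices), 3,
                                       byrow = TRUE)
  triangle_mesh(v, mesh$faces)
}

# Best rigid transform source -> target for paired points (Kabsch, SVD).
kabsch <- function(src, tgt) {
  cs <- colMeans(src); ct <- colMeans(tgt)
  H <- t(sweep(src, 2, cs)) %*% sweep(tgt, 2, ct)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(R, ct - as.vector(R %*% cs))
}

principal_axes <- function(v) {
  e <- eigen(stats::cov(v), symmetric = TRUE)
  A <- e$vectors
  if (det(A) < 0) A[, 3] <- -A[, 3]
  A
}

#' Rigid ICP registration of two meshes
#'
#' Point-to-point iterative closest point on the vertex sets: each source
#' vertex is matched to its nearest target vertex, the best rigid transform
#' for the matches is computed in closed form, and the two steps repeat
#' until the RMS closest-point distance converges. Initialization aligns
#' the centroids and, optionally, the principal axes (trying the four
#' sign-consistent axis orientations and keeping the best), since ICP only
#' converges locally.
#'
#' @param source,target [triangle_mesh] objects (vertex clouds are used).
#' @param max_iterations iteration cap.
#' @param tol stop when the RMS improvement falls below `tol` (mm).
#' @param init_axes also align principal axes during initialization.
#' @return List of class `icp_result`: `transform` (4x4), `rms` (final RMS
#'   closest-point distance, mm), `rms_history`, `converged`, `diverged`.
#' @export
icp_register <- function(source, target, max_iterations = 100L, tol = 1e-6,
                         init_axes = TRUE) {
  src0 <- source$vertices
  tgt <- target$vertices
  if (nrow(src0) == 0L || nrow(tgt) == 0L) stop("empty mesh in ICP")
  rms_of <- function(pts) {
    nn <- cpp_nn1(pts, tgt)
    sqrt(mean(rowSums((pts - tgt[nn, , drop = FALSE])^2)))
  }
  cs <- colMeans(src0); ct <- colMeans(tgt)
  inits <- list(rigid_transform(diag(3), ct - cs))
  if (init_axes && nrow(src0) > 3L && nrow(tgt) > 3L) {
    As <- principal_axes(src0); At <- principal_axes(tgt)
    for (sx in c(1, -1)) for (sy in c(1, -1)) {
      S <- diag(c(sx, sy, sx * sy))  # keeps det = +1
      R <- At %*% S %*% t(As)
      inits <- c(inits, list(rigid_transform(R, ct - as.vector(R %*% cs))))
    }
  }
  init_rms <- vapply(inits, function(tr) {
    p <- src0 %*% t(tr[1:3, 1:3]) +
      matrix(tr[1:3, 4], nrow(src0), 3, byrow = TRUE)
    rms_of(p)
  }, numeric(1))
  transform <- inits[[which.min(init_rms)]]
  rms0 <- min(init_rms)
  hist <- numeric(0)
  best <- list(transform = transform, rms = rms0)
  prev <- Inf
  for (it in seq_len(max_iterations)) {
    pts <- src0 %*% t(transform[1:3, 1:3]) +
      matrix(transform[1:3, 4], nrow(src0), 3, byrow = TRUE)
    nn <- cpp_nn1(pts, tgt)
    transform <- kabsch(src0, tgt[nn, , drop = FALSE])
    pts <- src0 %*% t(transform[1:3, 1:3]) +
      matrix(transform[1:3, 4], nrow(src0), 3, byrow = TRUE)
    r <- rms_of(pts)
    hist <- c(hist, r)
    if (r < best$rms) best <- list(transform = transform, rms = r)
    if (is.finite(prev) && abs(prev - r) < tol) break
    prev <- r
  }
  diverged <- best$rms > rms0 + 1e-12
  if (diverged)
    warning("ICP diverged (final RMS above initial); returning best transform")
  structure(list(transform = best$transform, rms = best$rms,
                 rms_history = hist,
                 converged = length(hist) < max_iterations,
                 diverged = diverged),
            class = "icp_result")
}

#' Voxel grid specification
#'
#' @param origin length-3 position of the center of voxel (1,1,1), mm.
#' @param spacing scalar or length-3 voxel edge length, mm.
#' @param dims integer length-3 voxel counts.
#' @return List of class `voxel_grid`.
#' @export
voxel_grid <- function(origin, spacing, dims) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L)) stop("dims must be 3 positive ints")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("spacing must be positive")
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 dims = dims), class = "voxel_grid")
}

voxel_centers <- function(grid) {
  xs <- grid$origin[1] + (seq_len(grid$dims[1]) - 1L) * grid$spacing[1]
  ys <- grid$origin[2] + (seq_len(grid$dims[2]) - 1L) * grid$spacing[2]
  zs <- grid$origin[3] + (seq_len(grid$dims[3]) - 1L) * grid$spacing[3]
  as.matrix(expand.grid(x = xs, y = ys, z = zs))
}

#' Bounding voxel grid of a mesh
#' @param mesh a [triangle_mesh].
#' @param spacing voxel size (mm).
#' @param margin_mm margin around the bounding box.
#' @return A [voxel_grid()].
#' @export
mesh_voxel_grid <- function(mesh, spacing, margin_mm = 0) {
  lo <- apply(mesh$vertices, 2, min) - margin_mm
  hi <- apply(mesh$vertices, 2, max) + margin_mm
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  voxel_grid(lo, spacing, dims)
}

#' Assign a per-vertex scalar field to the voxels of a grid
#'
#' Every voxel center receives the value of the Euclidean-nearest mesh
#' vertex (ties go to the lowest vertex index); no interpolation, so the
#' output range is a subset of the field range.
#'
#' @param mesh a [triangle_mesh].
#' @param field numeric per-vertex values.
#' @param grid a [voxel_grid()].
#' @return 3D array `dims[1] x dims[2] x dims[3]` with attribute `grid`.
#' @export
assign_field_to_voxels <- function(mesh, field, grid) {
  if (length(field) != nrow(mesh$vertices))
    stop("field length does not match mesh vertex count")
  centers <- voxel_centers(grid)
  nn <- cpp_nn1(centers, mesh$vertices)
  vol <- array(field[nn], dim = grid$dims)
  attr(vol, "grid") <- grid
  vol
}

#' Planar slice of a voxel volume
#'
#' Resamples the volume (nearest voxel) on a pixel grid lying in the plane
#' at `offset` along `axis_direction`, for overlay with the 2D histology
#' mapping.
#'
#' @param volume 3D array with a `grid` attribute (see
#'   [assign_field_to_voxels()]), or pass `grid` explicitly.
#' @param offset plane offset along the axis (mm).
#' @param axis_direction unit 3-vector.
#' @param px_per_mm raster resolution.
#' @param grid the [voxel_grid()] of `volume` if not attached.
#' @return Numeric matrix (`NA` outside the volume) with attributes
#'   `origin_mm`, `px_per_mm`.
#' @export
field_to_slice <- function(volume, offset, axis_direction = c(0, 0, 1),
                           px_per_mm = 20, grid = attr(volume, "grid")) {
  if (is.null(grid)) stop("volume has no grid attribute; pass `grid`")
  b <- plane_basis(axis_direction)
  corners <- voxel_centers(voxel_grid(grid$origin,
                                      grid$spacing * pmax(grid$dims - 1L, 1L),
                                      c(2L, 2L, 2L)))
  pu <- corners %*% b$u; pv <- corners %*% b$v
  xs <- seq(min(pu), max(pu), by = 1 / px_per_mm)
  ys <- seq(min(pv), max(pv), by = 1 / px_per_mm)
  gridx <- expand.grid(u = xs, v = ys)
  pts <- offset * matrix(b$axis, nrow(gridx), 3, byrow = TRUE) +
    outer(gridx$u, b$u) + outer(gridx$v, b$v)
  idx <- sweep(pts, 2, grid$origin)
  idx <- round(sweep(idx, 2, grid$spacing, "/")) + 1L
  ok <- idx[, 1] >= 1 & idx[, 1] <= grid$dims[1] &
    idx[, 2] >= 1 & idx[, 2] <= grid$dims[2] &
    idx[, 3] >= 1 & idx[, 3] <= grid$dims[3]
  vals <- rep(NA_real_, nrow(idx))
  vals[ok] <- volume[idx[ok, , drop = FALSE]]
  m <- matrix(vals, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  attr(m, "origin_mm") <- c(min(pu), min(pv))
  attr(m, "px_per_mm") <- px_per_mm
  m
}

#' Write / read a 3D volume as a multi-page TIFF stack or NIfTI
#'
#' TIFF pages are the third array index; values are min-max normalized to
#' `[0, 1]` for TIFF (the range is stored in a sidecar JSON), NIfTI keeps
#' raw values.
#'
#' @param volume 3D numeric array.
#' @param path `.tif`/`.tiff` or `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("package 'tiff' needed for TIFF volumes")
    rng <- range(volume)
    den <- if (diff(rng) > 0) diff(rng) else 1
    pages <- lapply(seq_len(dim(volume)[3]),
                    function(k) (volume[, , k] - rng[1]) / den)
    tiff::writeTIFF(pages, path)
    jsonlite::write_json(list(min = rng[1], max = rng[2]),
                         paste0(path, ".json"), auto_unbox = TRUE)
  } else if (ext == "nii") {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("package 'RNifti' needed for NIfTI volumes")
    RNifti::writeNifti(RNifti::asNifti(volume), path)
  } else stop("unsupported volume format: ", ext)
  invisible(path)
}

#' Write a rigid transform as 4x4 matrix JSON
#' @param transform 4x4 matrix.
#' @param path output JSON path.
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(list(matrix = unclass(transform)), path,
                       digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  m <- jsonlite::fromJSON(path)$matrix
  out <- matrix(as.numeric(m), 4, 4)
  class(out) <- c("rigid_transform", class(out))
  out
}
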