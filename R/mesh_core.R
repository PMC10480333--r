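#' Triangle surface mesh
#'
#' Minimal container for a triangle surface mesh in millimetres: an `n x 3`
#' numeric matrix of vertex positions and an `m x 3` integer matrix of
#' 1-based vertex indices per face. Operations that need a well-defined
#' interior (enclosed volume, visibility-based labelling) additionally
#' require the mesh to be watertight, i.e. every edge shared by exactly two
#' faces.
#'
#' @param vertices numeric matrix (`n x 3`), coordinates in mm.
#' @param faces integer matrix (`m x 3`), 1-based vertex indices.
#' @return An object of class `triangle_mesh` with elements `vertices` and
#'   `faces`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (nrow(vertices) < 1L) stop("mesh must have at least one vertex")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (length(faces) && ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (length(faces) && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bbox [mm]: x %.3f..%.3f  y %.3f..%.3f  z %.3f..%.3f\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "-")

#' Boundary edges of a mesh
#'
#' Edges that are not shared by exactly two faces. A watertight mesh has
#' none.
#'
#' @param mesh a [triangle_mesh].
#' @return Character vector of offending edge keys `"i-j"` (empty if
#'   watertight).
#' @export
boundary_edges <- function(mesh) {
  f <- mesh$faces
  e <- edge_key(c(f[, 1], f[, 2], f[, 3]), c(f[, 2], f[, 3], f[, 1]))
  tab <- table(e)
  names(tab)[tab != 2L]
}

#' Test whether a mesh is watertight
#' @param mesh a [triangle_mesh].
#' @return Logical scalar.
#' @export
is_watertight <- function(mesh) {
  nrow(mesh$faces) > 0L && length(boundary_edges(mesh)) == 0L
}

stop_if_not_watertight <- function(mesh, what) {
  be <- boundary_edges(mesh)
  if (nrow(mesh$faces) == 0L || length(be) > 0L) {
    shown <- paste(utils::head(be, 10L), collapse = ", ")
    stop(sprintf(
      "%s requires a watertight mesh; %d boundary/non-manifold edges (%s%s)",
      what, length(be), shown, if (length(be) > 10L) ", ..." else ""))
  }
  invisible(TRUE)
}

#' Mesh center
#'
#' Arithmetic mean of the vertex positions. This is the reference point `C`
#' from which the visibility-based inner/outer labelling casts its segments.
#'
#' @param mesh a [triangle_mesh].
#' @return Numeric length-3 point (mm).
#' @export
mesh_center <- function(mesh) {
  if (nrow(mesh$vertices) < 1L) stop("mesh has no vertices")
  colMeans(mesh$vertices)
}

#' Enclosed volume of a watertight mesh
#'
#' Divergence-theorem (signed tetrahedra) volume, returned as an absolute
#' value so face winding does not matter.
#'
#' @param mesh a watertight, consistently oriented [triangle_mesh].
#' @return Volume in mm^3.
#' @export
enclosed_volume <- function(mesh) {
  stop_if_not_watertight(mesh, "enclosed_volume")
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  det6 <- a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
    a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
    a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])
  abs(sum(det6)) / 6
}

#' Vertex labelling helper
#'
#' Validates a per-vertex inner(0)/outer(1) labelling against a mesh.
#' @param labels integer vector of 0/1.
#' @param mesh a [triangle_mesh].
#' @return The labelling as an integer vector.
#' @export
vertex_labeling <- function(labels, mesh) {
  labels <- as.integer(labels)
  if (length(labels) != nrow(mesh$vertices))
    stop("labelling length must equal vertex count")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0 (inner) or 1 (outer)")
  labels
}

#' Classify mesh vertices as inner (lumen-facing) or outer
#'
#' A vertex is inner (label 0) when the open segment between it and the mesh
#' center contains no point interior to the watertight wall mesh, i.e. the
#' vertex is directly visible from the center through the cavity. The
#' interior test is a segment-triangle intersection with the segment shrunk
#' by a small fraction at the vertex end so the vertex's own incident faces
#' never count as occluders. If the center itself lies inside the enclosed
#' material (as for a solid convex body) every segment starts in the
#' interior and all vertices are outer.
#'
#' @param mesh a watertight [triangle_mesh] of the wall.
#' @param eps fraction of the segment length shaved off at the vertex end.
#' @return Integer vector of labels: 0 = inner, 1 = outer.
#' @export
classify_inner_outer <- function(mesh, eps = 1e-6) {
  stop_if_not_watertight(mesh, "classify_inner_outer")
  v <- mesh$vertices
  n <- nrow(v)
  ctr <- mesh_center(mesh)
  # degenerate zero-thickness shell: no interior at all -> everything inner
  diam <- sqrt(sum((apply(v, 2, max) - apply(v, 2, min))^2))
  if (enclosed_volume(mesh) < 1e-12 * diam^3) return(rep(0L, n))
  center_inside <- cpp_points_in_mesh(matrix(ctr, 1, 3), v, mesh$faces)[1]
  if (center_inside) return(rep(1L, n))
  p0 <- matrix(ctr, n, 3, byrow = TRUE)
  # shrink at the vertex end: stop just short of the vertex itself
  p1 <- v - eps * (v - p0)
  hit <- cpp_segments_hit_mesh(p0, p1, v, mesh$faces)
  as.integer(hit)
}

vertex_adjacency <- function(mesh) {
  f <- mesh$faces
  i <- c(f[, 1], f[, 2], f[, 3], f[, 2], f[, 3], f[, 1])
  j <- c(f[, 2], f[, 3], f[, 1], f[, 1], f[, 2], f[, 3])
  keep <- !duplicated(paste(i, j))
  split(j[keep], factor(i[keep], levels = seq_len(nrow(mesh$vertices))))
}

#' Majority-vote refinement of an inner/outer labelling
#'
#' Each vertex takes the majority label among its edge neighbours; ties and
#' isolated vertices keep the current label. Vertices are updated
#' sequentially in index order and passes repeat until a fixed point (or
#' `max_passes`).
#'
#' @param mesh a [triangle_mesh].
#' @param labels integer 0/1 labelling (see [vertex_labeling()]).
#' @param max_passes maximum number of full sweeps (default 100).
#' @param single_pass if `TRUE`, perform exactly one sweep.
#' @return Refined integer labelling.
#' @export
refine_labels <- function(mesh, labels, max_passes = 100L,
                          single_pass = FALSE) {
  labels <- vertex_labeling(labels, mesh)
  adj <- vertex_adjacency(mesh)
  n <- length(labels)
  passes <- if (single_pass) 1L else max_passes
  for (p in seq_len(passes)) {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- adj[[i]]
      if (length(nb) == 0L) next
      ones <- sum(labels[nb])
      maj <- if (2L * ones > length(nb)) 1L
             else if (2L * ones < length(nb)) 0L
             else labels[i]  # tie keeps current label
      if (maj != labels[i]) {
        labels[i] <- maj
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  labels
}

#' Wall thickness estimate from an inner/outer labelling
#'
#' For each vertex, the Euclidean distance to the nearest vertex of the
#' opposite class, a simple proxy of local wall thickness.
#'
#' @param mesh a [triangle_mesh].
#' @param labels integer 0/1 labelling containing both classes.
#' @return Numeric per-vertex thickness field (mm).
#' @export
wall_thickness <- function(mesh, labels) {
  labels <- vertex_labeling(labels, mesh)
  if (length(unique(labels)) < 2L)
    stop("wall_thickness needs both inner and outer vertices")
  v <- mesh$vertices
  inner <- v[labels == 0L, , drop = FALSE]
  outer <- v[labels == 1L, , drop = FALSE]
  thick <- numeric(nrow(v))
  i0 <- labels == 0L
  nn_o <- cpp_nn1(v[i0, , drop = FALSE], outer)
  thick[i0] <- sqrt(rowSums((v[i0, , drop = FALSE] -
                               outer[nn_o, , drop = FALSE])^2))
  nn_i <- cpp_nn1(v[!i0, , drop = FALSE], inner)
  thick[!i0] <- sqrt(rowSums((v[!i0, , drop = FALSE] -
                                inner[nn_i, , drop = FALSE])^2))
  thick
}

#' Read and write per-vertex scalar fields
#'
#' Scalar fields (WSS in Pa, thickness in mm, ...) are stored as a 2-column
#' CSV `vertex_index,value` with 1-based indices.
#'
#' @param path CSV file path.
#' @param mesh optional [triangle_mesh] used to validate the length.
#' @return Numeric vector ordered by vertex index.
#' @export
read_scalar_field <- function(path, mesh = NULL) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2L) stop("scalar field CSV needs columns vertex_index,value")
  ord <- order(df[[1L]])
  vals <- as.numeric(df[[2L]][ord])
  if (!all(is.finite(vals))) stop("scalar field values must be finite")
  if (!is.null(mesh) && length(vals) != nrow(mesh$vertices))
    stop("scalar field length does not match mesh vertex count")
  vals
}

#' @rdname read_scalar_field
#' @param values numeric per-vertex values.
#' @export
write_scalar_field <- function(values, path) {
  utils::write.csv(
    data.frame(vertex_index = seq_along(values), value = values),
    path, row.names = FALSE)
  invisible(path)
}
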