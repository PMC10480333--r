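#' Read a triangle mesh from STL, PLY or OBJ
#'
#' Format is chosen from the file extension. STL may be binary or ASCII;
#' PLY must be ASCII; OBJ supports triangle (or fanned polygon) faces.
#' STL files carry no connectivity, so coincident vertices are merged on
#' read to restore a shared-vertex mesh.
#'
#' @param path file path ending in `.stl`, `.ply` or `.obj`.
#' @return A [triangle_mesh].
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = read_stl(path),
         ply = read_ply(path),
         obj = read_obj(path),
         stop("unsupported mesh format: ", ext))
}

#' Write a triangle mesh to STL (ASCII), PLY (ASCII) or OBJ
#'
#' @param mesh a [triangle_mesh].
#' @param path output path; extension selects the format.
#' @param vertex_attr optional named list of per-vertex numeric attributes,
#'   written as extra vertex properties (PLY only).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, vertex_attr = NULL) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = write_stl_ascii(mesh, path),
         ply = write_ply(mesh, path, vertex_attr),
         obj = write_obj(mesh, path),
         stop("unsupported mesh format: ", ext))
  invisible(path)
}

merge_coincident_vertices <- function(V, F, digits = 9L) {
  key <- paste(round(V[, 1], digits), round(V[, 2], digits),
               round(V[, 3], digits))
  idx <- match(key, unique(key))
  keep <- !duplicated(key)
  Fm <- matrix(idx[F], ncol = 3L)
  triangle_mesh(V[keep, , drop = FALSE], Fm)
}

read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  head5 <- readBin(con, "raw", 5L)
  is_ascii <- identical(rawToChar(head5), "solid")
  if (is_ascii) {
    # could still be binary with a header starting 'solid'; check for 'facet'
    txt <- tryCatch(readLines(path, warn = FALSE), error = function(e) NULL)
    if (!is.null(txt) && any(grepl("facet", txt, fixed = TRUE)))
      return(read_stl_ascii(txt))
    close(con); con <- file(path, "rb"); on.exit(close(con))
  }
  seek(con, 80L)
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  rec <- readBin(con, "raw", ntri * 50L)
  m <- matrix(rec, nrow = 50L)
  vals <- vapply(seq_len(ntri), function(i)
    readBin(m[1:48, i], "numeric", 12L, size = 4L, endian = "little"),
    numeric(12L))
  vals <- t(vals)  # ntri x 12: normal, v1, v2, v3
  V <- rbind(vals[, 4:6, drop = FALSE], vals[, 7:9, drop = FALSE],
             vals[, 10:12, drop = FALSE])
  ord <- as.vector(t(matrix(seq_len(3L * ntri), ncol = 3L)))
  V <- V[ord, , drop = FALSE]
  F <- matrix(seq_len(3L * ntri), ncol = 3L, byrow = TRUE)
  merge_coincident_vertices(V, F)
}

read_stl_ascii <- function(lines) {
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(x)
    as.numeric(x[2:4]))
  V <- do.call(rbind, nums)
  if (nrow(V) %% 3L != 0L) stop("malformed ASCII STL")
  F <- matrix(seq_len(nrow(V)), ncol = 3L, byrow = TRUE)
  merge_coincident_vertices(V, F)
}

write_stl_ascii <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid mesh", con)
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; c3 <- v[f[i, 3], ]
    n <- c((b[2] - a[2]) * (c3[3] - a[3]) - (b[3] - a[3]) * (c3[2] - a[2]),
           (b[3] - a[3]) * (c3[1] - a[1]) - (b[1] - a[1]) * (c3[3] - a[3]),
           (b[1] - a[1]) * (c3[2] - a[2]) - (b[2] - a[2]) * (c3[1] - a[1]))
    nl <- sqrt(sum(n^2)); if (nl > 0) n <- n / nl
    writeLines(c(
      sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
      "    outer loop",
      sprintf("      vertex %.9g %.9g %.9g", a[1], a[2], a[3]),
      sprintf("      vertex %.9g %.9g %.9g", b[1], b[2], b[3]),
      sprintf("      vertex %.9g %.9g %.9g", c3[1], c3[2], c3[3]),
      "    endloop",
      "  endfacet"), con)
  }
  writeLines("endsolid mesh", con)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!startsWith(lines[1], "ply")) stop("not a PLY file")
  end <- match("end_header", trimws(lines))
  header <- trimws(lines[seq_len(end)])
  if (any(grepl("^format binary", header)))
    stop("only ASCII PLY is supported")
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", header, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", header, value = TRUE)[1]))
  body <- lines[(end + 1L):length(lines)]
  vlines <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  V <- t(vapply(vlines, function(x) as.numeric(x[1:3]), numeric(3L)))
  flines <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  F <- t(vapply(flines, function(x) as.integer(x[2:4]) + 1L, integer(3L)))
  triangle_mesh(V, F)
}

write_ply <- function(mesh, path, vertex_attr = NULL) {
  v <- mesh$vertices
  f <- mesh$faces
  attr_names <- names(vertex_attr)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               if (length(attr_names))
                 sprintf("property float %s", attr_names),
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  vm <- v
  for (a in attr_names) vm <- cbind(vm, vertex_attr[[a]])
  writeLines(apply(vm, 1L, function(r)
    paste(sprintf("%.9g", r), collapse = " ")), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
             con)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- strsplit(trimws(grep("^v ", lines, value = TRUE)), "\\s+")
  V <- t(vapply(vl, function(x) as.numeric(x[2:4]), numeric(3L)))
  fl <- strsplit(trimws(grep("^f ", lines, value = TRUE)), "\\s+")
  F <- do.call(rbind, lapply(fl, function(x) {
    idx <- as.integer(sub("/.*", "", x[-1L]))
    if (length(idx) == 3L) matrix(idx, 1L)
    else t(vapply(2:(length(idx) - 1L),
                  function(k) c(idx[1L], idx[k], idx[k + 1L]), integer(3L)))
  }))
  triangle_mesh(V, F)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices
  writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  f <- mesh$faces
  writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
}
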