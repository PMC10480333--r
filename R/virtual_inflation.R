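#' Configuration for virtual inflation
#'
#' @param k_target number of closest target (lumen) vertices whose centroid
#'   attracts each inner vertex.
#' @param k_inner number of closest inner vertices whose mean displacement
#'   drives each outer vertex.
#' @param step_fraction fraction of the remaining displacement applied per
#'   iteration, in (0, 1]. Damped steps avoid oscillation around the target.
#' @param max_iterations iteration cap.
#' @param convergence_tol stop when the largest inner-vertex move in an
#'   iteration falls below this (mm).
#' @return A list of class `inflation_config`.
#' @export
inflation_config <- function(k_target = 5L, k_inner = 5L,
                             step_fraction = 0.5, max_iterations = 200L,
                             convergence_tol = 1e-3) {
  stopifnot(k_target >= 1L, k_inner >= 1L,
            step_fraction > 0, step_fraction <= 1, convergence_tol > 0)
  structure(list(k_target = as.integer(k_target),
                 k_inner = as.integer(k_inner),
                 step_fraction = step_fraction,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol),
            class = "inflation_config")
}

#' Virtually inflate a resected dome mesh toward the preoperative lumen
#'
#' The resected dome collapses after explantation. Inflation restores its
#' in-vivo shape using the preoperative lumen surface as the ground truth
#' for the amount of inflation: per iteration every inner (lumen-facing)
#' vertex moves a damped step toward the centroid of its `k_target` nearest
#' target-mesh vertices, and every outer vertex moves by the average
#' displacement of its `k_inner` nearest inner vertices so the local wall
#' thickness is maintained. Connectivity is untouched.
#'
#' @param dome deflated dome [triangle_mesh].
#' @param labels inner(0)/outer(1) labelling of `dome`, e.g. from
#'   [classify_inner_outer()] + [refine_labels()].
#' @param target preoperative lumen [triangle_mesh].
#' @param cfg an [inflation_config()].
#' @return The inflated [triangle_mesh], with an attribute `history`: a
#'   data.frame with one row per iteration (max/RMS inner displacement in
#'   the iteration, RMS distance of inner vertices to the nearest target
#'   vertex) and, when the mesh is watertight, attribute `volume` with the
#'   enclosed volume before/after.
#' @export
inflate_dome <- function(dome, labels, target, cfg = inflation_config()) {
  labels <- vertex_labeling(labels, dome)
  if (!any(labels == 0L)) stop("labelling has no inner vertices")
  if (nrow(target$vertices) < cfg$k_target)
    stop("target mesh has fewer vertices than k_target")
  v <- dome$vertices
  inner_idx <- which(labels == 0L)
  outer_idx <- which(labels == 1L)
  tv <- target$vertices
  hist_max <- hist_rms <- hist_dist <- numeric(0)
  for (it in seq_len(cfg$max_iterations)) {
    vi <- v[inner_idx, , drop = FALSE]
    nn <- cpp_knn(vi, tv, cfg$k_target)
    goal <- vapply(seq_len(3L), function(d) {
      m <- matrix(tv[nn, d], nrow = nrow(nn))
      rowMeans(m)
    }, numeric(nrow(nn)))
    disp <- cfg$step_fraction * (goal - vi)
    if (length(outer_idx)) {
      k_in <- min(cfg$k_inner, length(inner_idx))
      nn_in <- cpp_knn(v[outer_idx, , drop = FALSE], vi, k_in)
      disp_out <- vapply(seq_len(3L), function(d) {
        m <- matrix(disp[nn_in, d], nrow = nrow(nn_in))
        rowMeans(m)
      }, numeric(nrow(nn_in)))
      v[outer_idx, ] <- v[outer_idx, , drop = FALSE] + disp_out
    }
    v[inner_idx, ] <- vi + disp
    mag <- sqrt(rowSums(disp^2))
    hist_max <- c(hist_max, max(mag))
    hist_rms <- c(hist_rms, sqrt(mean(mag^2)))
    d_t <- v[inner_idx, , drop = FALSE] -
      tv[cpp_nn1(v[inner_idx, , drop = FALSE], tv), , drop = FALSE]
    hist_dist <- c(hist_dist, sqrt(mean(rowSums(d_t^2))))
    if (max(mag) < cfg$convergence_tol) break
  }
  out <- triangle_mesh(v, dome$faces)
  attr(out, "history") <- data.frame(
    iteration = seq_along(hist_max),
    max_displacement = hist_max,
    rms_displacement = hist_rms,
    rms_dist_to_target = hist_dist)
  if (is_watertight(dome)) {
    attr(out, "volume") <- c(before = enclosed_volume(dome),
                             after = enclosed_volume(out))
  }
  out
}
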