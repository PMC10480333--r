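# Seeded phantom generators for every input the pipeline consumes, with
# ground truth, so the whole pipeline runs without clinical data.

icosahedron <- function() {
  p <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, p, 0), c(1, p, 0), c(-1, -p, 0), c(1, -p, 0),
             c(0, -1, p), c(0, 1, p), c(0, -1, -p), c(0, 1, -p),
             c(p, 0, -1), c(p, 0, 1), c(-p, 0, -1), c(-p, 0, 1))
  v <- v / sqrt(1 + p^2)
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(v = v, f = f)
}

#' Icosphere mesh
#'
#' Subdivided icosahedron projected onto a sphere; watertight and
#' consistently oriented.
#'
#' @param radius sphere radius (mm).
#' @param subdivisions number of 4-to-1 triangle subdivisions (0 = plain
#'   icosahedron; 3 gives 642 vertices).
#' @param center length-3 sphere center.
#' @return A [triangle_mesh].
#' @export
icosphere <- function(radius = 1, subdivisions = 3L, center = c(0, 0, 0)) {
  ico <- icosahedron()
  v <- ico$v
  f <- ico$f
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env(hash = TRUE)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      m <- (v[a, ] + v[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 4L * nrow(f), 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c3 <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      nf[4L * i - 3L, ] <- c(a, ab, ca)
      nf[4L * i - 2L, ] <- c(b, bc, ab)
      nf[4L * i - 1L, ] <- c(c3, ca, bc)
      nf[4L * i, ] <- c(ab, bc, ca)
    }
    f <- nf
  }
  triangle_mesh(v * radius + matrix(center, nrow(v), 3, byrow = TRUE), f)
}

# Faces of a pole-capped lat-long grid: pole vertex index + n_rings x n_seg
# ring index matrix. flip reverses the winding.
cap_faces <- function(pole, rings, flip = FALSE) {
  n_rings <- nrow(rings); n_seg <- ncol(rings)
  jp <- c(2:n_seg, 1L)
  out <- list(cbind(pole, rings[1L, ], rings[1L, jp]))
  for (i in seq_len(n_rings - 1L)) {
    a <- rings[i, ]; b <- rings[i, jp]
    c3 <- rings[i + 1L, ]; d <- rings[i + 1L, jp]
    out <- c(out, list(cbind(a, c3, d), cbind(a, d, b)))
  }
  f <- do.call(rbind, out)
  if (flip) f <- f[, c(1L, 3L, 2L)]
  f
}

# Area of a surface of revolution r(theta) about the z axis,
# theta in [0, pi/2], from a dense sampled radius profile.
revolution_area <- function(r_fun, n = 2000L) {
  th <- seq(0, pi / 2, length.out = n)
  r <- r_fun(th)
  dr <- c(diff(r) / diff(th), 0)
  dr[n] <- dr[n - 1L]
  sum(2 * pi * r * sin(th) * sqrt(r^2 + dr^2) * (pi / 2) / (n - 1L))
}

#' Deflated-dome phantom with lumen target and ground truth
#'
#' Emulates a resected aneurysm dome: a watertight bowl-shaped shell (a
#' hemispherical wall of constant thickness, closed by a rim band)
#' together with the preoperative lumen surface it should be inflated
#' toward. Deflation is modelled as inward radial buckling: the cap is
#' compressed radially by a smooth dimple `r(theta) = r0 (1 - d
#' exp(-(theta/w)^2))`, deepest at the pole (depth `0.45 *
#' deflation_factor` of the radius) and vanishing at the rim. Because a
#' thin tissue wall bends far more easily than it stretches, collapse is
#' near-isometric; the dimple width `w` is therefore solved at
#' construction time so the deflated inner surface keeps the area of the
#' undeformed lumen hemisphere. The outer surface is the constant-distance
#' normal offset of the inner surface, so the ground-truth wall thickness
#' is `wall_thickness` everywhere. At `deflation_factor -> 0` the dome
#' equals the undeformed shell.
#'
#' @param outer_radius outer wall radius of the undeformed dome (mm).
#' @param wall_thickness wall thickness (mm), < `outer_radius`.
#' @param deflation_factor fraction in [0, 1): 0 = undeformed, larger =
#'   deeper collapse (0.8 dents the pole to ~64% of its radius).
#' @param mesh_resolution azimuthal segments of the dome grid.
#' @param target_subdivisions icosphere subdivisions of the lumen target.
#' @param seed RNG seed (used for the optional `noise_mm` jitter).
#' @param noise_mm sd of seeded Gaussian vertex jitter (default 0).
#' @return List: `dome` (deflated shell [triangle_mesh]), `target` (lumen
#'   icosphere of radius `outer_radius - wall_thickness`), `labels`
#'   (ground-truth inner/outer per dome vertex), `thickness` (ground-truth
#'   wall thickness per vertex, mm), `undeformed` (the shell at
#'   deflation 0).
#' @export
generate_dome_phantom <- function(outer_radius = 5, wall_thickness = 0.5,
                                  deflation_factor = 0.8,
                                  mesh_resolution = 48L,
                                  target_subdivisions = 3L,
                                  seed = 1L, noise_mm = 0) {
  stopifnot(deflation_factor >= 0, deflation_factor < 1,
            wall_thickness > 0, wall_thickness < outer_radius)
  set.seed(seed)
  R <- outer_radius
  t <- wall_thickness
  r_lumen <- R - t
  depth <- 0.45 * deflation_factor
  dent_width <- if (depth > 1e-9) {
    # near-isometric collapse: pick the dimple width that preserves the
    # inner-surface area (bending, not stretching)
    target_area <- 2 * pi * r_lumen^2
    obj <- function(w) {
      revolution_area(function(th)
        r_lumen * (1 - depth * exp(-(th / w)^2))) - target_area
    }
    lo <- 0.08; hi <- 1.5
    if (obj(lo) > 0 && obj(hi) < 0) stats::uniroot(obj, c(lo, hi))$root
    else 0.35  # fallback width; area then only approximately preserved
  } else Inf
  build_shell <- function(df) {
    dent <- function(th) {
      if (df <= 0) rep(0, length(th))
      else depth * exp(-(th / dent_width)^2)
    }
    n_seg <- as.integer(mesh_resolution)
    n_rings <- max(3L, as.integer(round(n_seg / 2)))
    thetas <- (pi / 2) * seq_len(n_rings) / n_rings
    phis <- 2 * pi * (seq_len(n_seg) - 1L) / n_seg
    # inner meridian (lateral s, axial z) and its outward unit normal
    th_all <- c(0, thetas)
    r_in <- r_lumen * (1 - dent(th_all))
    s_in <- r_in * sin(th_all)
    z_in <- r_in * cos(th_all)
    ds <- stats::splinefun(th_all, s_in)(th_all, deriv = 1L)
    dz <- stats::splinefun(th_all, z_in)(th_all, deriv = 1L)
    len <- sqrt(ds^2 + dz^2)
    nrm_s <- dz / len
    nrm_z <- -ds / len
    flipn <- (nrm_s * s_in + nrm_z * z_in) < 0
    nrm_s[flipn] <- -nrm_s[flipn]
    nrm_z[flipn] <- -nrm_z[flipn]
    nrm_s[1] <- 0; nrm_z[1] <- 1   # pole normal is axial
    s_out <- s_in + t * nrm_s
    z_out <- z_in + t * nrm_z
    ring_pts <- function(s, z) {
      do.call(rbind, lapply(seq_along(s), function(i)
        cbind(s[i] * cos(phis), s[i] * sin(phis), z[i])))
    }
    vo <- rbind(c(0, 0, z_out[1]), ring_pts(s_out[-1], z_out[-1]))
    vi <- rbind(c(0, 0, z_in[1]), ring_pts(s_in[-1], z_in[-1]))
    nvo <- nrow(vo)
    V <- rbind(vo, vi)
    ring_idx <- function(off) {
      matrix(off + 1L + seq_len(n_rings * n_seg), n_rings, n_seg,
             byrow = TRUE)
    }
    ro <- ring_idx(0L)
    ri <- ring_idx(nvo)
    f_out <- cap_faces(1L, ro)
    f_in <- cap_faces(nvo + 1L, ri, flip = TRUE)
    # rim band between the two boundary rings
    a <- ro[n_rings, ]; b <- ro[n_rings, c(2:n_seg, 1L)]
    c3 <- ri[n_rings, ]; d <- ri[n_rings, c(2:n_seg, 1L)]
    f_rim <- rbind(cbind(a, d, b), cbind(a, c3, d))
    labels <- c(rep(1L, nvo), rep(0L, nrow(vi)))
    if (noise_mm > 0) V <- V + matrix(stats::rnorm(length(V), 0, noise_mm),
                                      nrow(V), 3L)
    list(mesh = triangle_mesh(V, rbind(f_out, f_in, f_rim)),
         labels = labels)
  }
  shell <- build_shell(deflation_factor)
  undef <- build_shell(0)
  list(dome = shell$mesh,
       target = icosphere(r_lumen, target_subdivisions),
       labels = shell$labels,
       thickness = rep(t, nrow(shell$mesh$vertices)),
       undeformed = undef$mesh)
}

#' Stain palettes of the synthetic histology phantom
#'
#' Base tissue and accent (texture blob) colours per stain, plus the slide
#' background and scanner padding colours. Chosen to mimic the visual
#' character of the stains (H&E pink/purple, MT blue/red, ORO pale with
#' red lipid droplets, aSMA tan/brown) while being linearly separable in
#' colour space.
#'
#' @param stain one of `STAIN_LABELS`.
#' @return List with `base`, `accent`, `background`, `padding` RGB triples
#'   in `[0, 1]`.
#' @export
stain_palette <- function(stain) {
  stain <- match.arg(stain, STAIN_LABELS)
  pal <- list(
    HE = list(base = c(0.80, 0.52, 0.68), accent = c(0.38, 0.22, 0.55)),
    MT = list(base = c(0.45, 0.50, 0.78), accent = c(0.72, 0.25, 0.38)),
    ORO = list(base = c(0.88, 0.80, 0.74), accent = c(0.78, 0.12, 0.12)),
    ASMA = list(base = c(0.76, 0.62, 0.44), accent = c(0.42, 0.28, 0.14)))
  c(pal[[stain]], list(background = c(0.97, 0.96, 0.95),
                       padding = c(0.06, 0.05, 0.07)))
}

#' Synthetic u-shaped stained histology image with ground-truth mask
#'
#' A u-shaped tissue band (annulus with an angular opening) on a light
#' slide background inside a dark scanner-padding frame, textured with
#' seeded accent-colour blobs (nuclei, fibres or lipid droplets depending
#' on the stain) and mild pixel noise.
#'
#' @param stain one of `STAIN_LABELS`.
#' @param size image side length in px (square image).
#' @param u_shape_params list: `center` (fractions of size), `r_outer`,
#'   `r_inner` (fractions), `gap_half_deg` (half-angle of the opening,
#'   degrees; the opening points up), `pad_frac` (padding frame width).
#' @param texture_density accent blobs per tissue pixel.
#' @param seed RNG seed.
#' @param noise_sd sd of the additive pixel noise.
#' @return List: `image` (RGB array), `mask` ([tissue_mask()] ground
#'   truth), `params`.
#' @export
generate_histology_image <- function(stain, size = 2000L,
                                     u_shape_params = list(),
                                     texture_density = 2e-4,
                                     seed = 1L, noise_sd = 0.01) {
  stain <- match.arg(stain, STAIN_LABELS)
  p <- utils::modifyList(list(center = c(0.5, 0.52), r_outer = 0.38,
                              r_inner = 0.22, gap_half_deg = 40,
                              pad_frac = 0.03), u_shape_params)
  set.seed(seed)
  H <- W <- as.integer(size)
  cx <- p$center[1] * W; cy <- p$center[2] * H
  xs <- matrix(seq_len(W), H, W, byrow = TRUE)
  ys <- matrix(seq_len(H), H, W)
  dx <- xs - cx; dy <- ys - cy
  rho <- sqrt(dx^2 + dy^2)
  ang <- atan2(dy, dx)
  # opening points up (negative y in image coordinates)
  dang <- abs(atan2(sin(ang + pi / 2), cos(ang + pi / 2)))
  band <- rho >= p$r_inner * size & rho <= p$r_outer * size &
    dang > p$gap_half_deg * pi / 180
  pal <- stain_palette(stain)
  img <- array(0, c(H, W, 3L))
  for (ch in 1:3) img[, , ch] <- pal$background[ch]
  pad <- max(1L, round(p$pad_frac * size))
  for (ch in 1:3) {
    m <- img[, , ch]
    m[c(seq_len(pad), H - seq_len(pad) + 1L), ] <- pal$padding[ch]
    m[, c(seq_len(pad), W - seq_len(pad) + 1L)] <- pal$padding[ch]
    m[band] <- pal$base[ch]
    img[, , ch] <- m
  }
  # seeded accent blobs inside the band
  n_blobs <- max(1L, round(texture_density * sum(band)))
  bx <- stats::runif(4L * n_blobs, 1, W)
  by <- stats::runif(4L * n_blobs, 1, H)
  inb <- band[cbind(pmin(pmax(round(by), 1L), H),
                    pmin(pmax(round(bx), 1L), W))]
  bx <- bx[inb][seq_len(min(n_blobs, sum(inb)))]
  by <- by[inb][seq_len(min(n_blobs, sum(inb)))]
  r_blob <- pmax(2, stats::runif(length(bx), 0.002, 0.005) * size)
  for (k in seq_along(bx)) {
    r <- r_blob[k]
    rows <- max(1L, floor(by[k] - r)):min(H, ceiling(by[k] + r))
    cols <- max(1L, floor(bx[k] - r)):min(W, ceiling(bx[k] + r))
    sub_dx <- outer(rep(1, length(rows)), cols) - bx[k]
    sub_dy <- outer(rows, rep(1, length(cols))) - by[k]
    hit <- (sub_dx^2 + sub_dy^2 <= r^2) & band[rows, cols, drop = FALSE]
    for (ch in 1:3) {
      blk <- img[rows, cols, ch]
      blk[hit] <- pal$accent[ch]
      img[rows, cols, ch] <- blk
    }
  }
  if (noise_sd > 0) {
    img <- img + array(stats::rnorm(length(img), 0, noise_sd), dim(img))
    img[img < 0] <- 0
    img[img > 1] <- 1
  }
  list(image = img, mask = tissue_mask(band), params = p)
}

#' Synthetic per-vertex wall shear stress field
#'
#' Smooth positive scalar field standing in for a CFD-derived WSS field:
#' either a linear gradient along an axis or a localized high-WSS spot.
#'
#' @param mesh a [triangle_mesh].
#' @param pattern `"gradient"` (monotone along `axis`) or `"spot"`
#'   (Gaussian bump around `spot_vertex`).
#' @param seed RNG seed (picks `spot_vertex` when not given).
#' @param base,amplitude field minimum and dynamic range (Pa).
#' @param axis gradient direction.
#' @param spot_vertex vertex index of the spot maximum.
#' @param spot_sigma spot width (mm).
#' @return Numeric per-vertex field (Pa), all values > 0.
#' @export
generate_wss_field <- function(mesh, pattern = c("gradient", "spot"),
                               seed = 1L, base = 0.5, amplitude = 4,
                               axis = c(0, 0, 1), spot_vertex = NULL,
                               spot_sigma = 1) {
  pattern <- match.arg(pattern)
  set.seed(seed)
  v <- mesh$vertices
  if (pattern == "gradient") {
    s <- as.vector(v %*% axis)
    rng <- diff(range(s))
    if (rng == 0) rng <- 1
    base + amplitude * (s - min(s)) / rng
  } else {
    if (is.null(spot_vertex)) spot_vertex <- sample.int(nrow(v), 1L)
    d2 <- rowSums(sweep(v, 2, v[spot_vertex, ])^2)
    base + amplitude * exp(-d2 / (2 * spot_sigma^2))
  }
}

#' Synthetic micro-CT slice mask stack with calcifications
#'
#' Cross-section masks of the dome wall at evenly spaced cutting planes,
#' plus calcification masks: seeded spherical mineral deposits embedded in
#' the wall (calcification pixels are a subset of wall pixels).
#'
#' @param mesh watertight dome [triangle_mesh].
#' @param n_slices number of cutting planes.
#' @param px_per_mm in-plane resolution (the acquisition this emulates has
#'   10 um isotropic voxels, i.e. 100 px/mm; scale down for speed).
#' @param calcification_spec data.frame with columns `x`, `y`, `z`,
#'   `radius_mm`, or `NULL` to place `n_calc` seeded deposits at random
#'   wall vertices.
#' @param n_calc number of seeded deposits when `calcification_spec` is
#'   `NULL`.
#' @param seed RNG seed.
#' @param axis_direction cutting axis.
#' @return List: `masks`, `calc_masks` (lists of [tissue_mask()]),
#'   `offsets` (mm), `calcifications` (the deposit table used), `px_per_mm`.
#' @export
generate_microct_stack <- function(mesh, n_slices = 8L, px_per_mm = 20,
                                   calcification_spec = NULL, n_calc = 2L,
                                   seed = 1L, axis_direction = c(0, 0, 1)) {
  stopifnot(n_slices >= 1L)
  set.seed(seed)
  proj <- as.vector(mesh$vertices %*% axis_direction)
  lo <- min(proj); hi <- max(proj)
  offsets <- lo + (hi - lo) * (seq_len(n_slices) - 0.5) / n_slices
  if (is.null(calcification_spec)) {
    idx <- sample.int(nrow(mesh$vertices), n_calc)
    calcification_spec <- data.frame(
      x = mesh$vertices[idx, 1], y = mesh$vertices[idx, 2],
      z = mesh$vertices[idx, 3],
      radius_mm = stats::runif(n_calc, 0.3, 0.6))
  }
  b <- plane_basis(axis_direction)
  masks <- vector("list", n_slices)
  calc_masks <- vector("list", n_slices)
  for (k in seq_len(n_slices)) {
    m <- slice_mesh_at_plane(mesh, offsets[k], axis_direction, px_per_mm)
    org <- attr(m, "origin_mm")
    H <- nrow(m); W <- ncol(m)
    xs <- org[1] + (seq_len(W) - 1L) / px_per_mm
    ys <- org[2] + (seq_len(H) - 1L) / px_per_mm
    cm <- matrix(FALSE, H, W)
    for (i in seq_len(nrow(calcification_spec))) {
      cc <- as.numeric(calcification_spec[i, c("x", "y", "z")])
      r <- calcification_spec$radius_mm[i]
      cu <- sum(cc * b$u); cv <- sum(cc * b$v); cw <- sum(cc * b$axis)
      dz2 <- (offsets[k] - cw)^2
      if (dz2 >= r^2) next
      r2d <- sqrt(r^2 - dz2)
      du <- matrix(xs, H, W, byrow = TRUE) - cu
      dv <- matrix(ys, H, W) - cv
      cm <- cm | (du^2 + dv^2 <= r2d^2)
    }
    cm <- cm & (m != 0)   # calcification is inside the wall
    masks[[k]] <- m
    calc_masks[[k]] <- tissue_mask(cm)
  }
  list(masks = masks, calc_masks = calc_masks, offsets = offsets,
       calcifications = calcification_spec, px_per_mm = px_per_mm)
}
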