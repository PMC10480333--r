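#' Histologic stain labels
#'
#' The four stains handled by the pipeline: hematoxylin-eosin (`HE`),
#' Masson trichrome (`MT`), Oil Red O (`ORO`) and alpha-smooth-muscle-actin
#' (`ASMA`).
#' @export
STAIN_LABELS <- c("HE", "MT", "ORO", "ASMA")

#' Colour features of a stain patch
#'
#' Per-channel 8-bin histograms plus channel means and standard deviations,
#' computed after rescaling the patch to a common size. These summarize the
#' stain palette, which is what distinguishes the four stains.
#'
#' @param img RGB raster array.
#' @param bins histogram bins per channel.
#' @return Named numeric feature vector.
#' @export
stain_features <- function(img, bins = 8L) {
  if (length(dim(img)) != 3L) stop("stain features need an RGB image")
  br <- seq(0, 1, length.out = bins + 1L)
  feats <- unlist(lapply(1:3, function(ch) {
    x <- as.vector(img[, , ch])
    h <- graphics::hist(pmin(pmax(x, 0), 1), breaks = br, plot = FALSE)
    c(h$counts / length(x), mean(x), stats::sd(x))
  }))
  names(feats) <- paste0("f", seq_along(feats))
  feats
}

#' Train the 4-way stain classifier
#'
#' A single-hidden-layer neural network ([nnet::nnet]) on colour-histogram
#' features of labelled 500x500 patches. Synthetic training patches can be
#' produced with [generate_histology_image()].
#'
#' @param patches list of RGB raster arrays.
#' @param labels character vector of stain labels (`STAIN_LABELS`).
#' @param hidden hidden units.
#' @param seed RNG seed for the weight initialization.
#' @return A `stain_classifier` object.
#' @export
train_stain_classifier <- function(patches, labels, hidden = 8L, seed = 1L) {
  labels <- match.arg(labels, STAIN_LABELS, several.ok = TRUE)
  if (length(patches) != length(labels))
    stop("patches and labels lengths differ")
  X <- t(vapply(patches, stain_features, stain_features(patches[[1]])))
  y <- factor(labels, levels = STAIN_LABELS)
  set.seed(seed)
  fit <- nnet::nnet(X, nnet::class.ind(y), size = hidden, softmax = TRUE,
                    decay = 1e-3, maxit = 300, trace = FALSE)
  structure(list(net = fit, levels = STAIN_LABELS), class = "stain_classifier")
}

#' Classify the stain of a histology patch
#'
#' @param img RGB raster array (any size; features are scale-free).
#' @param model a `stain_classifier` from [train_stain_classifier()], or a
#'   path to one saved with [save_stain_classifier()].
#' @return One of `STAIN_LABELS`.
#' @export
classify_stain <- function(img, model) {
  if (length(dim(img)) != 3L) stop("classify_stain needs an RGB image")
  if (is.character(model)) model <- load_stain_classifier(model)
  x <- matrix(stain_features(img), nrow = 1L)
  p <- stats::predict(model$net, x)
  model$levels[which.max(p)]
}

#' Persist / restore a trained stain classifier
#' @param model a `stain_classifier`.
#' @param path file path (RDS).
#' @export
save_stain_classifier <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_stain_classifier
#' @export
load_stain_classifier <- function(path) readRDS(path)

#' Two-threshold Otsu
#'
#' Three-class Otsu thresholding on a `[0, 1]` sample (256-bin histogram):
#' returns the pair of thresholds maximizing the between-class variance.
#' In a scanned slide the three luminance classes are the black scanner
#' padding, the stained tissue and the light slide background.
#'
#' @param x numeric values in `[0, 1]`.
#' @return Numeric length-2 vector `c(low, high)`, `low < high`.
#' @export
otsu_two_thresholds <- function(x) {
  h <- graphics::hist(pmin(pmax(x, 0), 1),
                      breaks = seq(0, 1, length.out = 257L), plot = FALSE)
  cnt <- h$counts
  mids <- h$mids
  n <- sum(cnt)
  P <- cumsum(cnt) / n                 # class mass up to bin t
  S <- cumsum(cnt * mids) / n          # first moment up to bin t
  mu <- S[256]
  best <- -Inf
  best_t <- c(1L, 128L)
  for (t1 in 1:254) {
    w1 <- P[t1]
    if (w1 <= 0) next
    m1 <- S[t1] / w1
    t2 <- (t1 + 1L):255L
    w2 <- P[t2] - P[t1]
    w3 <- 1 - P[t2]
    ok <- w2 > 0 & w3 > 0
    if (!any(ok)) next
    m2 <- (S[t2] - S[t1]) / w2
    m3 <- (mu - S[t2]) / w3
    bc <- w1 * (m1 - mu)^2 + w2 * (m2 - mu)^2 + w3 * (m3 - mu)^2
    bc[!ok] <- -Inf
    j <- which.max(bc)
    if (bc[j] > best) {
      best <- bc[j]
      best_t <- c(t1, t2[j])
    }
  }
  br <- seq(0, 1, length.out = 257L)
  c(br[best_t[1] + 1L], br[best_t[2] + 1L])  # upper edges of chosen bins
}

# Morphological geodesic-active-contour refinement of a binary mask.
# The speed image g = 1/(1 + alpha |grad(G_sigma * I)|^2) is small at edges;
# the curve is attracted to edges by a gradient-advection step and kept
# smooth by a majority (curvature-like) step. This is the morphological
# formulation of GAC acting on the indicator function of the mask.
gac_refine <- function(lum, mask, iterations = 100L, alpha = 200,
                       sigma = 2) {
  if (iterations <= 0L) return(mask)
  sm <- from_ebimage(EBImage::gblur(as_ebimage(lum), sigma = sigma))
  gx <- sm * 0; gy <- sm * 0
  gy[2:(nrow(sm) - 1), ] <- (sm[3:nrow(sm), ] - sm[1:(nrow(sm) - 2), ]) / 2
  gx[, 2:(ncol(sm) - 1)] <- (sm[, 3:ncol(sm)] - sm[, 1:(ncol(sm) - 2)]) / 2
  g <- 1 / (1 + alpha * (gx^2 + gy^2))
  dgy <- g * 0; dgx <- g * 0
  dgy[2:(nrow(g) - 1), ] <- (g[3:nrow(g), ] - g[1:(nrow(g) - 2), ]) / 2
  dgx[, 2:(ncol(g) - 1)] <- (g[, 3:ncol(g)] - g[, 1:(ncol(g) - 2)]) / 2
  cpp_morph_gac(dgx, dgy, matrix(as.integer(mask != 0), nrow(mask)),
                as.integer(iterations))
}

#' Stain-aware tissue segmentation of a histology image
#'
#' Two thresholds on the luminance are determined with Otsu's method: the
#' first separates the dark scanner padding from the slide, the second
#' separates the (darker) tissue from the light slide background.
#' Components smaller than `min_object_area` (dissected fragments,
#' impurities) are removed and the mask is refined with a morphological
#' geodesic-active-contour step initialized from the threshold mask. All
#' four stains use the same luminance path; H&E and MT are simply darker
#' than ORO and aSMA, which the image-specific Otsu thresholds absorb.
#' Images larger than `max_side` pixels on a side are processed on a
#' downsampled proxy and the mask is upsampled back.
#'
#' @param img RGB raster array.
#' @param stain one of `STAIN_LABELS` or `"auto"` (metadata only; the
#'   thresholds adapt per image).
#' @param min_object_area smallest kept component, px; default 0.1% of the
#'   image.
#' @param gac_iterations active-contour refinement iterations.
#' @param max_side processing-resolution cap (px).
#' @return A [tissue_mask()] on the input pixel grid.
#' @export
segment_tissue <- function(img, stain = "auto", min_object_area = NULL,
                           gac_iterations = 100L, max_side = 4096L) {
  lum <- luminance(img)
  H <- nrow(lum); W <- ncol(lum)
  if (is.null(min_object_area)) min_object_area <- ceiling(0.001 * H * W)
  scale <- max(H, W) / max_side
  work <- lum
  if (scale > 1) {
    # as_ebimage transposes, so EBImage's w is our column count
    work <- from_ebimage(EBImage::resize(as_ebimage(lum),
                                         w = round(W / scale),
                                         h = round(H / scale)))
  }
  if (stats::sd(work) < 1e-6) {
    warning("uniform image: Otsu threshold undefined, returning empty mask")
    return(tissue_mask(matrix(0L, H, W)))
  }
  th <- otsu_two_thresholds(as.vector(work))
  # the middle luminance class is the tissue: above the padding threshold,
  # below the slide-background threshold
  m <- work > th[1] & work <= th[2]
  area_scale <- if (scale > 1) scale^2 else 1
  m <- remove_small_objects(m, max(1, min_object_area / area_scale))
  # stain accents (nuclei, droplets) can fall below the padding threshold;
  # they are interior holes, not background
  m <- from_ebimage(EBImage::fillHull(as_ebimage(m))) != 0
  m <- gac_refine(work, m, iterations = gac_iterations)
  m <- remove_small_objects(m, max(1, min_object_area / area_scale))
  if (scale > 1) {
    m <- from_ebimage(EBImage::resize(as_ebimage(m), w = W, h = H))
    m <- matrix(as.integer(m > 0.5), H, W)
  }
  tissue_mask(m)
}
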