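# Raster conventions: images are numeric arrays dim c(H, W) (grayscale /
# mask) or c(H, W, 3) (RGB), values in [0, 1], origin top-left, 1-based
# (row, col) indexing; point coordinates are (x = col, y = row).

#' Read an RGB or grayscale raster (PNG or TIFF)
#'
#' @param path image path (`.png`, `.tif`, `.tiff`).
#' @return Numeric array `H x W` or `H x W x 3`, values in `[0, 1]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = {
                  if (!requireNamespace("tiff", quietly = TRUE))
                    stop("package 'tiff' needed for TIFF input")
                  tiff::readTIFF(path)
                },
                stop("unsupported image format: ", ext))
  if (length(dim(img)) == 3L && dim(img)[3] >= 3L)
    img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write a raster to PNG or TIFF
#'
#' @param img numeric array in `[0, 1]` (`H x W` or `H x W x 3`).
#' @param path output path; extension selects the format.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  img[img < 0] <- 0
  img[img > 1] <- 1
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(img, path),
         tif = ,
         tiff = {
           if (!requireNamespace("tiff", quietly = TRUE))
             stop("package 'tiff' needed for TIFF output")
           tiff::writeTIFF(img, path)
         },
         stop("unsupported image format: ", ext))
  invisible(path)
}

#' Luminance of an RGB raster
#'
#' Rec. 601 weighting; grayscale input is returned unchanged.
#' @param img raster array.
#' @return `H x W` matrix in `[0, 1]`.
#' @export
luminance <- function(img) {
  if (length(dim(img)) == 2L) return(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# EBImage stores images transposed (x = first dim); these helpers convert.
as_ebimage <- function(m) EBImage::Image(t(m))

from_ebimage <- function(img) t(EBImage::imageData(img))

#' Binary mask helpers
#'
#' A tissue mask is an integer `H x W` matrix of 0/1 with an optional
#' `pixel_size_um` attribute (micrometres per pixel).
#'
#' @param m numeric/logical matrix; nonzero means foreground.
#' @param pixel_size_um pixel edge length in micrometres (metadata).
#' @return Integer 0/1 matrix of class `tissue_mask`.
#' @export
tissue_mask <- function(m, pixel_size_um = NA_real_) {
  m <- matrix(as.integer(m != 0), nrow = nrow(m))
  attr(m, "pixel_size_um") <- pixel_size_um
  class(m) <- c("tissue_mask", class(m))
  m
}

#' Remove connected components smaller than a pixel area
#' @param mask 0/1 matrix.
#' @param min_area minimum component area in px.
#' @return 0/1 integer matrix.
#' @export
remove_small_objects <- function(mask, min_area) {
  lab <- from_ebimage(EBImage::bwlabel(as_ebimage(mask != 0)))
  if (max(lab) == 0) return(matrix(0L, nrow(mask), ncol(mask)))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  matrix(as.integer(lab %in% keep), nrow = nrow(mask))
}

largest_component <- function(mask) {
  lab <- from_ebimage(EBImage::bwlabel(as_ebimage(mask != 0)))
  if (max(lab) == 0) return(list(mask = mask * 0L, n_components = 0L))
  sizes <- tabulate(lab[lab > 0])
  list(mask = matrix(as.integer(lab == which.max(sizes)), nrow(mask)),
       n_components = length(sizes))
}

#' Morphological disk dilation of a binary mask
#' @param mask 0/1 matrix.
#' @param radius disk radius in px; 0 returns the mask unchanged.
#' @return 0/1 integer matrix.
#' @export
dilate_mask <- function(mask, radius) {
  if (radius <= 0) return(matrix(as.integer(mask != 0), nrow(mask)))
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  out <- from_ebimage(EBImage::dilate(as_ebimage(mask != 0), brush))
  matrix(as.integer(out != 0), nrow(mask))
}
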