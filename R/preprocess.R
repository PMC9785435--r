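# Denoising of eye images ahead of boundary search: specular reflection
# points are masked and filled by inward (harmonic) interpolation; eyelashes
# -- thin dark detail -- are suppressed by grayscale morphological closing.

#' Convert an image to a normalized grayscale matrix
#'
#' Accepts a 2-D intensity grid or a 3-D array with 3 (RGB) or 4 (RGBA,
#' alpha ignored) channels, 8-bit or float. Color is collapsed with Rec. 601
#' luma weights (0.299, 0.587, 0.114). Output values lie in [0, 1].
#'
#' @param image numeric matrix or 3-D array.
#' @return numeric matrix in [0, 1], indexed [row, col].
#' @examples
#' toGray(array(128 / 255, c(4, 4, 3)))[1, 1]
#' @export
toGray <- function(image) {
  if (!is.numeric(image)) stop("image must be numeric")
  nd <- length(dim(image))
  if (is.null(dim(image)) || nd < 2L || nd > 3L)
    stop("image must have 2 dimensions (gray) or 3 (color)")
  if (nd == 3L) {
    nc <- dim(image)[3]
    if (nc == 1L) image <- image[, , 1L]
    else if (nc %in% c(3L, 4L))
      image <- 0.299 * image[, , 1L] + 0.587 * image[, , 2L] +
        0.114 * image[, , 3L]
    else stop("color images must have 1, 3 or 4 channels")
  }
  if (max(image) > 1) image <- image / 255
  .clamp01(image)
}

#' Read an image file as a grayscale matrix
#'
#' Reads PNG (always) or TIFF (when the \pkg{tiff} package is available) and
#' converts to normalized grayscale via \code{\link{toGray}}.
#'
#' @param path image file path.
#' @return numeric matrix in [0, 1].
#' @export
readGrayImage <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop("unsupported image format: ", ext, " (PNG or TIFF expected)"))
  toGray(img)
}

#' Detect specular reflection points
#'
#' Builds the binary mask of near-saturated pixels (intensity >=
#' \code{threshold}), dilated by \code{dilatePx} pixels to cover bloom halos
#' around each spot.
#'
#' @param image grayscale matrix in [0, 1].
#' @param threshold normalized gray level in (0, 1).
#' @param dilatePx dilation margin in pixels (0 disables).
#' @return logical matrix, \code{TRUE} = pixel to be filled.
#' @export
detectReflections <- function(image, threshold = 0.90, dilatePx = 2L) {
  .checkGray(image)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)")
  mask <- image >= threshold
  if (any(mask) && dilatePx > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(dilatePx) + 1L, "disc")
    mask <- EBImage::dilate(mask * 1, brush) > 0.5
  }
  mask
}

#' Fill masked pixels by inward (harmonic) interpolation
#'
#' Replaces masked pixels by the harmonic interpolant of the surrounding
#' intensities: masked pixels are iteratively set to the mean of their 4
#' neighbors (Neumann boundary at the image border) until the largest
#' per-pixel change drops below \code{tol} or \code{maxIter} sweeps have run.
#' Pixels outside the mask are returned bit-identical to the input.
#'
#' @param image grayscale matrix in [0, 1].
#' @param mask logical matrix of the same shape; \code{TRUE} = fill.
#' @param tol convergence tolerance on the per-sweep max change.
#' @param maxIter sweep cap.
#' @return grayscale matrix in [0, 1].
#' @export
inpaintReflections <- function(image, mask, tol = 1e-5, maxIter = 500L) {
  .checkGray(image)
  if (!is.logical(mask) || !identical(dim(mask), dim(image)))
    stop("mask must be a logical matrix with the same shape as the image")
  if (all(mask)) stop("all-true mask: no boundary to interpolate from")
  if (!any(mask)) return(image)
  h <- nrow(image); w <- ncol(image)
  out <- image
  out[mask] <- mean(image[!mask])
  ridx <- c(1L, seq_len(h), h); cidx <- c(1L, seq_len(w), w)
  midx <- which(mask)
  for (it in seq_len(maxIter)) {
    p <- out[ridx, cidx]
    nb <- (p[seq_len(h), 2:(w + 1L)] + p[3:(h + 2L), 2:(w + 1L)] +
           p[2:(h + 1L), seq_len(w)] + p[2:(h + 1L), 3:(w + 2L)]) / 4
    delta <- abs(nb[midx] - out[midx])
    out[midx] <- nb[midx]
    if (max(delta) < tol) break
  }
  .clamp01(out)
}

#' Suppress eyelash strokes by grayscale morphological closing
#'
#' Applies a grayscale closing with a disk structuring element of radius
#' \code{selemRadius}. Closing is extensive (output >= input pointwise) and
#' idempotent; dark structures thinner than the element -- eyelash strokes --
#' are raised toward the surrounding intensity while boundary steps wider
#' than the element are preserved.
#'
#' @param image grayscale matrix in [0, 1].
#' @param selemRadius disk radius in pixels (>= 1).
#' @return grayscale matrix in [0, 1].
#' @export
suppressEyelashes <- function(image, selemRadius = 3L) {
  .checkGray(image)
  if (!is.numeric(selemRadius) || selemRadius < 1) stop("selemRadius must be >= 1")
  brush <- EBImage::makeBrush(2L * as.integer(selemRadius) + 1L, "disc")
  out <- EBImage::closing(image, brush)
  matrix(as.numeric(out), nrow(image), ncol(image))
}

#' Denoise an eye image
#'
#' Composition of the two denoising stages in fixed order: reflection
#' detection + inpainting, then eyelash suppression. Each stage can be
#' disabled via \code{config$denoise$stages_enabled}. When \code{box} is
#' given and \code{config$denoise$box_only} is \code{TRUE} (default), the
#' stages run only inside the box padded by \code{box_pad_frac}; the rest of
#' the image passes through untouched. The closing radius is scaled
#' proportionally to image size (reference: radius \code{closing_radius_px}
#' at a 224-px image).
#'
#' @param image grayscale matrix in [0, 1].
#' @param config configuration list from \code{\link{irisConfig}}.
#' @param box optional \linkS4class{BoundingBox} restricting the denoising.
#' @return grayscale matrix in [0, 1], same shape as the input.
#' @export
denoise <- function(image, config = irisConfig(), box = NULL) {
  .checkGray(image)
  dcfg <- config$denoise
  h <- nrow(image); w <- ncol(image)
  region <- c(1L, h, 1L, w)  # rows then cols
  if (!is.null(box) && isTRUE(dcfg$box_only)) {
    stopifnot(is(box, "BoundingBox"))
    padw <- dcfg$box_pad_frac * box@w; padh <- dcfg$box_pad_frac * box@h
    region <- c(max(1L, floor(box@y - padh)), min(h, ceiling(box@y + box@h - 1 + padh)),
                max(1L, floor(box@x - padw)), min(w, ceiling(box@x + box@w - 1 + padw)))
  }
  rows <- region[1]:region[2]; cols <- region[3]:region[4]
  sub <- image[rows, cols, drop = FALSE]
  stages <- dcfg$stages_enabled
  if ("reflections" %in% stages) {
    mask <- detectReflections(sub, dcfg$reflection_threshold,
                              dcfg$mask_dilate_px)
    if (any(mask) && !all(mask)) sub <- inpaintReflections(sub, mask)
  }
  if ("eyelashes" %in% stages) {
    rad <- max(1L, round(dcfg$closing_radius_px * min(h, w) / 224))
    sub <- suppressEyelashes(sub, rad)
  }
  out <- image
  out[rows, cols] <- sub
  .clamp01(out)
}
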