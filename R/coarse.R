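# Coarse initialization: the detector bounding box (from an annotation file)
# or a simple intensity-based pupil estimate supplies the initial center and
# the search ranges for the precise boundary search.

#' Load bounding-box annotations
#'
#' Reads boxes from a CSV file with columns \code{image, x, y, w, h} (extra
#' columns ignored) or a JSON array of objects with those fields. Every box
#' is validated; malformed rows are reported with their row numbers.
#'
#' @param path CSV or JSON file path.
#' @return named list of \linkS4class{BoundingBox}, names = image ids
#'   (empty list, with a warning, for an empty file).
#' @export
loadBoxes <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "json") {
    j <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (length(j) == 0) data.frame() else as.data.frame(j)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (nrow(df) == 0L) {
    warning("no annotations found in ", path)
    return(stats::setNames(list(), character(0)))
  }
  need <- c("image", "x", "y", "w", "h")
  if (!all(need %in% names(df)))
    stop("annotation file must provide columns: ", paste(need, collapse = ", "))
  bad <- character(0)
  boxes <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    b <- tryCatch({
      vals <- suppressWarnings(as.numeric(df[i, c("x", "y", "w", "h")]))
      if (anyNA(vals)) stop("non-numeric box fields")
      BoundingBox(vals[1], vals[2], vals[3], vals[4])
    }, error = function(e) e)
    if (inherits(b, "error")) bad <- c(bad, sprintf("row %d: %s", i,
                                                    conditionMessage(b)))
    else boxes[[i]] <- b
  }
  if (length(bad)) stop("malformed annotation rows:\n  ",
                        paste(bad, collapse = "\n  "))
  stats::setNames(boxes, as.character(df$image))
}

#' Coarse pupil estimate from image intensity
#'
#' Fallback when no detector output or annotation is available. The center of
#' a detector box may not equal the pupil center, but it usually falls within
#' the pupil; this estimator mimics that behavior from intensity alone:
#' reflections are inpainted, the image is thresholded at a low intensity
#' quantile (plus a margin), and the centroid of the largest connected dark
#' component is taken as the pupil center. The returned box is a square of
#' side \code{6 * requiv} (the component's equivalent radius), centered on
#' the centroid and clipped to the image.
#'
#' @param image grayscale matrix in [0, 1].
#' @param quantileProb probability of the dark quantile (default 0.05).
#' @param margin gray-level margin added to the quantile threshold.
#' @param minArea minimum component area in pixels.
#' @param maxAreaFrac maximum component area as a fraction of the image (a
#'   pupil is compact; a "dark" region covering most of the frame means the
#'   threshold failed to separate anything).
#' @return a \linkS4class{BoundingBox}.
#' @export
coarsePupilEstimate <- function(image, quantileProb = 0.05, margin = 0.05,
                                minArea = 50L, maxAreaFrac = 0.25) {
  .checkGray(image)
  mask <- detectReflections(image, 0.90, 2L)
  if (any(mask) && !all(mask)) image <- inpaintReflections(image, mask)
  thr <- stats::quantile(image, quantileProb, names = FALSE) + margin
  dark <- (image <= thr) * 1
  lab <- EBImage::bwlabel(dark)
  ncomp <- max(lab)
  if (ncomp < 1) stop("no dark component found; supply a bounding box")
  areas <- tabulate(lab[lab > 0], nbins = ncomp)
  best <- which.max(areas)
  if (areas[best] < minArea)
    stop("largest dark component below minimum area; supply a bounding box")
  if (areas[best] > maxAreaFrac * length(image))
    stop("no compact dark component found; supply a bounding box")
  idx <- which(lab == best, arr.ind = TRUE)
  cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
  requiv <- sqrt(areas[best] / pi)
  side <- 6 * requiv
  x1 <- max(1, cx - side / 2); y1 <- max(1, cy - side / 2)
  x2 <- min(ncol(image), cx + side / 2); y2 <- min(nrow(image), cy + side / 2)
  BoundingBox(x1, y1, x2 - x1, y2 - y1)
}

#' Search ranges from a detector bounding box
#'
#' Converts a bounding box into the initial center and the candidate grids of
#' the two-stage search: the inner-boundary grid is a square neighborhood of
#' the box center (\code{center_window_px}, step 1 px) crossed with radii
#' from \code{r_min_px} to \code{r_max_frac * min(w, h)} (step 1 px); the box
#' side lengths are carried along for the outer-radius range.
#'
#' @param box a \linkS4class{BoundingBox}.
#' @param image grayscale matrix (for clipping the center window).
#' @param config configuration list from \code{\link{irisConfig}}.
#' @return list with \code{initialCenter} (cx, cy), \code{innerGrid}
#'   (a \linkS4class{SearchGrid}), and \code{boxDims} (w, h).
#' @export
boxToSearch <- function(box, image, config = irisConfig()) {
  stopifnot(is(box, "BoundingBox"))
  .checkGray(image)
  ccfg <- config$coarse; ocfg <- config$operators
  cx <- box@x + box@w / 2; cy <- box@y + box@h / 2
  rMax <- floor(ccfg$r_max_frac * min(box@w, box@h))
  if (rMax < ccfg$r_min_px)
    stop("box too small for the minimum inner radius")
  wpx <- ccfg$center_window_px
  xs <- (round(cx) - wpx):(round(cx) + wpx)
  ys <- (round(cy) - wpx):(round(cy) + wpx)
  xs <- xs[xs >= 1 & xs <= ncol(image)]
  ys <- ys[ys >= 1 & ys <= nrow(image)]
  centers <- as.matrix(expand.grid(cx = xs, cy = ys))
  params <- OperatorParams(n = ocfg$n_inner, deltaR = ocfg$delta_r,
                           sigma = ocfg$sigma, arcs = cbind(0, 360),
                           gradientSign = ocfg$gradient_sign)
  list(initialCenter = c(cx = cx, cy = cy),
       innerGrid = SearchGrid(centers, seq(ccfg$r_min_px, rMax), params),
       boxDims = c(w = box@w, h = box@h))
}
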