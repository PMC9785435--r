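# Two-stage precise localization: the pupillary (inner) boundary is found
# first by a full-circle compensated-gradient search seeded by the detector
# box; the limbic (outer) boundary is then searched over lateral arcs, with
# its center confined to a tiny neighborhood of the inner center and its
# radius confined to (1.2 * rp, 0.5 * max(box sides)).

#' Locate the pupillary (inner) iris boundary
#'
#' Runs the boundary search over the grid derived from the detector box
#' (\code{\link{boxToSearch}}): full-circle integration path, \code{n_inner}
#' sample points (default 32 -- the inner contour is short).
#'
#' @param image denoised grayscale matrix in [0, 1].
#' @param box a \linkS4class{BoundingBox} seeding the search.
#' @param config configuration list from \code{\link{irisConfig}}.
#' @param objective objective passed to \code{\link{searchMax}}.
#' @return a \linkS4class{ScoredCircle}.
#' @export
locateInner <- function(image, box, config = irisConfig(),
                        objective = "modified") {
  bs <- boxToSearch(box, image, config)
  searchMax(image, bs$innerGrid, objective,
            minValidFrac = config$operators$min_valid_frac)
}

#' Radius search range for the outer boundary
#'
#' The outer radius is confined to the open interval
#' \eqn{1.2 r_p < r < 0.5 \max(\mathrm{rows}, \mathrm{cols})}, where
#' \eqn{r_p} is the inner radius and rows/cols are the detector-box side
#' lengths; the interval is discretized at 1-px steps.
#'
#' @param rp inner (pupillary) radius in pixels.
#' @param box the \linkS4class{BoundingBox} used for detection.
#' @return integer vector of candidate radii; length 0 signals failure
#'   (degenerate range).
#' @examples
#' outerRadiusRange(30, BoundingBox(1, 1, 200, 180))  # 37..99
#' @export
outerRadiusRange <- function(rp, box) {
  stopifnot(is.numeric(rp), rp > 0, is(box, "BoundingBox"))
  lo <- 1.2 * rp
  hi <- 0.5 * max(box@w, box@h)
  if (hi <= lo) return(integer(0))
  lo1 <- floor(lo) + 1L          # smallest integer strictly above lo
  hi1 <- ceiling(hi) - 1L        # largest integer strictly below hi
  if (hi1 < lo1) return(integer(0))
  seq.int(lo1, hi1)
}

#' Locate the limbic (outer) iris boundary
#'
#' Searches with \code{n_outer} sample points (default 256) over the lateral
#' arcs (two 90-degree arcs centered on the horizontal axis, avoiding
#' eyelid/eyelash interference at the top and bottom), center candidates
#' within \code{outer_center_window_px} (default 3 px) of the inner center,
#' and radii from \code{\link{outerRadiusRange}}.
#'
#' @param image denoised grayscale matrix in [0, 1].
#' @param inner the inner-boundary \linkS4class{ScoredCircle}.
#' @param box the detector \linkS4class{BoundingBox}.
#' @param config configuration list from \code{\link{irisConfig}}.
#' @param objective objective passed to \code{\link{searchMax}}.
#' @return a \linkS4class{ScoredCircle}.
#' @export
locateOuter <- function(image, inner, box, config = irisConfig(),
                        objective = "modified") {
  stopifnot(is(inner, "ScoredCircle"))
  ocfg <- config$operators
  radii <- outerRadiusRange(inner@circle@r, box)
  if (length(radii) == 0L) stop("empty outer radius range")
  wpx <- ocfg$outer_center_window_px
  xs <- (round(inner@circle@cx) - wpx):(round(inner@circle@cx) + wpx)
  ys <- (round(inner@circle@cy) - wpx):(round(inner@circle@cy) + wpx)
  xs <- xs[xs >= 1 & xs <= ncol(image)]
  ys <- ys[ys >= 1 & ys <= nrow(image)]
  params <- OperatorParams(n = ocfg$n_outer, deltaR = ocfg$delta_r,
                           sigma = ocfg$sigma,
                           arcs = .arcsMatrix(ocfg$outer_arcs),
                           gradientSign = ocfg$gradient_sign)
  grid <- SearchGrid(as.matrix(expand.grid(cx = xs, cy = ys)), radii, params)
  searchMax(image, grid, objective, minValidFrac = ocfg$min_valid_frac)
}

.emptyScored <- function() ScoredCircle(Circle(NA_real_, NA_real_, NA_real_),
                                        NA_real_)

# Shared pipeline body; objective switches between the compensated operator
# and the integro-differential operator on identical grids.
.locatePipeline <- function(image, box, config, objective) {
  if (is.character(image)) image <- readGrayImage(image)
  image <- toGray(image)
  if (is.null(box)) {
    box <- tryCatch(coarsePupilEstimate(image), error = function(e) NULL)
    if (is.null(box))    # no usable coarse seed: report a failed inner stage
      return(new("LocalizationResult", inner = .emptyScored(),
                 outer = .emptyScored(),
                 bboxUsed = BoundingBox(1, 1, ncol(image), nrow(image)),
                 status = "inner_failed",
                 paramsUsed = list(objective = objective, config = config)))
  }
  den <- denoise(image, config, box = box)
  inner <- tryCatch(locateInner(den, box, config, objective),
                    error = function(e) NULL)
  if (is.null(inner))
    return(new("LocalizationResult", inner = .emptyScored(),
               outer = .emptyScored(), bboxUsed = box,
               status = "inner_failed",
               paramsUsed = list(objective = objective, config = config)))
  outer <- tryCatch(locateOuter(den, inner, box, config, objective),
                    error = function(e) NULL)
  if (is.null(outer))
    return(new("LocalizationResult", inner = inner, outer = .emptyScored(),
               bboxUsed = box, status = "outer_failed",
               paramsUsed = list(objective = objective, config = config)))
  new("LocalizationResult", inner = inner, outer = outer, bboxUsed = box,
      status = "ok", paramsUsed = list(objective = objective, config = config))
}

#' Locate both iris boundaries in an eye image
#'
#' Full pipeline: grayscale conversion, detector box (given, or the coarse
#' pupil estimate), denoising within the box, inner-boundary search, then
#' outer-boundary search constrained by the inner result. Stage failures are
#' recorded in the result status rather than raised.
#'
#' @param image grayscale/RGB array, or a path to a PNG/TIFF file.
#' @param box optional \linkS4class{BoundingBox}; when \code{NULL} the coarse
#'   pupil estimate is used.
#' @param config configuration list from \code{\link{irisConfig}}.
#' @return a \linkS4class{LocalizationResult}.
#' @examples
#' sc <- renderScene(SceneSpec(seed = 11L))
#' res <- locateIris(sc$image, truthBox(sc$truth))
#' status(res)
#' @export
locateIris <- function(image, box = NULL, config = irisConfig()) {
  .locatePipeline(image, box, config, "modified")
}

#' @describeIn locateIris the same pipeline with Daugman's
#'   integro-differential objective substituted in both stages, over the
#'   identical candidate grids (the comparison baseline).
#' @export
locateIrisDaugman <- function(image, box = NULL, config = irisConfig()) {
  .locatePipeline(image, box, config, "daugman")
}

#' Serialize a localization result to JSON
#'
#' @param result a \linkS4class{LocalizationResult}.
#' @param path optional output file; when omitted the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to file).
#' @export
resultToJSON <- function(result, path = NULL) {
  stopifnot(is(result, "LocalizationResult"))
  x <- list(status = result@status,
            inner = list(cx = result@inner@circle@cx,
                         cy = result@inner@circle@cy,
                         r = result@inner@circle@r,
                         score = result@inner@score),
            outer = list(cx = result@outer@circle@cx,
                         cy = result@outer@circle@cy,
                         r = result@outer@circle@r,
                         score = result@outer@score),
            bbox = list(x = result@bboxUsed@x, y = result@bboxUsed@y,
                        w = result@bboxUsed@w, h = result@bboxUsed@h),
            objective = result@paramsUsed$objective)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Draw localization overlays onto an image
#'
#' Marks the recovered inner and outer circles (1-px rings) on a copy of the
#' image, for visual inspection.
#'
#' @param image grayscale matrix in [0, 1].
#' @param result a \linkS4class{LocalizationResult}.
#' @param path optional PNG output path.
#' @return the annotated matrix (invisibly when written to file).
#' @export
drawOverlay <- function(image, result, path = NULL) {
  .checkGray(image)
  ring <- function(img, circ, value) {
    if (!is.finite(circ@cx)) return(img)
    t <- seq(0, 2 * pi, length.out = max(64L, round(4 * circ@r)))
    xs <- round(circ@cx + circ@r * cos(t)); ys <- round(circ@cy - circ@r * sin(t))
    keep <- xs >= 1 & xs <= ncol(img) & ys >= 1 & ys <= nrow(img)
    img[cbind(ys[keep], xs[keep])] <- value
    img
  }
  out <- ring(image, result@inner@circle, 1)
  out <- ring(out, result@outer@circle, 0)
  if (!is.null(path)) { png::writePNG(out, path); return(invisible(out)) }
  out
}
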