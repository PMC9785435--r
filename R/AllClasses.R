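#' @import methods
NULL

#' Circle in pixel coordinates
#'
#' A circle parameterized by its center \code{(cx, cy)} and radius \code{r},
#' all in pixels. \code{cx} is the column coordinate, \code{cy} the row
#' coordinate; both are continuous and 1-based (pixel centers sit at integer
#' coordinates). Circles carry the pupillary (inner) and limbic (outer) iris
#' boundaries throughout the package.
#'
#' @slot cx numeric, column coordinate of the center (pixels).
#' @slot cy numeric, row coordinate of the center (pixels).
#' @slot r numeric, radius in pixels, strictly positive.
#' @export
setClass("Circle", representation(cx = "numeric", cy = "numeric", r = "numeric"),
         validity = function(object) {
  if (length(object@cx) != 1L || length(object@cy) != 1L || length(object@r) != 1L)
    return("cx, cy and r must be scalars")
  v <- c(object@cx, object@cy, object@r)
  if (any(!is.finite(v) & !is.na(v)))
    return("cx, cy and r must be finite (NA allowed for failed fits)")
  if (!is.na(object@r) && object@r <= 0) return("radius must be > 0")
  TRUE
})

#' @param cx,cy center coordinates in pixels (column, row).
#' @param r radius in pixels.
#' @rdname Circle-class
#' @export
Circle <- function(cx, cy, r) new("Circle", cx = as.numeric(cx),
                                  cy = as.numeric(cy), r = as.numeric(r))

#' Axis-aligned bounding box
#'
#' A rectangle given by its top-left pixel \code{(x, y)} (1-based: column,
#' row) and its width \code{w} (columns) and height \code{h} (rows). Stands in
#' for the rectangular iris-detector output that seeds the boundary search.
#'
#' @slot x,y numeric, top-left pixel (column, row).
#' @slot w,h numeric, side lengths in pixels, strictly positive.
#' @export
setClass("BoundingBox",
         representation(x = "numeric", y = "numeric", w = "numeric", h = "numeric"),
         validity = function(object) {
  v <- c(object@x, object@y, object@w, object@h)
  if (length(v) != 4L || !all(is.finite(v))) return("x, y, w, h must be finite scalars")
  if (object@w <= 0 || object@h <= 0) return("box width and height must be > 0")
  TRUE
})

#' @param x,y top-left pixel (column, row).
#' @param w,h width and height in pixels.
#' @rdname BoundingBox-class
#' @export
BoundingBox <- function(x, y, w, h) new("BoundingBox", x = as.numeric(x),
                                        y = as.numeric(y), w = as.numeric(w),
                                        h = as.numeric(h))

#' Operator tuning parameters
#'
#' Parameters shared by the circular-boundary objectives: the number of points
#' \code{n} sampled uniformly along the integration path, the radial step
#' \code{deltaR} used by the radial gradient, the Gaussian standard deviation
#' \code{sigma} used to smooth the integro-differential radial profile, the
#' angular arcs forming the integration path, and the expected sign of the
#' outward intensity step.
#'
#' Arcs are rows of a two-column matrix \code{cbind(start, end)} in degrees,
#' counter-clockwise from the +x axis; a row with \code{start > end} wraps
#' through 0 (so \code{c(315, 45)} is the 90-degree arc centered on the right
#' horizontal). \code{cbind(0, 360)} is the full circle.
#'
#' @slot n integer, number of sample points along the path (>= 8).
#' @slot deltaR numeric, radial step in pixels (> 0).
#' @slot sigma numeric, Gaussian sigma in pixels (>= 0) for the smoothed
#'   radial derivative.
#' @slot arcs numeric matrix of angular intervals in degrees.
#' @slot gradientSign either \code{"outward_brighter"} (pupil < iris < sclera,
#'   the near-infrared convention) or \code{"outward_darker"}.
#' @export
setClass("OperatorParams",
         representation(n = "integer", deltaR = "numeric", sigma = "numeric",
                        arcs = "matrix", gradientSign = "character"),
         validity = function(object) {
  if (object@n < 8L) return("n must be >= 8")
  if (object@deltaR <= 0) return("deltaR must be > 0")
  if (object@sigma < 0) return("sigma must be >= 0")
  if (ncol(object@arcs) != 2L || nrow(object@arcs) < 1L)
    return("arcs must be a matrix with columns (start, end)")
  if (any(object@arcs < 0 | object@arcs > 360))
    return("arc endpoints must lie in [0, 360]")
  if (!object@gradientSign %in% c("outward_brighter", "outward_darker"))
    return("gradientSign must be 'outward_brighter' or 'outward_darker'")
  TRUE
})

#' @param n number of sample points.
#' @param deltaR radial step in pixels.
#' @param sigma Gaussian sigma in pixels.
#' @param arcs two-column matrix of angular intervals (degrees).
#' @param gradientSign \code{"outward_brighter"} or \code{"outward_darker"}.
#' @rdname OperatorParams-class
#' @export
OperatorParams <- function(n = 32L, deltaR = 1, sigma = 1,
                           arcs = cbind(0, 360),
                           gradientSign = "outward_brighter") {
  new("OperatorParams", n = as.integer(n), deltaR = as.numeric(deltaR),
      sigma = as.numeric(sigma), arcs = matrix(as.numeric(arcs), ncol = 2L),
      gradientSign = gradientSign)
}

#' Synthetic eye-scene specification
#'
#' Full description of one synthetic eye scene: a dark pupil disk inside a
#' textured iris annulus inside a bright sclera, plus the noise classes seen
#' in non-cooperative acquisition — near-saturated specular reflection spots,
#' dark eyelash strokes, partial upper-eyelid occlusion, off-angle (elliptic)
#' distortion and optical blur. Intensities are normalized gray levels in
#' [0, 1].
#'
#' @slot imageHeight,imageWidth image size in pixels.
#' @slot pupil,iris \linkS4class{Circle} ground-truth boundaries (pre-distortion).
#' @slot intensityPupil,intensityIris,intensitySclera base gray levels,
#'   required to increase outward.
#' @slot irisTextureAmplitude amplitude of the radial-sinusoid iris texture.
#' @slot nReflections number of specular reflection disks.
#' @slot reflectionRadiusRange two-vector, min/max reflection radius (px).
#' @slot nEyelashes number of eyelash strokes.
#' @slot eyelidCoverageFraction fraction of the iris vertical extent covered
#'   by the upper eyelid, in [0, 0.5].
#' @slot offAngleAxisRatio horizontal axis scaling in (0, 1]; 1 = circular.
#' @slot blurSigma Gaussian blur sigma in pixels (0 = none).
#' @slot seed integer seed driving all stochastic scene content.
#' @export
setClass("SceneSpec",
         representation(imageHeight = "integer", imageWidth = "integer",
                        pupil = "Circle", iris = "Circle",
                        intensityPupil = "numeric", intensityIris = "numeric",
                        intensitySclera = "numeric",
                        irisTextureAmplitude = "numeric",
                        nReflections = "integer",
                        reflectionRadiusRange = "numeric",
                        nEyelashes = "integer",
                        eyelidCoverageFraction = "numeric",
                        offAngleAxisRatio = "numeric",
                        blurSigma = "numeric", seed = "integer"),
         validity = function(object) {
  if (object@imageHeight < 16L || object@imageWidth < 16L)
    return("image must be at least 16x16")
  if (object@pupil@r >= object@iris@r)
    return("pupil radius must be smaller than iris radius")
  off <- sqrt((object@pupil@cx - object@iris@cx)^2 +
              (object@pupil@cy - object@iris@cy)^2)
  if (off > 3) return("pupil and iris centers must be within 3 px of each other")
  iv <- c(object@intensityPupil, object@intensityIris, object@intensitySclera)
  if (any(iv < 0 | iv > 1)) return("intensities must lie in [0, 1]")
  if (!(iv[1] < iv[2] && iv[2] < iv[3]))
    return("intensities must increase outward: pupil < iris < sclera")
  if (object@irisTextureAmplitude < 0 || object@irisTextureAmplitude > 1)
    return("irisTextureAmplitude must lie in [0, 1]")
  if (object@nReflections < 0L || object@nEyelashes < 0L)
    return("noise counts must be >= 0")
  if (length(object@reflectionRadiusRange) != 2L ||
      object@reflectionRadiusRange[1] > object@reflectionRadiusRange[2] ||
      object@reflectionRadiusRange[1] <= 0)
    return("reflectionRadiusRange must be a positive (min, max) pair")
  if (object@eyelidCoverageFraction < 0 || object@eyelidCoverageFraction > 0.5)
    return("eyelidCoverageFraction must lie in [0, 0.5]")
  if (object@offAngleAxisRatio <= 0 || object@offAngleAxisRatio > 1)
    return("offAngleAxisRatio must lie in (0, 1]")
  if (object@blurSigma < 0) return("blurSigma must be >= 0")
  # both boundaries must fit in the image when no eyelid occlusion is asked for
  if (object@eyelidCoverageFraction == 0) {
    a <- object@offAngleAxisRatio
    if (object@iris@cx - a * object@iris@r < 1 ||
        object@iris@cx + a * object@iris@r > object@imageWidth ||
        object@iris@cy - object@iris@r < 1 ||
        object@iris@cy + object@iris@r > object@imageHeight)
      return("iris circle exceeds image bounds")
  }
  TRUE
})

#' @param imageHeight,imageWidth image size in pixels.
#' @param pupil,iris \linkS4class{Circle} objects.
#' @param intensityPupil,intensityIris,intensitySclera base gray levels in [0,1].
#' @param irisTextureAmplitude texture amplitude in gray units.
#' @param nReflections number of reflection spots.
#' @param reflectionRadiusRange (min, max) reflection radius in pixels.
#' @param nEyelashes number of eyelash strokes.
#' @param eyelidCoverageFraction eyelid coverage of the iris, in [0, 0.5].
#' @param offAngleAxisRatio horizontal axis ratio in (0, 1].
#' @param blurSigma Gaussian blur sigma in pixels.
#' @param seed integer seed.
#' @rdname SceneSpec-class
#' @export
SceneSpec <- function(imageHeight = 224L, imageWidth = 224L,
                      pupil = Circle(112, 112, 20), iris = Circle(112, 112, 60),
                      intensityPupil = 0.10, intensityIris = 0.45,
                      intensitySclera = 0.85, irisTextureAmplitude = 0.04,
                      nReflections = 0L, reflectionRadiusRange = c(2, 4),
                      nEyelashes = 0L, eyelidCoverageFraction = 0,
                      offAngleAxisRatio = 1, blurSigma = 0, seed = 1L) {
  new("SceneSpec", imageHeight = as.integer(imageHeight),
      imageWidth = as.integer(imageWidth), pupil = pupil, iris = iris,
      intensityPupil = intensityPupil, intensityIris = intensityIris,
      intensitySclera = intensitySclera,
      irisTextureAmplitude = irisTextureAmplitude,
      nReflections = as.integer(nReflections),
      reflectionRadiusRange = as.numeric(reflectionRadiusRange),
      nEyelashes = as.integer(nEyelashes),
      eyelidCoverageFraction = as.numeric(eyelidCoverageFraction),
      offAngleAxisRatio = as.numeric(offAngleAxisRatio),
      blurSigma = as.numeric(blurSigma), seed = as.integer(seed))
}

#' Ground truth of a rendered synthetic scene
#'
#' Post-distortion ground truth emitted alongside each rendered scene: the
#' best-fit pupil and iris circles (equal-area circles when the scene is
#' off-angle), the tight bounding box of the iris, and the reflection-spot
#' centers.
#'
#' @slot spec the generating \linkS4class{SceneSpec}.
#' @slot pupil,iris ground-truth \linkS4class{Circle}s.
#' @slot bbox tight \linkS4class{BoundingBox} around the iris boundary.
#' @slot reflectionCenters two-column matrix (x, y) of reflection centers.
#' @export
setClass("SceneTruth",
         representation(spec = "SceneSpec", pupil = "Circle", iris = "Circle",
                        bbox = "BoundingBox", reflectionCenters = "matrix"))

#' Candidate grid for the circle-parameter search
#'
#' The exhaustive candidate set evaluated by \code{\link{searchMax}}: a list
#' of center candidates, a list of radius candidates, and the operator
#' parameters used to score every (center, radius) pair.
#'
#' @slot centers two-column numeric matrix of (cx, cy) candidates.
#' @slot radii numeric vector of radius candidates (pixels).
#' @slot params \linkS4class{OperatorParams}.
#' @export
setClass("SearchGrid",
         representation(centers = "matrix", radii = "numeric",
                        params = "OperatorParams"),
         validity = function(object) {
  if (nrow(object@centers) < 1L || ncol(object@centers) != 2L)
    return("centers must be a non-empty two-column matrix")
  if (length(object@radii) < 1L) return("radii must be non-empty")
  if (any(object@radii <= 0)) return("radii must be > 0")
  TRUE
})

#' @param centers two-column matrix of (cx, cy) candidates.
#' @param radii numeric vector of candidate radii.
#' @param params \linkS4class{OperatorParams}.
#' @rdname SearchGrid-class
#' @export
SearchGrid <- function(centers, radii, params = OperatorParams()) {
  new("SearchGrid", centers = matrix(as.numeric(centers), ncol = 2L),
      radii = as.numeric(radii), params = params)
}

#' A circle with its objective score
#'
#' @slot circle \linkS4class{Circle}.
#' @slot score numeric objective value (gray-gradient units).
#' @export
setClass("ScoredCircle", representation(circle = "Circle", score = "numeric"))

#' @param circle a \linkS4class{Circle}.
#' @param score numeric score.
#' @rdname ScoredCircle-class
#' @export
ScoredCircle <- function(circle, score) new("ScoredCircle", circle = circle,
                                            score = as.numeric(score))

#' Result of the two-stage iris localization
#'
#' @slot inner \linkS4class{ScoredCircle}, the pupillary boundary.
#' @slot outer \linkS4class{ScoredCircle}, the limbic boundary.
#' @slot bboxUsed the \linkS4class{BoundingBox} that seeded the search.
#' @slot status one of \code{"ok"}, \code{"inner_failed"}, \code{"outer_failed"}.
#' @slot paramsUsed list with the inner/outer \linkS4class{OperatorParams}
#'   and the objective name.
#' @export
setClass("LocalizationResult",
         representation(inner = "ScoredCircle", outer = "ScoredCircle",
                        bboxUsed = "BoundingBox", status = "character",
                        paramsUsed = "list"),
         validity = function(object) {
  if (!object@status %in% c("ok", "inner_failed", "outer_failed"))
    return("status must be ok, inner_failed or outer_failed")
  TRUE
})

## ---- accessors -------------------------------------------------------------

#' @describeIn Circle-class center as a named (cx, cy) vector.
#' @param object,x a Circle.
#' @export
setGeneric("center", function(object) standardGeneric("center"))

#' @rdname Circle-class
#' @export
setMethod("center", "Circle", function(object) c(cx = object@cx, cy = object@cy))

#' @rdname Circle-class
#' @export
setGeneric("radius", function(object) standardGeneric("radius"))

#' @rdname Circle-class
#' @export
setMethod("radius", "Circle", function(object) object@r)

#' @rdname ScoredCircle-class
#' @param object a ScoredCircle.
#' @export
setGeneric("score", function(object) standardGeneric("score"))

#' @rdname ScoredCircle-class
#' @export
setMethod("score", "ScoredCircle", function(object) object@score)

#' @rdname ScoredCircle-class
#' @export
setMethod("center", "ScoredCircle", function(object) center(object@circle))

#' @rdname ScoredCircle-class
#' @export
setMethod("radius", "ScoredCircle", function(object) radius(object@circle))

#' @describeIn SceneTruth-class ground-truth pupil circle.
#' @param object a SceneTruth.
#' @export
setGeneric("truthPupil", function(object) standardGeneric("truthPupil"))

#' @rdname SceneTruth-class
#' @export
setMethod("truthPupil", "SceneTruth", function(object) object@pupil)

#' @rdname SceneTruth-class
#' @export
setGeneric("truthIris", function(object) standardGeneric("truthIris"))

#' @rdname SceneTruth-class
#' @export
setMethod("truthIris", "SceneTruth", function(object) object@iris)

#' @rdname SceneTruth-class
#' @export
setGeneric("truthBox", function(object) standardGeneric("truthBox"))

#' @rdname SceneTruth-class
#' @export
setMethod("truthBox", "SceneTruth", function(object) object@bbox)

#' @rdname LocalizationResult-class
#' @param object a LocalizationResult.
#' @export
setGeneric("innerBoundary", function(object) standardGeneric("innerBoundary"))

#' @rdname LocalizationResult-class
#' @export
setMethod("innerBoundary", "LocalizationResult", function(object) object@inner)

#' @rdname LocalizationResult-class
#' @export
setGeneric("outerBoundary", function(object) standardGeneric("outerBoundary"))

#' @rdname LocalizationResult-class
#' @export
setMethod("outerBoundary", "LocalizationResult", function(object) object@outer)

#' @rdname LocalizationResult-class
#' @export
setGeneric("status", function(object) standardGeneric("status"))

#' @rdname LocalizationResult-class
#' @export
setMethod("status", "LocalizationResult", function(object) object@status)

## ---- show methods ----------------------------------------------------------

setMethod("show", "Circle", function(object) {
  cat(sprintf("Circle: center (%.2f, %.2f), r = %.2f px\n",
              object@cx, object@cy, object@r))
})

setMethod("show", "BoundingBox", function(object) {
  cat(sprintf("BoundingBox: (x, y) = (%.1f, %.1f), %g x %g px\n",
              object@x, object@y, object@w, object@h))
})

setMethod("show", "ScoredCircle", function(object) {
  cat(sprintf("ScoredCircle: center (%.2f, %.2f), r = %.2f px, score = %.4g\n",
              object@circle@cx, object@circle@cy, object@circle@r, object@score))
})

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf("SceneSpec %dx%d: pupil r=%.1f, iris r=%.1f", object@imageWidth,
              object@imageHeight, object@pupil@r, object@iris@r))
  cat(sprintf(", refl=%d, lashes=%d, eyelid=%.2f, axis=%.2f, seed=%d\n",
              object@nReflections, object@nEyelashes,
              object@eyelidCoverageFraction, object@offAngleAxisRatio,
              object@seed))
})

setMethod("show", "SceneTruth", function(object) {
  cat("SceneTruth\n  pupil: "); show(object@pupil)
  cat("  iris:  "); show(object@iris)
  cat("  bbox:  "); show(object@bbox)
  cat(sprintf("  reflections: %d\n", nrow(object@reflectionCenters)))
})

setMethod("show", "LocalizationResult", function(object) {
  cat(sprintf("LocalizationResult [%s]\n", object@status))
  cat("  inner: "); show(object@inner)
  cat("  outer: "); show(object@outer)
})

setMethod("show", "SearchGrid", function(object) {
  cat(sprintf("SearchGrid: %d centers x %d radii (%d candidates), n = %d\n",
              nrow(object@centers), length(object@radii),
              nrow(object@centers) * length(object@radii), object@params@n))
})

#' Convert results to plain data frames
#'
#' @param x a \linkS4class{LocalizationResult}.
#' @param row.names,optional,... passed through (unused).
#' @return one-row \code{data.frame} with inner/outer circle parameters,
#'   scores and status.
#' @export
as.data.frame.LocalizationResult <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  data.frame(inner_cx = x@inner@circle@cx, inner_cy = x@inner@circle@cy,
             inner_r = x@inner@circle@r, inner_score = x@inner@score,
             outer_cx = x@outer@circle@cx, outer_cy = x@outer@circle@cy,
             outer_r = x@outer@circle@r, outer_score = x@outer@score,
             status = x@status, stringsAsFactors = FALSE)
}
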