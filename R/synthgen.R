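# Synthetic eye-scene generator: dark pupil disk inside a textured iris
# annulus inside a bright sclera, with the noise classes of non-cooperative
# acquisition (specular reflections, eyelashes, eyelid occlusion, off-angle
# distortion, blur). Every scene carries exact ground truth, so boundary
# recovery is testable without any external dataset.

# Fixed rendering constants (gray levels in [0,1])
.LID_INTENSITY  <- 0.72
.LASH_INTENSITY <- 0.08
.REFL_INTENSITY <- 0.99

#' Render one synthetic eye scene
#'
#' Deterministically renders the scene described by \code{spec} and returns
#' the image together with its post-distortion ground truth. Boundaries are
#' anti-aliased with a 1-px linear soft edge by default; \code{hardEdge =
#' TRUE} renders ideal hard-edged disks (a pixel takes the inner value iff
#' its center lies inside the boundary), which makes analytic checks exact.
#'
#' Off-angle distortion scales the horizontal axis of both boundaries by
#' \code{offAngleAxisRatio}; the reported truth circles are then the
#' equal-area circles of the rendered ellipses (radius \eqn{r\sqrt{a}}),
#' centered at the ellipse centers.
#'
#' @param spec a \linkS4class{SceneSpec}.
#' @param hardEdge logical; render hard boundary edges (no anti-aliasing).
#' @return list with elements \code{image} (numeric matrix in [0,1], indexed
#'   [row, col]) and \code{truth} (a \linkS4class{SceneTruth}).
#' @examples
#' sc <- renderScene(SceneSpec(seed = 7L))
#' dim(sc$image)
#' truthIris(sc$truth)
#' @export
renderScene <- function(spec, hardEdge = FALSE) {
  stopifnot(is(spec, "SceneSpec"))
  validObject(spec)
  h <- spec@imageHeight; w <- spec@imageWidth
  a <- spec@offAngleAxisRatio
  if (spec@eyelidCoverageFraction == 0 &&
      (spec@iris@cx - a * spec@iris@r < 1 ||
       spec@iris@cx + a * spec@iris@r > w ||
       spec@iris@cy - spec@iris@r < 1 ||
       spec@iris@cy + spec@iris@r > h))
    stop("iris circle exceeds image bounds")

  X <- matrix(seq_len(w), h, w, byrow = TRUE)
  Y <- matrix(seq_len(h), h, w)

  cov <- function(rho, r) {
    if (hardEdge) (rho <= r) * 1 else .clamp01(r + 0.5 - rho)
  }

  .withSeed(spec@seed, {
    rhoI <- sqrt(((X - spec@iris@cx) / a)^2 + (Y - spec@iris@cy)^2)
    rhoP <- sqrt(((X - spec@pupil@cx) / a)^2 + (Y - spec@pupil@cy)^2)

    img <- matrix(spec@intensitySclera, h, w)

    irisVal <- matrix(spec@intensityIris, h, w)
    if (spec@irisTextureAmplitude > 0) {
      amp <- spec@irisTextureAmplitude
      phase <- stats::runif(1, 0, 2 * pi)
      lambda <- stats::runif(1, 5, 8)
      tex <- amp * sin(2 * pi * rhoI / lambda + phase) +
        matrix(stats::runif(h * w, -amp / 3, amp / 3), h, w)
      irisVal <- irisVal + tex
    }
    cI <- cov(rhoI, spec@iris@r)
    img <- img * (1 - cI) + irisVal * cI
    cP <- cov(rhoP, spec@pupil@r)
    img <- img * (1 - cP) + spec@intensityPupil * cP

    # upper eyelid: covers the top fraction of the iris vertical extent
    lidY <- -Inf
    if (spec@eyelidCoverageFraction > 0) {
      lidY <- (spec@iris@cy - spec@iris@r) +
        spec@eyelidCoverageFraction * 2 * spec@iris@r
      cL <- if (hardEdge) (Y <= lidY) * 1 else .clamp01(lidY - Y + 0.5)
      img <- img * (1 - cL) + .LID_INTENSITY * cL
    }

    # eyelash strokes: dark anti-aliased segments hanging into the upper iris
    if (spec@nEyelashes > 0L) {
      for (i in seq_len(spec@nEyelashes)) {
        x0 <- spec@iris@cx + stats::runif(1, -0.8, 0.8) * a * spec@iris@r
        y0 <- if (is.finite(lidY)) lidY else spec@iris@cy - spec@iris@r
        tilt <- stats::runif(1, -0.45, 0.45)
        len <- stats::runif(1, 0.35, 0.65) * spec@iris@r
        halfw <- stats::runif(1, 0.5, 1.0)
        x1 <- x0 + sin(tilt) * len
        y1 <- y0 + cos(tilt) * len
        img <- .drawSegment(img, x0, y0, x1, y1, halfw, .LASH_INTENSITY,
                            hardEdge)
      }
    }

    # specular reflection spots: near-saturated disks around the iris region
    reflC <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y")))
    if (spec@nReflections > 0L) {
      for (i in seq_len(spec@nReflections)) {
        ang <- stats::runif(1, 0, 2 * pi)
        d <- stats::runif(1, 0.3, 1.1) * spec@iris@r
        rcx <- min(max(spec@iris@cx + a * d * cos(ang), 4), w - 3)
        rcy <- min(max(spec@iris@cy + d * sin(ang), 4), h - 3)
        rr <- stats::runif(1, spec@reflectionRadiusRange[1],
                           spec@reflectionRadiusRange[2])
        rho <- sqrt((X - rcx)^2 + (Y - rcy)^2)
        cR <- cov(rho, rr)
        img <- img * (1 - cR) + .REFL_INTENSITY * cR
        reflC <- rbind(reflC, c(rcx, rcy))
      }
    }

    if (spec@blurSigma > 0) img <- .gaussBlur(img, spec@blurSigma)
    img <- .clamp01(img)

    sa <- sqrt(a)  # equal-area circle of the rendered ellipse
    truth <- new("SceneTruth", spec = spec,
                 pupil = Circle(spec@pupil@cx, spec@pupil@cy, spec@pupil@r * sa),
                 iris = Circle(spec@iris@cx, spec@iris@cy, spec@iris@r * sa),
                 bbox = .ellipseBBox(spec@iris@cx, spec@iris@cy,
                                     a * spec@iris@r, spec@iris@r, w, h),
                 reflectionCenters = reflC)
    list(image = img, truth = truth)
  })
}

# Tight pixel bounding box of an axis-aligned ellipse (semi-axes ax, ay).
.ellipseBBox <- function(cx, cy, ax, ay, w, h) {
  x1 <- max(1, ceiling(cx - ax - 0.5)); x2 <- min(w, floor(cx + ax + 0.5))
  y1 <- max(1, ceiling(cy - ay - 0.5)); y2 <- min(h, floor(cy + ay + 0.5))
  BoundingBox(x1, y1, x2 - x1 + 1, y2 - y1 + 1)
}

# Blend an anti-aliased thick segment into the image.
.drawSegment <- function(img, x0, y0, x1, y1, halfw, value, hardEdge = FALSE) {
  h <- nrow(img); w <- ncol(img)
  pad <- ceiling(halfw) + 1
  cmin <- max(1, floor(min(x0, x1) - pad)); cmax <- min(w, ceiling(max(x0, x1) + pad))
  rmin <- max(1, floor(min(y0, y1) - pad)); rmax <- min(h, ceiling(max(y0, y1) + pad))
  if (cmin > cmax || rmin > rmax) return(img)
  cols <- cmin:cmax; rows <- rmin:rmax
  Xs <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  Ys <- matrix(rows, length(rows), length(cols))
  dx <- x1 - x0; dy <- y1 - y0
  L2 <- dx * dx + dy * dy
  t <- if (L2 == 0) 0 else .clamp01(((Xs - x0) * dx + (Ys - y0) * dy) / L2)
  d <- sqrt((Xs - (x0 + t * dx))^2 + (Ys - (y0 + t * dy))^2)
  alpha <- if (hardEdge) (d <= halfw) * 1 else .clamp01(halfw + 0.5 - d)
  img[rows, cols] <- img[rows, cols] * (1 - alpha) + value * alpha
  img
}

#' Scene parameter ranges for batch generation
#'
#' Sampling ranges used by \code{\link{generateBatch}}. The \code{noise}
#' presets select which interference classes are active: \code{"clean"} has
#' none, single-noise strata activate one class, and \code{"combined"}
#' activates reflections, eyelashes and eyelid occlusion together.
#'
#' @param noise one of \code{"clean"}, \code{"reflections"},
#'   \code{"eyelashes"}, \code{"occlusion"}, \code{"off_angle"},
#'   \code{"combined"}.
#' @return named list of (min, max) ranges consumed by
#'   \code{\link{generateBatch}}.
#' @export
sceneParamRanges <- function(noise = c("clean", "reflections", "eyelashes",
                                       "occlusion", "off_angle", "combined")) {
  noise <- match.arg(noise)
  rng <- list(
    imageHeight = c(224, 224), imageWidth = c(224, 224),
    irisR = c(48, 66), pupilR = c(16, 28), pupilRFracMax = 0.45,
    centerJitter = c(-8, 8), offsetMax = 2,
    intensityPupil = c(0.08, 0.12), intensityIris = c(0.40, 0.50),
    intensitySclera = c(0.82, 0.88), textureAmplitude = c(0.04, 0.04),
    nReflections = c(0, 0), reflectionRadius = c(2, 4),
    nEyelashes = c(0, 0), eyelidCoverage = c(0, 0),
    axisRatio = c(1, 1), blurSigma = c(0.5, 0.5)
  )
  if (noise %in% c("reflections", "combined")) rng$nReflections <- c(2, 4)
  if (noise %in% c("eyelashes", "combined")) rng$nEyelashes <- c(3, 6)
  if (noise %in% c("occlusion", "combined")) rng$eyelidCoverage <- c(0.15, 0.30)
  if (noise == "off_angle") rng$axisRatio <- c(0.92, 1)
  rng
}

#' Generate a reproducible batch of synthetic scenes
#'
#' Draws \code{n} scene specifications from \code{ranges} with a seeded
#' sampler and renders each. The batch is fully reproducible from
#' \code{(n, ranges, seed)}. When \code{outDir} is given, each image is
#' written as an 8-bit grayscale PNG with a JSON ground-truth sidecar, plus a
#' \code{manifest.csv} listing all truth fields.
#'
#' @param n number of scenes (>= 1).
#' @param ranges parameter ranges, see \code{\link{sceneParamRanges}}.
#' @param seed integer seed for the batch sampler.
#' @param outDir optional output directory.
#' @param hardEdge passed to \code{\link{renderScene}}.
#' @return list of \code{list(image, truth)} scene records (invisibly when
#'   \code{outDir} is given).
#' @export
generateBatch <- function(n, ranges = sceneParamRanges(), seed = 1L,
                          outDir = NULL, hardEdge = FALSE) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be >= 1")
  n <- as.integer(n)
  for (nm in setdiff(names(ranges), c("pupilRFracMax", "offsetMax"))) {
    v <- ranges[[nm]]
    if (length(v) != 2L || v[1] > v[2])
      stop("invalid range for '", nm, "': min must be <= max")
  }
  specs <- .withSeed(seed, {
    lapply(seq_len(n), function(i) .sampleSpec(ranges))
  })
  scenes <- lapply(specs, renderScene, hardEdge = hardEdge)
  if (!is.null(outDir)) {
    writeSceneBatch(scenes, outDir)
    return(invisible(scenes))
  }
  scenes
}

# Draw one SceneSpec from ranges; consumes the current RNG stream.
.sampleSpec <- function(rng) {
  u <- function(r) stats::runif(1, r[1], r[2])
  ui <- function(r) if (r[1] == r[2]) as.integer(r[1]) else
    sample(seq.int(r[1], r[2]), 1L)
  h <- as.integer(rng$imageHeight[1]); w <- as.integer(rng$imageWidth[1])
  icx <- w / 2 + u(rng$centerJitter)
  icy <- h / 2 + u(rng$centerJitter)
  irisR <- u(rng$irisR)
  pupilR <- min(u(rng$pupilR), rng$pupilRFracMax * irisR)
  offAng <- stats::runif(1, 0, 2 * pi)
  offD <- stats::runif(1, 0, rng$offsetMax)
  SceneSpec(imageHeight = h, imageWidth = w,
            pupil = Circle(icx + offD * cos(offAng), icy + offD * sin(offAng),
                           pupilR),
            iris = Circle(icx, icy, irisR),
            intensityPupil = u(rng$intensityPupil),
            intensityIris = u(rng$intensityIris),
            intensitySclera = u(rng$intensitySclera),
            irisTextureAmplitude = u(rng$textureAmplitude),
            nReflections = ui(rng$nReflections),
            reflectionRadiusRange = rng$reflectionRadius,
            nEyelashes = ui(rng$nEyelashes),
            eyelidCoverageFraction = u(rng$eyelidCoverage),
            offAngleAxisRatio = u(rng$axisRatio),
            blurSigma = u(rng$blurSigma),
            seed = sample.int(.Machine$integer.max - 1L, 1L))
}

# Truth -> plain list for JSON serialization.
.truthToList <- function(truth) {
  list(pupil = list(cx = truth@pupil@cx, cy = truth@pupil@cy, r = truth@pupil@r),
       iris = list(cx = truth@iris@cx, cy = truth@iris@cy, r = truth@iris@r),
       bbox = list(x = truth@bbox@x, y = truth@bbox@y,
                   w = truth@bbox@w, h = truth@bbox@h),
       reflection_centers = if (nrow(truth@reflectionCenters))
         unname(apply(truth@reflectionCenters, 1L,
                      function(p) list(x = p[1], y = p[2]), simplify = FALSE))
       else list())
}

#' Write a scene batch to disk
#'
#' @param scenes list of \code{list(image, truth)} records from
#'   \code{\link{generateBatch}}.
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest \code{data.frame}.
#' @export
writeSceneBatch <- function(scenes, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(scenes), function(i) {
    sc <- scenes[[i]]
    stem <- sprintf("scene_%04d", i)
    png::writePNG(sc$image, file.path(dir, paste0(stem, ".png")))
    jsonlite::write_json(.truthToList(sc$truth),
                         file.path(dir, paste0(stem, ".json")),
                         auto_unbox = TRUE, digits = NA)
    tr <- sc$truth
    data.frame(filename = paste0(stem, ".png"),
               pupil_cx = tr@pupil@cx, pupil_cy = tr@pupil@cy,
               pupil_r = tr@pupil@r,
               iris_cx = tr@iris@cx, iris_cy = tr@iris@cy, iris_r = tr@iris@r,
               bbox_x = tr@bbox@x, bbox_y = tr@bbox@y,
               bbox_w = tr@bbox@w, bbox_h = tr@bbox@h,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
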