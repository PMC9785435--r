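test_that("noiseless hard-edge scene is three-tone and in range", {
  spec <- SceneSpec(irisTextureAmplitude = 0, seed = 2L)
  sc <- renderScene(spec, hardEdge = TRUE)
  expect_true(all(sc$image >= 0 & sc$image <= 1))
  expect_identical(sort(unique(as.vector(sc$image))), c(0.10, 0.45, 0.85))
})

test_that("rendering is deterministic for a fixed seed", {
  spec <- SceneSpec(seed = 7L, nReflections = 3L, nEyelashes = 4L,
                    eyelidCoverageFraction = 0.2, blurSigma = 0.5)
  a <- renderScene(spec)
  b <- renderScene(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$truth@reflectionCenters, b$truth@reflectionCenters)
})

test_that("truth bbox tightly encloses the iris circle", {
  sc <- renderScene(SceneSpec(pupil = Circle(112, 112, 20),
                              iris = Circle(112, 112, 60), seed = 1L))
  bb <- truthBox(sc$truth)
  expect_true(bb@w %in% c(120, 121) && bb@h %in% c(120, 121))
  expect_equal(bb@x + (bb@w - 1) / 2, 112)
  expect_equal(bb@y + (bb@h - 1) / 2, 112)
})

test_that("off-angle truth uses the equal-area circle of the rendered ellipse", {
  spec <- SceneSpec(offAngleAxisRatio = 0.9, seed = 3L)
  sc <- renderScene(spec)
  expect_equal(radius(truthIris(sc$truth)), 60 * sqrt(0.9))
  expect_equal(radius(truthPupil(sc$truth)), 20 * sqrt(0.9))
  # bbox narrower horizontally than vertically
  expect_lt(truthBox(sc$truth)@w, truthBox(sc$truth)@h)
})

test_that("spec invariants are enforced", {
  expect_error(SceneSpec(pupil = Circle(112, 112, 70)), "pupil radius")
  expect_error(SceneSpec(intensityPupil = 0.5, intensityIris = 0.4),
               "increase outward")
  expect_error(SceneSpec(pupil = Circle(100, 112, 20)), "within 3 px")
  expect_error(SceneSpec(iris = Circle(30, 112, 60), pupil = Circle(30, 112, 15)),
               "exceeds image bounds")
})

test_that("reflection spots are near-saturated and eyelashes dark", {
  sc <- renderScene(SceneSpec(seed = 5L, nReflections = 3L))
  rc <- sc$truth@reflectionCenters
  expect_identical(nrow(rc), 3L)
  for (i in seq_len(nrow(rc)))
    expect_gte(sc$image[round(rc[i, 2]), round(rc[i, 1])], 0.95)
  lash <- renderScene(SceneSpec(seed = 5L, nEyelashes = 4L))
  expect_lte(min(lash$image), 0.15)
})

test_that("ground-truth consistency: max radial step sits at the truth radii", {
  sc <- renderScene(SceneSpec(seed = 9L))
  tr <- sc$truth
  for (deg in c(0, 45, 120, 200, 300)) {
    rho <- seq(2, 90, by = 0.5)
    # intensity profile along the ray at `deg`: first sample of an arc
    # starting there, at each radius
    iv <- sapply(rho, function(r)
      sampleOnCircle(sc$image, Circle(tr@pupil@cx, tr@pupil@cy, r), 8,
                     arcs = rbind(c(deg, (deg + 90) %% 360)))$intensity[1])
    d <- diff(iv)
    mid <- (radius(truthPupil(tr)) + radius(truthIris(tr))) / 2
    innerIdx <- which(rho < mid)
    stepP <- rho[innerIdx][which.max(d[innerIdx])]
    expect_lt(abs(stepP + 0.25 - radius(truthPupil(tr))), 1)
    outerIdx <- which(rho >= mid & rho < 89)
    stepI <- rho[outerIdx][which.max(d[outerIdx])]
    expect_lt(abs(stepI + 0.25 - radius(truthIris(tr))), 1)
  }
})

test_that("generateBatch is reproducible, validated, and writes sidecars", {
  expect_error(generateBatch(0), ">= 1")
  rng <- sceneParamRanges("clean")
  rng$irisR <- c(66, 48)
  expect_error(generateBatch(2, rng), "min must be <= max")

  b1 <- generateBatch(10, sceneParamRanges("clean"), seed = 0L)
  b2 <- generateBatch(10, sceneParamRanges("clean"), seed = 0L)
  expect_identical(lapply(b1, `[[`, "image"), lapply(b2, `[[`, "image"))
  specs <- vapply(b1, function(s) s$truth@spec@seed, integer(1))
  expect_identical(length(unique(specs)), 10L)

  b3 <- generateBatch(100, sceneParamRanges("combined"), seed = 1L)
  for (s in b3)
    expect_lt(radius(truthPupil(s$truth)), radius(truthIris(s$truth)))

  d <- file.path(tempdir(), "scenes-test")
  on.exit(unlink(d, recursive = TRUE), add = TRUE)
  writeSceneBatch(b1[1:2], d)
  expect_true(file.exists(file.path(d, "scene_0001.png")))
  j <- jsonlite::fromJSON(file.path(d, "scene_0001.json"))
  expect_equal(j$iris$r, radius(truthIris(b1[[1]]$truth)))
  man <- read.csv(file.path(d, "manifest.csv"))
  expect_identical(nrow(man), 2L)
  # PNG round trip preserves the 8-bit quantized image
  img <- png::readPNG(file.path(d, "scene_0001.png"))
  expect_equal(img, matrix(round(b1[[1]]$image * 255) / 255,
                           nrow(img), ncol(img)), tolerance = 1 / 255)
})
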