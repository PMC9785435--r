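test_that("toGray handles gray, RGB and degenerate inputs", {
  g <- matrix(runif(20), 4, 5)
  expect_equal(toGray(g), g)
  rgb <- array(128, c(4, 4, 3))
  expect_equal(unique(as.vector(toGray(rgb))), 128 / 255)
  red <- array(0, c(4, 4, 3)); red[, , 1] <- 255
  expect_equal(unique(as.vector(toGray(red))), 0.299)
  expect_error(toGray(array(0.5, c(2, 2, 2, 2))), "dimensions")
  expect_error(toGray(1:5), "dimensions")
})

test_that("reflection detection thresholds, dilates and counts components", {
  sc <- renderScene(SceneSpec(irisTextureAmplitude = 0, seed = 2L))
  expect_false(any(detectReflections(sc$image, 0.90)))  # sclera max 0.85
  expect_error(detectReflections(sc$image, 1.5), "\\(0, 1\\)")

  img <- matrix(0.4, 100, 100)
  centers <- list(c(20, 20), c(50, 70), c(80, 40))
  for (cc in centers) img <- paintSpot(img, cc[1], cc[2], 3)
  m <- detectReflections(img, 0.90)
  expect_identical(max(EBImage::bwlabel(m * 1)), 3L)
  for (cc in centers) expect_true(m[cc[2], cc[1]])
  # dilation margin: mask extends beyond the spot
  expect_true(m[20 + 5, 20])
  expect_false(m[20 + 8, 20])
})

test_that("harmonic inpainting is local, bounded and converges to the boundary value", {
  img <- matrix(0.4, 40, 40)
  mask <- matrix(FALSE, 40, 40); mask[15:25, 15:25] <- TRUE
  expect_equal(inpaintReflections(img, mask), img)  # constant boundary

  expect_identical(inpaintReflections(img, matrix(FALSE, 40, 40)), img)
  expect_error(inpaintReflections(img, matrix(TRUE, 40, 40)), "all-true")

  # bright spot inside a uniform dark pupil: fill returns to the background
  img2 <- paintSpot(matrix(0.10, 60, 60), 30, 30, 3, 0.98)
  mask2 <- detectReflections(img2, 0.90)
  out <- inpaintReflections(img2, mask2)
  expect_true(all(abs(out[mask2] - 0.10) < 0.02))
  expect_identical(out[!mask2], img2[!mask2])  # exact locality
  expect_true(all(out >= 0 & out <= 1))
})

test_that("closing is extensive, idempotent and suppresses a lash stroke", {
  img <- matrix(0.5, 30, 30)
  expect_equal(suppressEyelashes(img, 3), img)

  sc <- renderScene(SceneSpec(seed = 6L))
  cl1 <- suppressEyelashes(sc$image, 3)
  expect_true(all(cl1 >= sc$image - 1e-12))            # extensive
  expect_equal(suppressEyelashes(cl1, 3), cl1)          # idempotent

  clean <- renderScene(SceneSpec(seed = 6L))$image
  noisy <- renderScene(SceneSpec(seed = 6L, nEyelashes = 1L))$image
  foot <- which(abs(noisy - clean) > 0.05)
  expect_gt(length(foot), 10)
  fixed <- suppressEyelashes(noisy, 3)
  madBefore <- mean(abs(noisy[foot] - clean[foot]))
  madAfter <- mean(abs(fixed[foot] - clean[foot]))
  expect_lt(madAfter, 0.5 * madBefore)
})

test_that("denoise composes stages in order and stays bounded", {
  sc <- renderScene(SceneSpec(seed = 2L))
  cfg0 <- irisConfig(denoise = list(stages_enabled = character(0)))
  expect_identical(denoise(sc$image, cfg0), sc$image)   # all stages off

  # noiseless scene: reflections stage is a no-op, equal to closing alone
  cfg <- irisConfig(denoise = list(box_only = FALSE))
  expect_equal(denoise(sc$image, cfg), suppressEyelashes(sc$image, 3),
               tolerance = 1e-6)

  b <- generateBatch(1, sceneParamRanges("combined"), seed = 3L)
  den <- denoise(b[[1]]$image, irisConfig(), box = truthBox(b[[1]]$truth))
  expect_lt(max(den[truthBox(b[[1]]$truth)@y:(truthBox(b[[1]]$truth)@y +
                 truthBox(b[[1]]$truth)@h - 1),
                 truthBox(b[[1]]$truth)@x:(truthBox(b[[1]]$truth)@x +
                 truthBox(b[[1]]$truth)@w - 1)]), 0.95)
  expect_true(all(den >= 0 & den <= 1))
  expect_identical(dim(den), dim(b[[1]]$image))
})
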