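test_that("outer radius range follows the open-interval rule", {
  expect_identical(outerRadiusRange(30, BoundingBox(1, 1, 200, 180)), 37:99)
  expect_length(outerRadiusRange(90, BoundingBox(1, 1, 200, 180)), 0)
  # monotonicity of the lower end
  lows <- sapply(c(10, 20, 30, 40), function(rp)
    min(outerRadiusRange(rp, BoundingBox(1, 1, 200, 180))))
  expect_true(all(diff(lows) > 0))
})

test_that("inner and outer boundaries are recovered on clean scenes", {
  sc <- renderScene(cleanSpec(seed = 31L))
  tr <- sc$truth
  den <- denoise(sc$image, irisConfig(), box = truthBox(tr))
  inner <- locateInner(den, truthBox(tr))
  rp <- circleRecovery(inner@circle, truthPupil(tr), 1, 1)
  expect_true(rp$hit)
  outer <- locateOuter(den, inner, truthBox(tr))
  ri <- circleRecovery(outer@circle, truthIris(tr), 2, 2)
  expect_true(ri$hit)
  # concentric scene: recovered centers agree closely
  expect_lte(sqrt(sum((center(outer) - center(inner))^2)), 1)
  # reported outer radius lies strictly inside its admissible range
  rng <- outerRadiusRange(radius(inner), truthBox(tr))
  expect_true(radius(outer) %in% rng)
})

test_that("a reflection inside the pupil does not break inner recovery", {
  clean <- renderScene(cleanSpec(seed = 32L))
  tr <- clean$truth
  spot <- paintSpot(clean$image, tr@pupil@cx + 8, tr@pupil@cy, 3, 0.98)
  den <- denoise(spot, irisConfig(), box = truthBox(tr))
  inner <- locateInner(den, truthBox(tr))
  expect_true(circleRecovery(inner@circle, truthPupil(tr), 1, 1)$hit)
})

test_that("eyelid occlusion is tolerated by the lateral-arc outer search", {
  sc <- renderScene(SceneSpec(seed = 33L, eyelidCoverageFraction = 0.25,
                              blurSigma = 0.5))
  tr <- sc$truth
  res <- locateIris(sc$image, truthBox(tr))
  expect_identical(status(res), "ok")
  expect_true(circleRecovery(outerBoundary(res)@circle, truthIris(tr))$hit)
})

test_that("full pipeline handles failure paths and stays deterministic", {
  res <- locateIris(matrix(0.5, 120, 120))
  expect_identical(status(res), "inner_failed")

  sc <- renderScene(cleanSpec(seed = 34L))
  r1 <- locateIris(sc$image, truthBox(sc$truth))
  r2 <- locateIris(sc$image, truthBox(sc$truth))
  expect_identical(resultToJSON(r1), resultToJSON(r2))
  expect_identical(status(r1), "ok")
  # Eq.-5 style containment on the reported result
  expect_gt(radius(outerBoundary(r1)), 1.2 * radius(innerBoundary(r1)))

  df <- as.data.frame(r1)
  expect_identical(nrow(df), 1L)
  expect_equal(df$outer_r, radius(outerBoundary(r1)))
})

test_that("daugman pipeline shares grids and agrees on clean scenes", {
  sc <- renderScene(cleanSpec(seed = 35L))
  tr <- sc$truth
  rm_ <- locateIris(sc$image, truthBox(tr))
  rd <- locateIrisDaugman(sc$image, truthBox(tr))
  expect_identical(status(rd), "ok")
  dm <- abs(c(center(innerBoundary(rm_)) - center(innerBoundary(rd)),
              radius(innerBoundary(rm_)) - radius(innerBoundary(rd)),
              center(outerBoundary(rm_)) - center(outerBoundary(rd)),
              radius(outerBoundary(rm_)) - radius(outerBoundary(rd))))
  expect_lte(max(dm), 1)

  # grid parity: identical inner candidate sets by construction
  den <- denoise(sc$image, irisConfig(), box = truthBox(tr))
  g1 <- boxToSearch(truthBox(tr), den, irisConfig())$innerGrid
  g2 <- boxToSearch(truthBox(tr), den, irisConfig())$innerGrid
  expect_identical(g1@centers, g2@centers)
  expect_identical(g1@radii, g2@radii)
})

test_that("pipeline works end to end from a PNG file and coarse estimate", {
  sc <- renderScene(cleanSpec(seed = 36L))
  f <- file.path(tempdir(), "eye.png")
  on.exit(unlink(f), add = TRUE)
  png::writePNG(sc$image, f)
  res <- locateIris(f)          # no box: coarse pupil estimate path
  expect_identical(status(res), "ok")
  expect_true(circleRecovery(innerBoundary(res)@circle,
                             truthPupil(sc$truth))$hit)
  ov <- drawOverlay(readGrayImage(f), res)
  expect_identical(dim(ov), dim(sc$image))
})
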