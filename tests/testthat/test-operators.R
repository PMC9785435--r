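# Oracle geometry: a hard-edged disk of radius 20. Bilinear corner pixels sit
# at most sqrt(2) px from a sample point, so a ring at r = 18.5 touches only
# inside pixels and a ring at r = 21.5 only outside pixels; gradients across
# the pair are exactly the intensity step.

test_that("circular sampling reads constants, hard edges and bounds correctly", {
  img <- matrix(0.5, 80, 80)
  s <- sampleOnCircle(img, Circle(40, 40, 15), 32)
  expect_true(all(s$valid))
  expect_equal(unique(s$intensity), 0.5)

  big <- sampleOnCircle(img, Circle(40, 40, 100), 32)
  expect_false(any(big$valid))

  disk <- makeDisk(60, 60, 20)
  onEdge <- sampleOnCircle(disk, Circle(60, 60, 21.5), 32)
  expect_equal(range(onEdge$intensity), c(0.9, 0.9))
  expect_error(sampleOnCircle(img, Circle(40, 40, 10), n = 4), ">= 8")
})

test_that("radial gradient matches the straddle and interior-constancy oracles", {
  img <- matrix(0.5, 80, 80)
  p <- OperatorParams(n = 32L)
  rs <- radialGradient(img, Circle(40, 40, 15), p)
  expect_equal(unique(rs@g), 0)

  disk <- makeDisk(60, 60, 20)
  p3 <- OperatorParams(n = 32L, deltaR = 3)
  straddle <- radialGradient(disk, Circle(60, 60, 18.5), p3)
  expect_equal(range(straddle@g), c(0.8, 0.8))
  interior <- radialGradient(disk, Circle(60, 60, 10), p3)
  expect_equal(unique(interior@g), 0)
  # sign convention flips
  pd <- OperatorParams(n = 32L, deltaR = 3, gradientSign = "outward_darker")
  expect_equal(range(radialGradient(disk, Circle(60, 60, 18.5), pd)@g),
               c(-0.8, -0.8))
})

test_that("compensation reproduces the hand-computed cases", {
  expect_equal(compensation(c(2, 10, 4))[2], 7)
  expect_equal(unique(compensation(rep(1.3, 16))), 0)
  a <- 0.3
  expect_equal(unique(compensation(rep(c(a, -a), 8))), 2 * a)
  expect_error(compensation(c(1, 2)), "at least 3")

  # partial arc: the missing neighbor term is replaced by the existing one
  pp <- OperatorParams(n = 8L, arcs = rbind(c(0, 90)))
  rs <- radialGradient(matrix(0.5, 50, 50), Circle(25, 25, 10), pp)
  rs@g <- c(1, 5, 2, 2, 2, 2, 2, 3)
  cc <- compensation(rs)@C
  expect_equal(cc[1], abs(5 - 1))          # open start: |g2 - g1|
  expect_equal(cc[8], abs(3 - 2))          # open end:   |g7 - g8|
  expect_equal(cc[2], 0.5 * (abs(1 - 5) + abs(2 - 5)))
})

test_that("modified score matches the ideal-edge and spike-perturbation oracles", {
  expect_equal(score(modifiedScore(matrix(0.5, 60, 60), Circle(30, 30, 10))), 0)

  disk <- makeDisk(60, 60, 20)
  p3 <- OperatorParams(n = 32L, deltaR = 3)
  ms <- modifiedScore(disk, Circle(60, 60, 18.5), p3)
  expect_equal(score(ms), 32 * 0.8)
  # uncompensated equals compensated on the equal-gradient circle
  expect_equal(score(modifiedScore(disk, Circle(60, 60, 18.5), p3,
                                   compensate = FALSE)), 32 * 0.8)

  # one spike g[k] = 2.0 among 0.8: hand-evaluated sum(g - C) = n*0.8 - 1.2
  g <- rep(0.8, 32); g[10] <- 2.0
  C <- compensation(g)
  expect_equal(sum(g - C), 32 * 0.8 - 1.2)
  expect_lt(sum(g - C), 32 * 0.8 + 1.2)
})

test_that("daugman profile peaks at hard edges", {
  disk <- makeDisk(60, 60, 20)
  ds <- daugmanScore(disk, c(60, 60), 10:30, OperatorParams(n = 64L))
  scores <- vapply(ds, score, numeric(1))
  expect_lte(abs((10:30)[which.max(scores)] - 20), 1)
  expect_equal(unique(vapply(daugmanScore(matrix(0.5, 60, 60), c(30, 30),
                                          10:20), score, numeric(1))), 0)

  two <- makeTwoEdge()
  s2 <- vapply(daugmanScore(two, c(112, 112), 10:80, OperatorParams(n = 64L)),
               score, numeric(1))
  rr <- 10:80
  locmax <- rr[which(diff(sign(diff(s2))) == -2) + 1]
  top2 <- sort(locmax[order(s2[match(locmax, rr)], decreasing = TRUE)][1:2])
  expect_lte(abs(top2[1] - 20), 1)
  expect_lte(abs(top2[2] - 60), 1)
})

test_that("searchMax equals a literal nested-loop maximum and honors ties", {
  set.seed(42)
  img <- matrix(runif(80 * 80), 80, 80)
  p <- OperatorParams(n = 16L)
  for (rep in 1:5) {
    centers <- as.matrix(expand.grid(sample(25:55, 4), sample(25:55, 4)))
    radii <- sort(sample(5:20, 5))
    grid <- SearchGrid(centers, radii, p)
    got <- searchMax(img, grid, "modified")
    # independent nested-loop oracle over the same candidates
    best <- -Inf; bestC <- NULL
    for (ri in radii) for (ci in seq_len(nrow(centers))) {
      s <- score(modifiedScore(img, Circle(centers[ci, 1], centers[ci, 2], ri), p))
      if (s > best) { best <- s; bestC <- c(centers[ci, ], ri) }
    }
    expect_equal(score(got), best)
    expect_equal(unname(c(center(got), radius(got))), unname(bestC))
  }

  # single candidate grid
  single <- SearchGrid(cbind(40, 40), 10, p)
  one <- searchMax(img, single, "modified")
  expect_equal(unname(c(center(one), radius(one))), c(40, 40, 10))
  expect_equal(score(one), score(modifiedScore(img, Circle(40, 40, 10), p)))

  # ties break toward smaller radius, then (cy, cx)
  flat <- matrix(0.5, 60, 60)
  tie <- searchMax(flat, SearchGrid(as.matrix(expand.grid(28:30, 28:30)),
                                    c(8, 6, 7), p), "modified")
  expect_equal(unname(c(center(tie), radius(tie))), c(28, 28, 6))
})

test_that("search is translation-equivariant under integer shifts", {
  p <- OperatorParams(n = 32L, deltaR = 3)
  img1 <- makeDisk(60, 60, 20)
  img2 <- makeDisk(65, 67, 20)
  g1 <- SearchGrid(as.matrix(expand.grid(56:64, 56:64)), 15:25, p)
  g2 <- SearchGrid(as.matrix(expand.grid(61:69, 63:71)), 15:25, p)
  r1 <- searchMax(img1, g1, "modified")
  r2 <- searchMax(img2, g2, "modified")
  expect_equal(unname(center(r2) - center(r1)), c(5, 7))
  expect_identical(radius(r1), radius(r2))
  expect_identical(score(r1), score(r2))
})

test_that("compensated score never exceeds the uncompensated sum", {
  set.seed(7)
  img <- matrix(runif(100 * 100), 100, 100)
  p <- OperatorParams(n = 16L)
  for (i in 1:20) {
    circ <- Circle(runif(1, 30, 70), runif(1, 30, 70), runif(1, 5, 25))
    rs <- compensation(radialGradient(img, circ, p))
    expect_true(all(rs@C[rs@valid] >= 0))
    expect_lte(score(modifiedScore(img, circ, p)),
               score(modifiedScore(img, circ, p, compensate = FALSE)) + 1e-12)
  }
})

test_that("modified objective is at least as robust as the plain gradient sum
           against bright disks on the outer boundary", {
  nScenes <- 100
  hits <- matrix(FALSE, nScenes, 2,
                 dimnames = list(NULL, c("modified", "uncompensated")))
  cfg <- irisConfig()
  for (i in seq_len(nScenes)) {
    spec <- cleanSpec(seed = 1000L + i)
    sc <- renderScene(spec)
    tr <- sc$truth
    # k = 3 bright interference disks centered on the true outer circle
    set.seed(i)
    angs <- runif(3, 0, 2 * pi)
    img <- sc$image
    for (a in angs)
      img <- paintSpot(img, tr@iris@cx + tr@iris@r * cos(a),
                       tr@iris@cy - tr@iris@r * sin(a), 3)
    inner <- ScoredCircle(tr@pupil, 0)
    for (m in colnames(hits)) {
      out <- tryCatch(locateOuter(img, inner, truthBox(tr), cfg, m),
                      error = function(e) NULL)
      if (!is.null(out))
        hits[i, m] <- circleRecovery(out@circle, tr@iris)$hit
    }
  }
  expect_gte(mean(hits[, "modified"]), mean(hits[, "uncompensated"]))
})

test_that("daugman and modified agree in the clean limit", {
  for (sd in c(21L, 22L, 23L)) {
    sc <- renderScene(cleanSpec(seed = sd))
    box <- truthBox(sc$truth)
    den <- denoise(sc$image, irisConfig(), box = box)
    grid <- boxToSearch(box, den, irisConfig())$innerGrid
    a <- searchMax(den, grid, "modified")
    b <- searchMax(den, grid, "daugman")
    expect_lte(max(abs(c(center(a) - center(b), radius(a) - radius(b)))), 1)
  }
})
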