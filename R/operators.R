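# The scoring core: Daugman's integro-differential operator and the
# compensated radial-gradient operator, as objective functions over circle
# candidates, plus the exhaustive maximizing search.
#
# Geometry: angles in degrees counter-clockwise from the +x axis, with
# +x = increasing column and the visual "up" = decreasing row, so a point at
# angle t on circle (cx, cy, r) sits at (cx + r cos t, cy - r sin t).

#' Per-angle radial samples of a circle candidate
#'
#' Holds the radial gradient \code{g} and the compensation factor \code{C}
#' of each of the \code{n} points sampled along a circle's integration path,
#' together with validity flags (points whose sample pair leaves the image
#' are invalid) and the angular neighbor structure used by the compensation.
#'
#' @slot g numeric, radial gradients per sample point.
#' @slot C numeric, compensation factors (NA until \code{\link{compensation}}
#'   is applied), non-negative.
#' @slot valid logical, sample validity.
#' @slot anglesDeg numeric, sample angles in degrees.
#' @slot prevIdx,nextIdx integer, angular neighbor indices (NA at the open
#'   end of a partial arc).
#' @export
setClass("RadialSamples",
         representation(g = "numeric", C = "numeric", valid = "logical",
                        anglesDeg = "numeric", prevIdx = "integer",
                        nextIdx = "integer"))

# Allocate n sample points over the arc set. Arcs are rows (start, end) in
# degrees; start > end wraps through 0; a zero-length row means the full
# circle. Returns angles (deg), per-point arc id, and neighbor indices
# (NA = missing neighbor at an open arc end).
.arcAngles <- function(arcs, n) {
  lens <- apply(arcs, 1L, function(a) {
    l <- (a[2] - a[1]) %% 360
    if (l == 0) 360 else l
  })
  total <- sum(lens)
  nPer <- floor(n * lens / total)
  rem <- n - sum(nPer)
  if (rem > 0) {
    frac <- n * lens / total - nPer
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    nPer[add] <- nPer[add] + 1L
  }
  angles <- numeric(0); arcId <- integer(0)
  prevIdx <- integer(0); nextIdx <- integer(0)
  off <- 0L
  fullCircle <- nrow(arcs) == 1L && lens[1] == 360
  for (i in seq_len(nrow(arcs))) {
    k <- nPer[i]
    if (k == 0L) next
    angles <- c(angles, (arcs[i, 1] + (seq_len(k) - 1L) * lens[i] / k) %% 360)
    arcId <- c(arcId, rep.int(i, k))
    p <- off + c(NA_integer_, seq_len(k - 1L))
    nx <- off + c(seq_len(k - 1L) + 1L, NA_integer_)
    if (fullCircle) { p[1L] <- off + k; nx[k] <- off + 1L }
    prevIdx <- c(prevIdx, p); nextIdx <- c(nextIdx, nx)
    off <- off + k
  }
  list(anglesDeg = angles, arcId = arcId, prevIdx = prevIdx, nextIdx = nextIdx)
}

#' Sample image intensities along a circular path
#'
#' Places \code{n} points uniformly over the arc set and reads the image by
#' bilinear interpolation at the continuous sample coordinates. Points whose
#' coordinates leave the image are flagged invalid.
#'
#' @param image grayscale matrix in [0, 1].
#' @param circle a \linkS4class{Circle}.
#' @param n number of sample points (>= 8).
#' @param arcs two-column matrix of angular intervals in degrees (see
#'   \linkS4class{OperatorParams}); default full circle.
#' @return \code{data.frame} with columns \code{theta} (1..n),
#'   \code{angleDeg}, \code{intensity} (NA when invalid), \code{valid}.
#' @export
sampleOnCircle <- function(image, circle, n = 32L, arcs = cbind(0, 360)) {
  .checkGray(image)
  stopifnot(is(circle, "Circle"))
  if (n < 8L) stop("n must be >= 8")
  aa <- .arcAngles(matrix(as.numeric(arcs), ncol = 2L), as.integer(n))
  rad <- aa$anglesDeg * pi / 180
  bi <- .bilinear(image, circle@cx + circle@r * cos(rad),
                  circle@cy - circle@r * sin(rad))
  data.frame(theta = seq_len(n), angleDeg = aa$anglesDeg,
             intensity = bi$values, valid = bi$valid)
}

#' Radial gradient of a circle candidate
#'
#' For each sample point at angle \eqn{\theta} on the candidate circle, the
#' radial gradient is the intensity difference between the point at radius
#' \eqn{r + \Delta r} and the point at radius \eqn{r} along the same ray:
#' \eqn{g_\theta = I_{\theta, r+\Delta r} - I_{\theta, r}}. With
#' \code{gradientSign = "outward_darker"} the sign is flipped. Points with
#' either end of the pair outside the image are invalid and excluded.
#'
#' @param image grayscale matrix in [0, 1].
#' @param circle a \linkS4class{Circle}.
#' @param params an \linkS4class{OperatorParams}.
#' @return a \linkS4class{RadialSamples} (slot \code{C} still NA).
#' @export
radialGradient <- function(image, circle, params = OperatorParams()) {
  .checkGray(image)
  stopifnot(is(circle, "Circle"), is(params, "OperatorParams"))
  aa <- .arcAngles(params@arcs, params@n)
  rad <- aa$anglesDeg * pi / 180
  ca <- cos(rad); sa <- sin(rad)
  b1 <- .bilinear(image, circle@cx + circle@r * ca, circle@cy - circle@r * sa)
  r2 <- circle@r + params@deltaR
  b2 <- .bilinear(image, circle@cx + r2 * ca, circle@cy - r2 * sa)
  valid <- b1$valid & b2$valid
  if (!any(valid)) stop("no valid sample points: circle outside the image")
  g <- b2$values - b1$values
  if (params@gradientSign == "outward_darker") g <- -g
  g[!valid] <- NA_real_
  rs <- new("RadialSamples")   # slot "C" would partially match new()'s Class
  rs@g <- g; rs@C <- rep(NA_real_, length(g)); rs@valid <- valid
  rs@anglesDeg <- aa$anglesDeg
  rs@prevIdx <- as.integer(aa$prevIdx); rs@nextIdx <- as.integer(aa$nextIdx)
  rs
}

#' Compensation factor for isolated gradient spikes
#'
#' The compensation factor of the \eqn{\theta}-th sample point is half the
#' sum of the absolute differences between its radial gradient and those of
#' its two angular neighbors:
#' \eqn{C_\theta = \frac{1}{2}(|g_{\theta+1} - g_\theta| +
#' |g_{\theta-1} - g_\theta|)}. A sample whose gradient differs sharply from
#' both neighbors is likely an interference point (reflection, eyelash,
#' glasses edge) and has its contribution cancelled. Neighbor indices wrap
#' cyclically on a full-circle path; at the open end of a partial arc (or
#' next to an invalid sample) the missing neighbor term is replaced by the
#' existing one; with no usable neighbor, C = 0.
#'
#' @param g a \linkS4class{RadialSamples} from \code{\link{radialGradient}},
#'   or a plain numeric vector of gradients (then treated as one full circle
#'   with cyclic wrap-around).
#' @return same type as the input: a \linkS4class{RadialSamples} with slot
#'   \code{C} filled, or the numeric vector of compensation factors.
#' @examples
#' compensation(c(2, 10, 4))[2]  # 0.5 * (|4 - 10| + |2 - 10|) = 7
#' @export
compensation <- function(g) {
  if (is.numeric(g)) {
    k <- length(g)
    if (k < 3L) stop("compensation needs at least 3 samples")
    gn <- g[c(seq_len(k - 1L) + 1L, 1L)]
    gp <- g[c(k, seq_len(k - 1L))]
    return(0.5 * (abs(gn - g) + abs(gp - g)))
  }
  stopifnot(is(g, "RadialSamples"))
  if (sum(g@valid) < 3L) stop("compensation needs at least 3 valid samples")
  gg <- g@g
  k <- length(gg)
  self <- seq_len(k)
  pi_ <- g@prevIdx; ni_ <- g@nextIdx
  pMiss <- is.na(pi_); nMiss <- is.na(ni_)
  pi_[pMiss] <- self[pMiss]; ni_[nMiss] <- self[nMiss]
  pMiss <- pMiss | !g@valid[pi_]
  nMiss <- nMiss | !g@valid[ni_]
  tp <- abs(gg[pi_] - gg); tn <- abs(gg[ni_] - gg)
  tp[is.na(tp)] <- 0; tn[is.na(tn)] <- 0
  tp2 <- ifelse(pMiss, ifelse(nMiss, 0, tn), tp)
  tn2 <- ifelse(nMiss, ifelse(pMiss, 0, tp), tn)
  C <- 0.5 * (tp2 + tn2)
  C[!g@valid] <- NA_real_
  g@C <- C
  g
}

#' Compensated radial-gradient score of a circle candidate
#'
#' The objective maximized by the boundary search:
#' \eqn{\sum_{\theta=1}^{n} (g_\theta - C_\theta)} over the valid sample
#' points, rescaled by \code{n / n_valid} so that partially out-of-bounds
#' candidates remain comparable. \code{compensate = FALSE} gives the plain
#' (uncompensated) gradient-sum objective.
#'
#' @inheritParams radialGradient
#' @param compensate logical, subtract the compensation factor.
#' @return a \linkS4class{ScoredCircle}.
#' @export
modifiedScore <- function(image, circle, params = OperatorParams(),
                          compensate = TRUE) {
  rs <- radialGradient(image, circle, params)
  contrib <- if (compensate) {
    rs <- compensation(rs)
    rs@g - rs@C
  } else rs@g
  nValid <- sum(rs@valid)
  ScoredCircle(circle, sum(contrib[rs@valid]) * params@n / nValid)
}

#' Integro-differential (Daugman) radial profile at a fixed center
#'
#' For a fixed center, computes the normalized contour mean
#' \eqn{m(r)} = mean intensity over the arc set at each candidate radius,
#' differentiates it with central differences, convolves with a 1-D Gaussian
#' of standard deviation \code{sigma} (reflect padding), and returns the
#' absolute smoothed derivative as the score of each radius.
#'
#' @param image grayscale matrix in [0, 1].
#' @param center numeric (cx, cy).
#' @param radii ascending numeric vector of candidate radii (length >= 3,
#'   uniformly spaced).
#' @param params an \linkS4class{OperatorParams}.
#' @return list of \linkS4class{ScoredCircle}, one per radius (score NA for
#'   radii whose contour leaves the image).
#' @export
daugmanScore <- function(image, center, radii, params = OperatorParams()) {
  s <- .daugmanProfile(image, center[1], center[2], radii, params,
                       minValidFrac = 0.5)
  lapply(seq_along(radii), function(i)
    ScoredCircle(Circle(center[1], center[2], radii[i]), s[i]))
}

# Numeric Daugman profile used by both daugmanScore and searchMax.
# The contour mean is evaluated on support radii padded beyond both ends of
# the candidate list, so the radial derivative is centered (not one-sided)
# and the Gaussian smoothing has full support even at the range boundaries;
# scores are reported for the requested radii only.
.daugmanProfile <- function(image, cx, cy, radii, params, minValidFrac) {
  k0 <- length(radii)
  if (k0 < 3L) stop("daugman profile needs at least 3 radii")
  if (is.unsorted(radii, strictly = TRUE)) stop("radii must be sorted ascending")
  step <- radii[2] - radii[1]
  pad <- ceiling(3 * params@sigma / step) + 1L
  lowPad <- radii[1] - step * rev(seq_len(pad))
  lowPad <- lowPad[lowPad > 0]
  keep <- length(lowPad) + seq_len(k0)
  radii <- c(lowPad, radii, radii[k0] + step * seq_len(pad))
  k <- length(radii)
  aa <- .arcAngles(params@arcs, params@n)
  rad <- aa$anglesDeg * pi / 180
  ca <- cos(rad); sa <- sin(rad)
  X <- cx + outer(radii, ca)
  Y <- cy - outer(radii, sa)
  bi <- .bilinear(image, X, Y)
  V <- matrix(bi$valid, k)
  I <- matrix(bi$values, k)
  nValid <- rowSums(V)
  m <- rowSums(I, na.rm = TRUE) / nValid
  m[nValid < minValidFrac * params@n | nValid == 0] <- NA_real_
  scores <- rep(NA_real_, k)
  ok <- !is.na(m)
  if (any(ok)) {
    # longest contiguous valid run
    runs <- rle(ok)
    ends <- cumsum(runs$lengths)
    iBest <- which(runs$values)[which.max(runs$lengths[runs$values])]
    hi <- ends[iBest]; lo <- hi - runs$lengths[iBest] + 1L
    if (hi - lo + 1L >= 3L) {
      seg <- lo:hi
      ms <- m[seg]; rs <- radii[seg]; ns <- length(seg)
      d <- numeric(ns)
      d[1] <- (ms[2] - ms[1]) / (rs[2] - rs[1])
      d[ns] <- (ms[ns] - ms[ns - 1]) / (rs[ns] - rs[ns - 1])
      if (ns > 2L)
        d[2:(ns - 1)] <- (ms[3:ns] - ms[1:(ns - 2)]) / (rs[3:ns] - rs[1:(ns - 2)])
      sm <- .convReflect(d, .gaussKernel(params@sigma / step))
      scores[seg] <- abs(sm)
    }
  }
  scores[keep]
}

# Vectorized compensated-gradient scores over all (center, radius)
# candidates at once. centers is an m x 2 matrix; returns an m x k score
# matrix (NA = rejected candidate).
.modifiedScores <- function(image, centers, radii, params, compensate,
                            minValidFrac) {
  aa <- .arcAngles(params@arcs, params@n)
  rad <- aa$anglesDeg * pi / 180
  ca <- cos(rad); sa <- sin(rad)
  m <- nrow(centers); k <- length(radii); n <- params@n
  cxv <- rep(centers[, 1], times = k)   # candidate order: center fastest
  cyv <- rep(centers[, 2], times = k)
  rv <- rep(radii, each = m)
  b1 <- .bilinear(image, cxv + rv %o% ca, cyv - rv %o% sa)
  r2 <- rv + params@deltaR
  b2 <- .bilinear(image, cxv + r2 %o% ca, cyv - r2 %o% sa)
  nc <- m * k
  V <- matrix(b1$valid & b2$valid, nc)
  g <- matrix(b2$values - b1$values, nc)
  if (params@gradientSign == "outward_darker") g <- -g
  g[!V] <- NA_real_
  if (compensate) {
    self <- seq_len(n)
    pi_ <- aa$prevIdx; ni_ <- aa$nextIdx
    pArcMiss <- is.na(pi_); nArcMiss <- is.na(ni_)
    pi_[pArcMiss] <- self[pArcMiss]; ni_[nArcMiss] <- self[nArcMiss]
    pMiss <- matrix(pArcMiss, nc, n, byrow = TRUE) | !V[, pi_, drop = FALSE]
    nMiss <- matrix(nArcMiss, nc, n, byrow = TRUE) | !V[, ni_, drop = FALSE]
    tp <- abs(g[, pi_, drop = FALSE] - g); tp[is.na(tp)] <- 0
    tn <- abs(g[, ni_, drop = FALSE] - g); tn[is.na(tn)] <- 0
    # end-clamp / invalid-neighbor rule: a missing term is replaced by the
    # existing one; with both missing, C = 0
    tp2 <- tp; tp2[pMiss] <- tn[pMiss]; tp2[pMiss & nMiss] <- 0
    tn2 <- tn; tn2[nMiss] <- tp[nMiss]; tn2[pMiss & nMiss] <- 0
    contrib <- g - 0.5 * (tp2 + tn2)
  } else contrib <- g
  nValid <- rowSums(V)
  s <- rowSums(contrib, na.rm = TRUE) * n / pmax(nValid, 1L)
  s[nValid < max(minValidFrac * n, 3L)] <- NA_real_
  matrix(s, m, k)
}

#' Exhaustive maximum search over a candidate grid
#'
#' Scores every (center, radius) pair of the grid under the selected
#' objective and returns the global maximum. Ties are broken toward the
#' smaller radius, then lexicographically by (cy, cx). Candidates with fewer
#' than \code{minValidFrac * n} valid sample points are rejected.
#'
#' @param image grayscale matrix in [0, 1].
#' @param grid a \linkS4class{SearchGrid}.
#' @param objective \code{"modified"} (compensated radial gradient),
#'   \code{"daugman"} (integro-differential) or \code{"uncompensated"}
#'   (plain gradient sum).
#' @param minValidFrac minimum valid-sample fraction per candidate.
#' @return a \linkS4class{ScoredCircle}, the argmax.
#' @export
searchMax <- function(image, grid, objective = c("modified", "daugman",
                                                 "uncompensated"),
                      minValidFrac = 0.5) {
  .checkGray(image)
  stopifnot(is(grid, "SearchGrid"))
  validObject(grid)
  objective <- match.arg(objective)
  centers <- grid@centers; radii <- grid@radii; params <- grid@params
  m <- nrow(centers); k <- length(radii)
  if (objective == "daugman") {
    scores <- matrix(NA_real_, m, k)
    for (i in seq_len(m)) {
      scores[i, ] <- tryCatch(
        .daugmanProfile(image, centers[i, 1], centers[i, 2], radii, params,
                        minValidFrac),
        error = function(e) rep(NA_real_, k))
    }
  } else {
    scores <- .modifiedScores(image, centers, radii, params,
                              compensate = objective == "modified",
                              minValidFrac)
  }
  if (all(is.na(scores))) stop("every candidate failed scoring")
  best <- max(scores, na.rm = TRUE)
  hits <- which(scores == best, arr.ind = TRUE)
  ord <- order(radii[hits[, 2]], centers[hits[, 1], 2], centers[hits[, 1], 1])
  pick <- hits[ord[1L], ]
  ScoredCircle(Circle(centers[pick[1], 1], centers[pick[1], 2],
                      radii[pick[2]]), best)
}
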