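# Evaluation: box IoU, greedy detection matching with precision/recall,
# circle-recovery errors, and the synthetic benchmark harness comparing the
# boundary objectives on identical scenes and search fields.

#' Intersection over union of two boxes
#'
#' @param a,b \linkS4class{BoundingBox} objects.
#' @return IoU in [0, 1]; 0 when disjoint.
#' @examples
#' boxIou(BoundingBox(0, 0, 2, 2), BoundingBox(1, 0, 2, 2))  # 2/6
#' @export
boxIou <- function(a, b) {
  stopifnot(is(a, "BoundingBox"), is(b, "BoundingBox"))
  ix <- min(a@x + a@w, b@x + b@w) - max(a@x, b@x)
  iy <- min(a@y + a@h, b@y + b@h) - max(a@y, b@y)
  if (ix <= 0 || iy <= 0) return(0)
  inter <- ix * iy
  inter / (a@w * a@h + b@w * b@h - inter)
}

#' Match detections against ground truth
#'
#' Greedy matching in descending score order: each prediction is assigned to
#' the unmatched ground-truth box of highest IoU, provided the IoU reaches
#' \code{iouThreshold}; a matched pair is a true positive, unmatched
#' predictions are false positives and unmatched truths false negatives.
#' Precision = TP / (TP + FP) and recall = TP / (TP + FN).
#'
#' @param pred \code{data.frame} with columns \code{x, y, w, h} and
#'   optionally \code{score} (defaults to 1).
#' @param truth \code{data.frame} with columns \code{x, y, w, h}.
#' @param iouThreshold IoU threshold for a true positive (default 0.5).
#' @return list with \code{tp}, \code{fp}, \code{fn}, \code{precision},
#'   \code{recall}, \code{iou_threshold} (precision/recall are \code{NA}
#'   when undefined).
#' @export
matchDetections <- function(pred, truth, iouThreshold = 0.5) {
  toBoxes <- function(df) lapply(seq_len(nrow(df)), function(i)
    BoundingBox(df$x[i], df$y[i], df$w[i], df$h[i]))
  pb <- toBoxes(pred); tb <- toBoxes(truth)
  scores <- if ("score" %in% names(pred)) pred$score else rep(1, length(pb))
  ord <- order(scores, decreasing = TRUE)
  matched <- logical(length(tb))
  tp <- 0L
  for (i in ord) {
    if (length(tb) == 0L) break
    ious <- vapply(tb, boxIou, numeric(1), a = pb[[i]])
    ious[matched] <- -1
    j <- which.max(ious)
    if (length(j) && ious[j] >= iouThreshold) { matched[j] <- TRUE; tp <- tp + 1L }
  }
  fp <- length(pb) - tp
  fn <- length(tb) - tp
  list(tp = tp, fp = fp, fn = fn,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       iou_threshold = iouThreshold)
}

#' Average precision over a score sweep
#'
#' All-point-interpolation AP for user-supplied detection files: predictions
#' are ranked by score across images, each is greedily matched (IoU >=
#' \code{iouThreshold}) within its image, and AP is the area under the
#' interpolated precision-recall curve.
#'
#' @param pred \code{data.frame} with columns \code{image, x, y, w, h, score}.
#' @param truth \code{data.frame} with columns \code{image, x, y, w, h}.
#' @param iouThreshold IoU threshold for a true positive.
#' @return AP in [0, 1].
#' @export
averagePrecision <- function(pred, truth, iouThreshold = 0.5) {
  nTruth <- nrow(truth)
  if (nTruth == 0L) return(NA_real_)
  if (nrow(pred) == 0L) return(0)
  ord <- order(pred$score, decreasing = TRUE)
  matchedBy <- lapply(split(seq_len(nTruth), truth$image), identity)
  matched <- logical(nTruth)
  isTP <- logical(nrow(pred))
  for (k in seq_along(ord)) {
    i <- ord[k]
    cand <- matchedBy[[as.character(pred$image[i])]]
    if (is.null(cand)) next
    pb <- BoundingBox(pred$x[i], pred$y[i], pred$w[i], pred$h[i])
    ious <- vapply(cand, function(j)
      boxIou(pb, BoundingBox(truth$x[j], truth$y[j], truth$w[j], truth$h[j])),
      numeric(1))
    ious[matched[cand]] <- -1
    j <- which.max(ious)
    if (length(j) && ious[j] >= iouThreshold) {
      matched[cand[j]] <- TRUE; isTP[k] <- TRUE
    }
  }
  cumTP <- cumsum(isTP)
  prec <- cumTP / seq_along(cumTP)
  rec <- cumTP / nTruth
  # precision envelope, then area under the all-point interpolated curve
  penv <- rev(cummax(rev(prec)))
  sum(diff(c(0, rec)) * penv)
}

#' Circle-recovery error
#'
#' Euclidean center error and absolute radius error of a predicted circle
#' against truth; \code{hit} is true when both errors are within their
#' (inclusive) tolerances.
#'
#' @param pred,truth \linkS4class{Circle} objects.
#' @param tolCenter,tolRadius tolerances in pixels (defaults 2, 2).
#' @return list with \code{center_error}, \code{radius_error}, \code{hit}.
#' @export
circleRecovery <- function(pred, truth, tolCenter = 2, tolRadius = 2) {
  stopifnot(is(pred, "Circle"), is(truth, "Circle"))
  ce <- sqrt((pred@cx - truth@cx)^2 + (pred@cy - truth@cy)^2)
  re <- abs(pred@r - truth@r)
  list(center_error = ce, radius_error = re,
       hit = is.finite(ce) && is.finite(re) && ce <= tolCenter && re <= tolRadius)
}

#' Benchmark boundary objectives on synthetic scenes
#'
#' Generates seeded scene batches per noise stratum, denoises each scene
#' once, and runs every requested objective on the identical denoised image
#' and identical inner search grid (the outer grid follows each method's own
#' inner result, per the two-stage design). Per-method recovery rates and
#' mean errors are tabulated per stratum; failures are recorded per scene,
#' never aborting the batch.
#'
#' @param nScenes scenes per stratum (>= 1).
#' @param seed integer seed; scene content is reproducible from
#'   \code{(nScenes, strata, seed)}.
#' @param methods subset of \code{c("modified", "daugman", "uncompensated")}.
#' @param strata noise strata, see \code{\link{sceneParamRanges}}.
#' @param config configuration list from \code{\link{irisConfig}}.
#' @param tolCenter,tolRadius recovery tolerances in pixels.
#' @param outDir optional directory for \code{report.csv},
#'   \code{per_scene.csv} and \code{report.md}.
#' @return list with \code{report} (per method x stratum summary
#'   \code{data.frame}) and \code{perScene} (per-scene records including the
#'   selected circles).
#' @export
runBenchmark <- function(nScenes, seed = 1L,
                         methods = c("modified", "daugman", "uncompensated"),
                         strata = "combined", config = irisConfig(),
                         tolCenter = 2, tolRadius = 2, outDir = NULL) {
  if (nScenes < 1) stop("nScenes must be >= 1")
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list()
  for (si in seq_along(strata)) {
    stratum <- strata[si]
    scenes <- generateBatch(nScenes, sceneParamRanges(stratum),
                            seed = as.integer(seed) + 7919L * (si - 1L))
    for (sc in seq_along(scenes)) {
      img <- scenes[[sc]]$image; tr <- scenes[[sc]]$truth
      box <- tr@bbox
      den <- denoise(img, config, box = box)
      bs <- boxToSearch(box, den, config)
      for (m in methods) {
        inner <- tryCatch(
          searchMax(den, bs$innerGrid, m, config$operators$min_valid_frac),
          error = function(e) NULL)
        outer <- if (!is.null(inner)) tryCatch(
          locateOuter(den, inner, box, config, m),
          error = function(e) NULL) else NULL
        recI <- if (!is.null(inner))
          circleRecovery(inner@circle, tr@pupil, tolCenter, tolRadius)
        else list(center_error = NA_real_, radius_error = NA_real_, hit = FALSE)
        recO <- if (!is.null(outer))
          circleRecovery(outer@circle, tr@iris, tolCenter, tolRadius)
        else list(center_error = NA_real_, radius_error = NA_real_, hit = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          stratum = stratum, scene = sc, method = m,
          status = if (is.null(inner)) "inner_failed"
                   else if (is.null(outer)) "outer_failed" else "ok",
          inner_cx = if (is.null(inner)) NA_real_ else inner@circle@cx,
          inner_cy = if (is.null(inner)) NA_real_ else inner@circle@cy,
          inner_r = if (is.null(inner)) NA_real_ else inner@circle@r,
          outer_cx = if (is.null(outer)) NA_real_ else outer@circle@cx,
          outer_cy = if (is.null(outer)) NA_real_ else outer@circle@cy,
          outer_r = if (is.null(outer)) NA_real_ else outer@circle@r,
          inner_center_err = recI$center_error,
          inner_radius_err = recI$radius_error, inner_hit = recI$hit,
          outer_center_err = recO$center_error,
          outer_radius_err = recO$radius_error, outer_hit = recO$hit,
          stringsAsFactors = FALSE)
      }
    }
  }
  perScene <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(perScene,
                                     list(perScene$method, perScene$stratum),
                                     drop = TRUE), function(d)
    data.frame(method = d$method[1], stratum = d$stratum[1], n = nrow(d),
               inner_hit_rate = mean(d$inner_hit),
               outer_hit_rate = mean(d$outer_hit),
               both_hit_rate = mean(d$inner_hit & d$outer_hit),
               mean_center_err = mean(d$outer_center_err, na.rm = TRUE),
               mean_radius_err = mean(d$outer_radius_err, na.rm = TRUE),
               stringsAsFactors = FALSE)))
  agg <- agg[order(agg$stratum, agg$method), ]
  rownames(agg) <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(agg, file.path(outDir, "report.csv"), row.names = FALSE)
    utils::write.csv(perScene, file.path(outDir, "per_scene.csv"),
                     row.names = FALSE)
    md <- c("# Boundary-recovery benchmark", "",
            sprintf("Scenes per stratum: %d; seed: %d; tolerances: %g px center, %g px radius.",
                    nScenes, as.integer(seed), tolCenter, tolRadius), "",
            "| method | stratum | n | inner hit | outer hit | both | mean center err | mean radius err |",
            "|---|---|---|---|---|---|---|---|",
            sprintf("| %s | %s | %d | %.3f | %.3f | %.3f | %.2f | %.2f |",
                    agg$method, agg$stratum, agg$n, agg$inner_hit_rate,
                    agg$outer_hit_rate, agg$both_hit_rate,
                    agg$mean_center_err, agg$mean_radius_err))
    writeLines(md, file.path(outDir, "report.md"))
  }
  list(report = agg, perScene = perScene)
}
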