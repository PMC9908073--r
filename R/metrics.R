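# Evaluation statistics: distance error and hit rate on the circularized
# track, spatial tuning curves and similarity scores, motion-artifact
# scores, and event-classification metrics with shuffle nulls.

#' Signed log-significance transform
#'
#' `-log10(P) * sign(R)`; the p < 0.01 significance boundary maps to a
#' score of 2.
#'
#' @param P p-value.
#' @param R correlation (its sign is used).
#' @return signed score.
#' @export
signedLogP <- function(P, R) -log10(P) * sign(R)

#' Loop centers of the circularized position bins
#'
#' Bin b (1..K) is centered at `(b - 1/2) * 2L/K` on the loop of length 2L
#' formed by the two running directions of an L-cm track.
#'
#' @param K bin count.
#' @param trackLength_cm track length L.
#' @return numeric vector of loop positions (cm).
#' @export
binCentersLoop <- function(K = 24L, trackLength_cm = 250) {
  (seq_len(K) - 0.5) * (2 * trackLength_cm / K)
}

# circular distance between loop positions on a loop of given length
.circDist <- function(a, b, loop) {
  d <- abs(a - b) %% loop
  pmin(d, loop - d)
}

#' Position decoding error metrics
#'
#' Distance error lambda(t) is the circular distance (cm) along the
#' circularized 2L loop between the centers of the true and decoded bins;
#' the hit rate rho is the percentage of frames with lambda within the
#' tolerance (default +/- 30 cm).
#'
#' @param trueBins,predictedBins integer bin series (equal length).
#' @param K bin count.
#' @param trackLength_cm track length L.
#' @param tolerance_cm hit tolerance (default 30).
#' @return list(lambda, lambdaBar, rho).
#' @export
positionMetrics <- function(trueBins, predictedBins, K = 24L,
                            trackLength_cm = 250, tolerance_cm = 30) {
  stopifnot(length(trueBins) == length(predictedBins))
  ctr <- binCentersLoop(K, trackLength_cm)
  lambda <- .circDist(ctr[trueBins], ctr[predictedBins], 2 * trackLength_cm)
  list(lambda = lambda, lambdaBar = mean(lambda),
       rho = 100 * mean(lambda <= tolerance_cm))
}

#' Spatial tuning curve of a trace
#'
#' The trace is zero-referenced by subtracting its minimum
#' (`Z(f) = T(f) - min(T)`), averaged within each position bin over the
#' frames visiting it (`A(b) = sum_i Z(f_i) / B_b`), and normalized by the
#' maximum bin value. Bins never visited are flagged and set to NA; a
#' curve with zero maximum is flagged and left all-zero.
#'
#' @param trace numeric trace T(f).
#' @param bins per-frame bin series.
#' @param K bin count.
#' @return list(curve = normalized, A = raw bin means, visits, flagged).
#' @export
tuningCurve <- function(trace, bins, K = 24L) {
  stopifnot(length(trace) == length(bins))
  Z <- trace - min(trace)
  visits <- tabulate(bins, nbins = K)
  A <- rep(NA_real_, K)
  for (b in which(visits > 0)) A[b] <- mean(Z[bins == b])
  mx <- max(A, na.rm = TRUE)
  flagged <- any(visits == 0) || !is.finite(mx) || mx == 0
  curve <- if (is.finite(mx) && mx > 0) A / mx else ifelse(is.na(A), NA, 0)
  list(curve = curve, A = A, visits = visits, flagged = flagged)
}

#' Tuning-curve similarity score
#'
#' Pearson correlation R and p-value P between two tuning curves (training
#' vs testing epoch), summarized as `S = -log10(P) * sign(R)`; S > 2
#' corresponds to p < 0.01 with a positive correlation. Degenerate
#' (zero-variance or too-short) curves return NA.
#'
#' @param curveTrain,curveTest numeric vectors over the same bins.
#' @return list(S, R, P); S is NA when undefined.
#' @export
similarityScore <- function(curveTrain, curveTest) {
  stopifnot(length(curveTrain) == length(curveTest))
  ok <- is.finite(curveTrain) & is.finite(curveTest)
  if (sum(ok) < 3L)
    return(list(S = NA_real_, R = NA_real_, P = NA_real_))
  a <- curveTrain[ok]; b <- curveTest[ok]
  if (sd(a) == 0 || sd(b) == 0)
    return(list(S = NA_real_, R = NA_real_, P = NA_real_))
  ct <- cor.test(a, b, method = "pearson")
  list(S = signedLogP(ct$p.value, ct$estimate),
       R = unname(ct$estimate), P = ct$p.value)
}

#' Motion-artifact score
#'
#' Restricts analysis to frames from position bins in which the maximum
#' image displacement d exceeds the pixel threshold (default 4), then
#' correlates the per-frame distance error lambda with d over those frames;
#' the score is `-log10(P) * sign(R)`. Returns NA when no bin qualifies or
#' the restricted series are degenerate.
#'
#' @param lambda per-frame distance error (cm).
#' @param d per-frame image displacement (pixels).
#' @param bins per-frame position bins.
#' @param pixelThreshold bin-selection threshold on max d (default 4).
#' @return list(Omega, R, P, framesUsed, binsUsed).
#' @export
motionArtifactScore <- function(lambda, d, bins, pixelThreshold = 4) {
  stopifnot(length(lambda) == length(d), length(d) == length(bins))
  qualifying <- integer(0)
  for (b in sort(unique(bins)))
    if (max(d[bins == b]) > pixelThreshold) qualifying <- c(qualifying, b)
  sel <- bins %in% qualifying
  if (!length(qualifying) || sum(sel) < 3L ||
      sd(lambda[sel]) == 0 || sd(d[sel]) == 0)
    return(list(Omega = NA_real_, R = NA_real_, P = NA_real_,
                framesUsed = sum(sel), binsUsed = qualifying))
  ct <- cor.test(lambda[sel], d[sel], method = "pearson")
  list(Omega = signedLogP(ct$p.value, ct$estimate),
       R = unname(ct$estimate), P = ct$p.value,
       framesUsed = sum(sel), binsUsed = qualifying)
}

# maximal runs of a given label: data.frame(start, end)
.labelRuns <- function(labels, type) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == type
  data.frame(start = starts[keep], end = ends[keep])
}

.eventScores <- function(trueLabels, predictedLabels, type) {
  ev <- .labelRuns(trueLabels, type)
  if (nrow(ev) == 0L)
    return(list(sensitivity = NA_real_, precision = NA_real_, F = NA_real_,
                nEvents = 0L))
  hit <- vapply(seq_len(nrow(ev)), function(i)
    any(predictedLabels[ev$start[i]:ev$end[i]] == type), logical(1))
  S <- 100 * mean(hit)
  pe <- .labelRuns(predictedLabels, type)
  if (nrow(pe) == 0L) {
    P <- if (S == 0) NA_real_ else 0
  } else {
    inTrue <- vapply(seq_len(nrow(pe)), function(i)
      any(trueLabels[pe$start[i]:pe$end[i]] == type), logical(1))
    P <- 100 * mean(inTrue)
  }
  Fv <- if (is.na(P) || (P + S) == 0) 0 else 2 * P * S / (P + S)
  list(sensitivity = S, precision = P, F = Fv, nEvents = nrow(ev))
}

#' Event classification metrics with a shuffle null
#'
#' An event (a maximal run of frames carrying the event label in the true
#' series) counts as correctly predicted when at least one frame inside its
#' window carries the predicted event label; sensitivity is the percentage
#' of events so predicted. Precision is the percentage of predicted event
#' episodes that overlap a true event window, and `F = 2PS/(P + S)`. The
#' null distribution permutes the labels of the true series' windows among
#' windows (window positions fixed) and recomputes F against the same
#' predictions.
#'
#' @param trueLabels,predictedLabels aligned per-frame label series.
#' @param type the event category scored.
#' @param nShuffles shuffle count for the null (default 1000).
#' @param seed RNG seed for the shuffles.
#' @return list(sensitivity, precision, F, nullF, pValue,
#'   frameSensitivity, framePrecision). Metrics are NA when the true
#'   series contains no event of the type.
#' @export
eventMetrics <- function(trueLabels, predictedLabels, type,
                         nShuffles = 1000L, seed = 1L) {
  stopifnot(length(trueLabels) == length(predictedLabels))
  actual <- .eventScores(trueLabels, predictedLabels, type)
  if (actual$nEvents == 0L)
    return(list(sensitivity = NA_real_, precision = NA_real_, F = NA_real_,
                nullF = numeric(0), pValue = NA_real_,
                frameSensitivity = NA_real_, framePrecision = NA_real_))
  # frame-level counterparts, reported for transparency
  tp <- sum(trueLabels == type & predictedLabels == type)
  frameSens <- 100 * tp / sum(trueLabels == type)
  framePrec <- if (sum(predictedLabels == type) == 0) NA_real_
               else 100 * tp / sum(predictedLabels == type)
  # shuffle null: permute window labels among windows
  r <- rle(trueLabels)
  set.seed(seed)
  nullF <- vapply(seq_len(nShuffles), function(i) {
    rs <- r
    rs$values <- sample(r$values)
    .eventScores(inverse.rle(rs), predictedLabels, type)$F
  }, numeric(1))
  pValue <- (1 + sum(nullF >= actual$F)) / (nShuffles + 1)
  list(sensitivity = actual$sensitivity, precision = actual$precision,
       F = actual$F, nullF = nullF, pValue = pValue,
       frameSensitivity = frameSens, framePrecision = framePrec)
}
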