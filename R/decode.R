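# Stage 4: Gray-code (ECOC) linear population decoding of position and a
# binary-tree classifier for behavior, with causal majority smoothing, the
# motion-only control predictor, and the circular-shift control.

#' Construct the cyclic half-window Gray code
#'
#' Row m (0-based) is +1 for categories b (0-based) with
#' `((b - m) mod K) < K/2` and -1 otherwise. The resulting M = K/2 rows form
#' a cyclic code in which adjacent category columns differ in exactly one
#' row and all columns are distinct.
#'
#' @param K number of categories (even, >= 2).
#' @return a \linkS4class{GrayCode}.
#' @export
makeGrayCode <- function(K) {
  if (K %% 2L != 0L || K < 2L) stop("K must be even and >= 2")
  M <- K %/% 2L
  code <- matrix(-1L, M, K)
  for (m in seq_len(M) - 1L)
    for (b in seq_len(K) - 1L)
      if (((b - m) %% K) < M) code[m + 1L, b + 1L] <- 1L
  new("GrayCode", code = code, K = as.integer(K), M = as.integer(M))
}

# ---------------------------------------------------------------------------
# binary linear units (L2-regularized linear SVM, hinge loss)
# ---------------------------------------------------------------------------

# standardize a design matrix, dropping zero-variance columns
.scaleDesign <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  keep <- which(is.finite(scl) & scl > 0)
  list(center = ctr, scale = scl, keep = keep)
}

.applyScale <- function(X, scaling) {
  Xs <- X[, scaling$keep, drop = FALSE]
  sweep(sweep(Xs, 2, scaling$center[scaling$keep]), 2,
        scaling$scale[scaling$keep], "/")
}

# fit one hinge-loss linear unit on standardized inputs against -1/+1
# targets; the margin sign is oriented so positive scores mean y = +1
.fitLinearUnit <- function(Xs, y, cost = 1) {
  stopifnot(all(y %in% c(-1, 1)))
  if (length(unique(y)) < 2L)
    return(list(constant = TRUE, value = y[1]))
  fit <- e1071::svm(Xs, factor(y, levels = c(-1, 1)), kernel = "linear",
                    cost = cost, scale = FALSE)
  w <- crossprod(fit$SV, fit$coefs)[, 1]
  b <- -fit$rho
  s <- drop(Xs %*% w) + b
  agree <- suppressWarnings(cor(s, y))
  flip <- if (is.finite(agree) && agree < 0) -1 else 1
  list(constant = FALSE, w = flip * w, b = flip * b)
}

.unitScores <- function(unit, Xs) {
  if (isTRUE(unit$constant)) rep(unit$value * 1e6, nrow(Xs))
  else drop(Xs %*% unit$w) + unit$b
}

# ---------------------------------------------------------------------------
# position decoder
# ---------------------------------------------------------------------------

#' Train the Gray-code position decoder
#'
#' Fits one binary linear classifier per code row to targets
#' `code[row, bin(f)]` over the training frames; all traces are used as
#' inputs (no spatial-selectivity preselection).
#'
#' @param traces a \linkS4class{CalciumTraces} or an N x frames matrix.
#' @param bins integer per-frame position bins in 1..K.
#' @param code a \linkS4class{GrayCode} (default: 24 bins).
#' @param trainingRange integer frame indices used for training.
#' @param cost SVM cost parameter (fixed regularization).
#' @return a \linkS4class{PositionDecoder}.
#' @export
trainPositionDecoder <- function(traces, bins, code = makeGrayCode(24L),
                                 trainingRange, cost = 1) {
  X <- if (is(traces, "CalciumTraces")) t(decodingInput(traces)) else t(traces)
  stopifnot(length(bins) == nrow(X))
  trBins <- bins[trainingRange]
  missing <- setdiff(seq_len(code@K), unique(trBins))
  if (length(missing))
    stop("training epoch never visits bin(s): ",
         paste(missing, collapse = ", "))
  Xtr <- X[trainingRange, , drop = FALSE]
  scaling <- .scaleDesign(Xtr)
  Xs <- .applyScale(Xtr, scaling)
  units <- lapply(seq_len(code@M), function(m)
    .fitLinearUnit(Xs, code@code[m, trBins], cost = cost))
  new("PositionDecoder", units = units, code = code, scaling = scaling,
      nInputs = ncol(X))
}

#' Decode position bins from trace vectors
#'
#' Computes the real-valued output of every classifier unit and returns,
#' per frame, the bin whose Gray codeword has the largest inner product
#' with the output vector (nearest codeword by margin); ties resolve to the
#' lowest bin index.
#'
#' @param model a \linkS4class{PositionDecoder}.
#' @param traces a \linkS4class{CalciumTraces}, an N x frames matrix, or a
#'   single trace vector of length N.
#' @return integer vector of decoded bins.
#' @export
predictPosition <- function(model, traces) {
  X <- if (is(traces, "CalciumTraces")) t(decodingInput(traces))
       else if (is.matrix(traces)) t(traces)
       else matrix(traces, nrow = 1)
  stopifnot(ncol(X) == model@nInputs)
  Xs <- .applyScale(X, model@scaling)
  S <- vapply(model@units, .unitScores, numeric(nrow(Xs)), Xs = Xs)
  if (nrow(Xs) == 1L) S <- matrix(S, nrow = 1)
  sims <- S %*% model@code@code
  as.integer(max.col(sims, ties.method = "first"))
}

#' Decode a bin from precomputed unit outputs
#'
#' Nearest-codeword matching on an explicit output vector: the decoded bin
#' maximizes the inner product with the codeword; ties resolve to the
#' lowest bin.
#'
#' @param outputs numeric vector of M unit outputs.
#' @param code a \linkS4class{GrayCode}.
#' @return integer bin index.
#' @export
nearestCodeword <- function(outputs, code) {
  sims <- drop(outputs %*% code@code)
  as.integer(which.max(sims))
}

#' Circular-shift control for position decoding
#'
#' For each shift, the trace matrix is circularly rotated against the bin
#' series before training (misaligned pairs); the trained decoder is then
#' tested on correctly aligned test-epoch data. Accuracy is averaged over
#' all shift values.
#'
#' @param traces a \linkS4class{CalciumTraces} or N x frames matrix.
#' @param bins per-frame bins.
#' @param code a \linkS4class{GrayCode}.
#' @param trainingRange,testRange frame index vectors.
#' @param shifts circular shifts in frames (default 500..2500 by 500).
#' @param trackLength_cm,tolerance_cm geometry for the error metrics.
#' @param cost SVM cost.
#' @return list(perShift data.frame, lambdaBar, rho) -- the mean distance
#'   error (cm) and hit rate (%) averaged over shifts.
#' @export
shiftControl <- function(traces, bins, code = makeGrayCode(24L),
                         trainingRange, testRange,
                         shifts = c(500L, 1000L, 1500L, 2000L, 2500L),
                         trackLength_cm = 250, tolerance_cm = 30, cost = 1) {
  X <- if (is(traces, "CalciumTraces")) decodingInput(traces) else traces
  n <- ncol(X)
  if (n <= max(shifts))
    stop("session (", n, " frames) must be longer than the maximum shift (",
         max(shifts), ")")
  res <- data.frame(shift = shifts, lambdaBar = NA_real_, rho = NA_real_)
  for (i in seq_along(shifts)) {
    s <- shifts[i]
    binsShifted <- bins[((seq_len(n) - 1L + s) %% n) + 1L]
    model <- trainPositionDecoder(X, binsShifted, code, trainingRange, cost)
    pred <- predictPosition(model, X[, testRange, drop = FALSE])
    pm <- positionMetrics(bins[testRange], pred, K = code@K,
                          trackLength_cm = trackLength_cm,
                          tolerance_cm = tolerance_cm)
    res$lambdaBar[i] <- pm$lambdaBar
    res$rho[i] <- pm$rho
  }
  list(perShift = res, lambdaBar = mean(res$lambdaBar), rho = mean(res$rho))
}

# ---------------------------------------------------------------------------
# behavior tree
# ---------------------------------------------------------------------------

.defaultTreeTopology <- function() {
  # most-frequent-category-first splits; each node peels one category off
  list(c("intertrial"), c("pre-trial"), c("reward retrieval"),
       c("correct choice"))
}

#' Train the binary-tree behavior classifier
#'
#' Ordered nodes each fit a binary linear classifier separating one
#' category from the remaining set: intertrial vs the event categories,
#' then pre-trial, then reward retrieval, then correct vs incorrect choice.
#' Nodes whose category is absent from the training labels are degenerate
#' (never selected) and flagged with a warning.
#'
#' @param predictors frames x p matrix (calcium trace vectors or motion
#'   features), or a \linkS4class{CalciumTraces}.
#' @param labels per-frame category labels.
#' @param trainingRange frame indices used for training.
#' @param topology ordered list of categories split off at each node.
#' @param smoothingWindow causal majority window (frames, default 5).
#' @param cost SVM cost.
#' @return a \linkS4class{BehaviorTree}.
#' @export
trainBehaviorTree <- function(predictors, labels, trainingRange,
                              topology = .defaultTreeTopology(),
                              smoothingWindow = 5L, cost = 1) {
  X <- if (is(predictors, "CalciumTraces")) t(decodingInput(predictors))
       else predictors
  stopifnot(nrow(X) == length(labels))
  cats <- behaviorCategories()
  trLab <- labels[trainingRange]
  if (length(unique(trLab)) < 2L)
    stop("at least two behavior categories must be present in training")
  absent <- setdiff(cats, unique(trLab))
  if (length(absent))
    warning("categories absent from training (leaves unreachable): ",
            paste(absent, collapse = ", "))
  Xtr <- X[trainingRange, , drop = FALSE]
  scaling <- .scaleDesign(Xtr)
  Xs <- .applyScale(Xtr, scaling)
  remaining <- cats
  nodes <- list()
  for (split in topology) {
    rest <- setdiff(remaining, split)
    inNode <- trLab %in% remaining
    y <- ifelse(trLab[inNode] %in% split, 1, -1)
    unit <- if (length(y) == 0L) list(constant = TRUE, value = -1)
            else if (length(unique(y)) < 2L)
              list(constant = TRUE, value = y[1])
            else .fitLinearUnit(Xs[inNode, , drop = FALSE], y, cost)
    nodes[[length(nodes) + 1L]] <- list(positive = split, rest = rest,
                                        unit = unit)
    remaining <- rest
  }
  new("BehaviorTree", nodes = nodes, categories = cats, scaling = scaling,
      smoothingWindow = as.integer(smoothingWindow))
}

#' Predict behavior labels (raw and majority-smoothed)
#'
#' Each frame descends the tree to a leaf; the reported label is then the
#' causal mode over a trailing window of `smoothingWindow` frames (the
#' current and previous frames; shorter at the start of the series). Ties
#' resolve to the most recent raw label among the tied categories.
#'
#' @param tree a \linkS4class{BehaviorTree}.
#' @param predictors frames x p matrix or \linkS4class{CalciumTraces}.
#' @return list(raw, smoothed) character label series.
#' @export
predictBehavior <- function(tree, predictors) {
  X <- if (is(predictors, "CalciumTraces")) t(decodingInput(predictors))
       else predictors
  Xs <- .applyScale(X, tree@scaling)
  n <- nrow(Xs)
  raw <- rep(tail(tree@categories, 1L), n)
  undecided <- rep(TRUE, n)
  for (nd in tree@nodes) {
    if (!any(undecided)) break
    s <- .unitScores(nd$unit, Xs[undecided, , drop = FALSE])
    hit <- s > 0
    idx <- which(undecided)
    raw[idx[hit]] <- nd$positive[1]
    undecided[idx[hit]] <- FALSE
    if (length(nd$rest) == 1L) {
      raw[idx[!hit]] <- nd$rest
      undecided[idx[!hit]] <- FALSE
    }
  }
  list(raw = raw, smoothed = smoothLabels(raw, tree@smoothingWindow))
}

#' Causal majority smoothing of a label series
#'
#' The smoothed label at frame f is the most frequent raw label within the
#' trailing window of `window` frames ending at f (shortened at the start
#' of the series). Ties resolve to the most recent raw label among the
#' tied categories.
#'
#' @param labels character label series.
#' @param window window length in frames (default 5).
#' @return smoothed character series of the same length.
#' @export
smoothLabels <- function(labels, window = 5L) {
  n <- length(labels)
  out <- character(n)
  for (f in seq_len(n)) {
    w <- labels[max(1L, f - window + 1L):f]
    tab <- table(w)
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1L) out[f] <- top
    else out[f] <- w[max(which(w %in% top))]  # most recent among tied
  }
  out
}
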