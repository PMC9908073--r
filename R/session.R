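# Orchestration: the virtual-sensor streaming loop. Frames are processed
# strictly in order and causally -- reference from the first frames, per-frame
# displacement estimation, correction, enhancement, trace extraction -- then
# the decoder is trained on the training split and predictions plus TTL
# output are emitted for the test split.

#' Session configuration
#'
#' @param fps frame rate.
#' @param frameDim working-frame dimensions c(height, width).
#' @param maskMode "contour-free" (tile mosaic) or "contour-based".
#' @param tile tile side for contour-free masks.
#' @param stabilization from [stabilizationConfig()].
#' @param enhance from [enhanceConfig()].
#' @param motionCorrection apply Stage-1 correction (TRUE) or bypass it.
#' @param trainingFraction fraction of frames used for decoder training
#'   (position decoding; default first half).
#' @param K position bin count.
#' @param trackLength_cm track length (cm).
#' @param tolerance_cm hit-rate tolerance (cm).
#' @param cost linear classifier cost.
#' @param dropFilter list(G, q, smallMaskLimit) for contour traces.
#' @param ttlRules list of TTL rules, each `list(line =, bins =)` (position
#'   mode) or `list(line =, labels =)` (behavior mode); 8 output lines.
#' @param seed integer seed.
#' @return validated config list.
#' @export
sessionConfig <- function(fps = 20, frameDim = c(512L, 512L),
                          maskMode = c("contour-free", "contour-based"),
                          tile = 16L,
                          stabilization = stabilizationConfig(
                            frameDim = frameDim),
                          enhance = enhanceConfig(),
                          motionCorrection = TRUE,
                          trainingFraction = 0.5, K = 24L,
                          trackLength_cm = 250, tolerance_cm = 30,
                          cost = 1,
                          dropFilter = list(G = 255, q = 0.9,
                                            smallMaskLimit = 50L),
                          ttlRules = list(), seed = 1L) {
  maskMode <- match.arg(maskMode)
  if (fps <= 0) stop("fps must be positive")
  if (trainingFraction <= 0 || trainingFraction >= 1)
    stop("trainingFraction must lie strictly between 0 and 1")
  list(fps = fps, frameDim = as.integer(frameDim), maskMode = maskMode,
       tile = as.integer(tile), stabilization = stabilization,
       enhance = enhance, motionCorrection = isTRUE(motionCorrection),
       trainingFraction = trainingFraction, K = as.integer(K),
       trackLength_cm = trackLength_cm, tolerance_cm = tolerance_cm,
       cost = cost, dropFilter = dropFilter, ttlRules = ttlRules,
       seed = as.integer(seed))
}

#' Process one frame through Stages 1-3
#'
#' Pure per-frame step: displacement estimation against the fixed
#' reference, rigid correction, enhancement, and mask summation. Uses only
#' the current frame and the fixed template, so streaming a stack frame by
#' frame is bit-identical to batch processing.
#'
#' @param frame raw working frame.
#' @param config from [sessionConfig()].
#' @param reference from [buildReference()].
#' @param masks a \linkS4class{PixelMaskSet}.
#' @return list(dx, dy, lowConfidence, traces).
#' @export
processFrame <- function(frame, config, reference, masks) {
  if (config$motionCorrection) {
    d <- estimateDisplacement(frame, reference, config$stabilization)
    if (d$dx != 0L || d$dy != 0L) frame <- applyCorrection(frame, d)
  } else {
    d <- list(dx = 0L, dy = 0L, lowConfidence = FALSE)
  }
  enhanced <- enhanceFrame(frame, config$enhance)
  list(dx = d$dx, dy = d$dy, lowConfidence = d$lowConfidence,
       traces = extractTraces(enhanced, masks))
}

# Stage 1-3 over a stack via the per-frame step
.processStack <- function(frames, config, reference, masks) {
  n <- dim(frames)[3]
  nm <- maskCount(masks)
  raw <- matrix(0, nm, n)
  dx <- integer(n); dy <- integer(n); lc <- logical(n)
  for (f in seq_len(n)) {
    st <- processFrame(frames[, , f], config, reference, masks)
    raw[, f] <- st$traces
    dx[f] <- st$dx; dy[f] <- st$dy; lc[f] <- st$lowConfidence
  }
  list(raw = raw,
       displacement = data.frame(dx = dx, dy = dy, lowConfidence = lc))
}

#' TTL output pattern from predictions
#'
#' @param predictions decoded bin indices or behavior labels.
#' @param rules list of rules `list(line =, bins =)` or
#'   `list(line =, labels =)`; lines are 0-based (0..7).
#' @param nLines number of TTL lines (default 8).
#' @return integer matrix frames x nLines of 0/1 pulses.
#' @export
applyTTLRules <- function(predictions, rules, nLines = 8L) {
  out <- matrix(0L, length(predictions), nLines,
                dimnames = list(NULL, paste0("line", seq_len(nLines) - 1L)))
  for (rule in rules) {
    targets <- if (!is.null(rule$bins)) rule$bins else rule$labels
    out[predictions %in% targets, rule$line + 1L] <- 1L
  }
  out
}

#' Stream a session end to end
#'
#' Runs the full causal pipeline on a frame stack: the reference template
#' is built from the first `nReferenceFrames` frames, every frame is
#' motion-corrected, enhanced and summed into traces, the decoder is
#' trained on the training split, and predictions plus TTL output are
#' emitted for the test split. Streaming the same stack twice with the
#' same config yields bit-identical traces and predictions.
#'
#' @param input a \linkS4class{MiniscopeSession}, a frame array, or a
#'   multi-page TIFF path.
#' @param config from [sessionConfig()].
#' @param bins optional per-frame position bins (taken from the session's
#'   trajectory when absent); enables position decoding.
#' @param labels optional per-frame behavior labels (taken from the
#'   session when absent); enables behavior decoding when no bins exist.
#' @param masks optional \linkS4class{PixelMaskSet}; by default tile masks
#'   (contour-free mode) or ground-truth-derived contour masks
#'   (contour-based mode on a synthetic session).
#' @param labelImage optional label image for contour-based masks.
#' @param outputDir optional directory; when given, traces, displacements,
#'   predictions, the TTL log, metrics and the config echo are written.
#' @return list(traces, displacement, model, predictions, ttl, metrics,
#'   trainingRange, testRange).
#' @export
streamSession <- function(input, config = sessionConfig(), bins = NULL,
                          labels = NULL, masks = NULL, labelImage = NULL,
                          outputDir = NULL) {
  session <- NULL
  if (is(input, "MiniscopeSession")) {
    session <- input
    frames <- sessionFrames(session)
    if (is.null(bins) && nrow(trajectory(session)))
      bins <- trajectory(session)$bin
    if (is.null(labels) && length(behaviorLabels(session)))
      labels <- behaviorLabels(session)
  } else if (is.character(input)) {
    frames <- readFrameStack(input)
  } else {
    frames <- input
  }
  d <- dim(frames)
  if (length(d) != 3L)
    stop("input must provide a height x width x frames stack")
  if (!all(d[1:2] == config$frameDim))
    stop("frame dimensions ", d[1], " x ", d[2],
         " do not match the configured working frame")
  n <- d[3]

  if (is.null(masks)) {
    if (config$maskMode == "contour-free") {
      if (d[1] != d[2]) stop("tile masks require a square working frame")
      masks <- makeTileMasks(d[1], config$tile)
    } else if (!is.null(labelImage)) {
      masks <- makeContourMasks(labelImage)
    } else if (!is.null(session) && length(session@cells)) {
      masks <- masksFromFootprints(session@cells, d[1:2])
    } else {
      stop("contour-based mode needs a label image or mask set")
    }
  }

  reference <- buildReference(frames, config$stabilization)
  st <- .processStack(frames, config, reference, masks)
  traces <- CalciumTraces(st$raw, maskSizes = maskSizes(masks),
                          kind = vapply(masks@masks, function(m) m$kind,
                                        character(1)))
  if (any(rowData(traces)$kind == "contour"))
    traces <- dropFilterTraces(traces, config$dropFilter$G,
                               config$dropFilter$q,
                               config$dropFilter$smallMaskLimit)

  nTrain <- floor(n * config$trainingFraction)
  trainingRange <- seq_len(nTrain)
  testRange <- (nTrain + 1L):n

  model <- NULL; predictions <- NULL; ttl <- NULL; metrics <- list()
  X <- decodingInput(traces)
  if (!is.null(bins)) {
    code <- makeGrayCode(config$K)
    model <- trainPositionDecoder(X, bins, code, trainingRange,
                                  cost = config$cost)
    predictions <- predictPosition(model, X[, testRange, drop = FALSE])
    pm <- positionMetrics(bins[testRange], predictions, K = config$K,
                          trackLength_cm = config$trackLength_cm,
                          tolerance_cm = config$tolerance_cm)
    metrics <- list(lambdaBar = pm$lambdaBar, rho = pm$rho,
                    lambdaMedian = median(pm$lambda))
    ttl <- applyTTLRules(predictions, config$ttlRules)
  } else if (!is.null(labels)) {
    model <- trainBehaviorTree(t(X), labels, trainingRange,
                               cost = config$cost)
    pb <- predictBehavior(model, t(X[, testRange, drop = FALSE]))
    predictions <- pb$smoothed
    metrics <- list(frameAccuracy =
                      100 * mean(predictions == labels[testRange]))
    ttl <- applyTTLRules(predictions, config$ttlRules)
  }

  out <- list(traces = traces, displacement = st$displacement,
              model = model, predictions = predictions, ttl = ttl,
              metrics = metrics, trainingRange = trainingRange,
              testRange = testRange, masks = masks, config = config)
  if (!is.null(outputDir)) writeSessionOutputs(out, outputDir)
  out
}

#' Write streaming outputs to disk
#'
#' Traces and displacements as frame-major CSV, predictions and the TTL
#' log as CSV, metrics and the config echo as JSON.
#'
#' @param result from [streamSession()].
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
writeSessionOutputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(traces = file.path(dir, "traces.csv"),
                displacement = file.path(dir, "displacement.csv"),
                predictions = file.path(dir, "predictions.csv"),
                metrics = file.path(dir, "metrics.json"),
                config = file.path(dir, "config.json"))
  write.csv(as.data.frame(t(decodingInput(result$traces))), paths$traces,
            row.names = FALSE)
  write.csv(result$displacement, paths$displacement, row.names = FALSE)
  if (!is.null(result$predictions)) {
    pred <- data.frame(frame = result$testRange,
                       prediction = result$predictions)
    if (!is.null(result$ttl)) pred <- cbind(pred, result$ttl)
    write.csv(pred, paths$predictions, row.names = FALSE)
  }
  cfg <- result$config
  cfg$ttlRules <- NULL
  jsonlite::write_json(result$metrics, paths$metrics, auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(cfg, paths$config, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
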