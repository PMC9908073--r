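#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assays<- rowData colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

# ---------------------------------------------------------------------------
# Synthetic session container
# ---------------------------------------------------------------------------

#' MiniscopeSession: a synthetic miniscope recording with ground truth
#'
#' Holds an 8-bit grayscale frame stack together with the ground truth that
#' produced it: the animal trajectory (or behavior label series), the
#' simulated cell population, the scripted image motion, and the noiseless
#' per-cell activation traces. All components span the same number of frames,
#' and regeneration with the same seed is bit-identical.
#'
#' @slot frames integer array, height x width x frames, values in 0..255.
#' @slot trajectory data.frame with columns `position_cm`, `direction`,
#'   `bin` (one row per frame), or a zero-row data.frame for behavior-only
#'   sessions.
#' @slot cells list of ground-truth cells (footprint patch, center, tuning).
#' @slot motion data.frame with per-frame true shifts `dx`, `dy` and `kind`.
#' @slot trueTraces numeric matrix, cells x frames, noiseless activations.
#' @slot behaviorLabels character vector of per-frame labels (length 0 for
#'   track sessions).
#' @slot fps frames per second.
#' @slot trackLength track length in cm (NA for behavior sessions).
#' @slot nBins number of circularized position bins.
#' @slot seed integer seed the session was generated from.
#' @slot params list echoing all generator parameters.
#' @export
setClass("MiniscopeSession",
  representation(frames = "array", trajectory = "data.frame",
                 cells = "list", motion = "data.frame",
                 trueTraces = "matrix", behaviorLabels = "character",
                 fps = "numeric", trackLength = "numeric", nBins = "integer",
                 seed = "integer", params = "list"))

setValidity("MiniscopeSession", function(object) {
  nf <- dim(object@frames)[3]
  msgs <- character()
  if (length(dim(object@frames)) != 3L)
    msgs <- c(msgs, "frames must be a 3D array (height x width x frames)")
  if (nrow(object@motion) != nf)
    msgs <- c(msgs, "motion script must have one row per frame")
  if (nrow(object@trajectory) > 0L && nrow(object@trajectory) != nf)
    msgs <- c(msgs, "trajectory must have one row per frame")
  if (ncol(object@trueTraces) > 0L && ncol(object@trueTraces) != nf)
    msgs <- c(msgs, "trueTraces must have one column per frame")
  if (length(object@behaviorLabels) > 0L &&
      length(object@behaviorLabels) != nf)
    msgs <- c(msgs, "behaviorLabels must have one entry per frame")
  rng <- range(object@frames)
  if (rng[1] < 0 || rng[2] > 255)
    msgs <- c(msgs, "frame values must lie in 0..255")
  if (length(msgs)) msgs else TRUE
})

# ---------------------------------------------------------------------------
# Pixel masks
# ---------------------------------------------------------------------------

#' PixelMaskSet: ROI pixel masks over the working frame
#'
#' Each mask is a set of pixel coordinates defining one ROI, either a 16x16
#' grid tile (`kind = "tile"`, 256 pixels) or a contour mask confined to a
#' 25x25 bounding region (`kind = "contour"`).
#'
#' @slot masks list; each element has `rows`, `cols` (1-based pixel
#'   coordinates), `C` (pixel count), `kind`, and `center`.
#' @slot frameDim integer height, width of the working frame.
#' @slot kind "tile" or "contour".
#' @export
setClass("PixelMaskSet",
  representation(masks = "list", frameDim = "integer", kind = "character"))

setValidity("PixelMaskSet", function(object) {
  msgs <- character()
  for (m in object@masks) {
    if (length(m$rows) != length(m$cols) || length(m$rows) < 1L)
      msgs <- c(msgs, "each mask needs >= 1 pixel with paired coordinates")
    if (any(m$rows < 1L | m$rows > object@frameDim[1]) ||
        any(m$cols < 1L | m$cols > object@frameDim[2]))
      msgs <- c(msgs, "mask pixels must lie within the working frame")
    if (m$kind == "tile" && m$C != 256L)
      msgs <- c(msgs, "tile masks must contain exactly 16 x 16 = 256 pixels")
    if (m$kind == "contour" &&
        (diff(range(m$rows)) >= 25L || diff(range(m$cols)) >= 25L))
      msgs <- c(msgs, "contour mask pixels must fit a 25 x 25 bounding region")
  }
  if (length(msgs)) unique(msgs) else TRUE
})

# ---------------------------------------------------------------------------
# Trace matrix (SummarizedExperiment: rows = ROIs, columns = frames)
# ---------------------------------------------------------------------------

#' CalciumTraces: per-ROI per-frame fluorescence sums
#'
#' A \linkS4class{SummarizedExperiment} whose `raw` assay holds the summed
#' fluorescence T(f) for each ROI (rows) and frame (columns). An optional
#' `filtered` assay holds the drop-filtered series F(f). Row metadata records
#' the pixel count C and kind of each mask.
#'
#' @export
setClass("CalciumTraces", contains = "SummarizedExperiment")

setValidity("CalciumTraces", function(object) {
  msgs <- character()
  if (!"raw" %in% names(assays(object)))
    msgs <- c(msgs, "a 'raw' assay is required")
  else if (any(assay(object, "raw") < 0))
    msgs <- c(msgs, "raw trace sums must be non-negative")
  if (!all(c("maskSize", "kind") %in% colnames(rowData(object))))
    msgs <- c(msgs, "rowData must carry maskSize and kind")
  if (length(msgs)) msgs else TRUE
})

# ---------------------------------------------------------------------------
# Gray code and decoders
# ---------------------------------------------------------------------------

#' GrayCode: cyclic half-window output code
#'
#' An M x K matrix with entries in {-1, +1}, M = K/2, in which cyclically
#' adjacent category columns differ in exactly one row (a cyclic Gray code),
#' used as the error-correcting output code of the position decoder.
#'
#' @slot code integer matrix M x K with entries -1/+1.
#' @slot K number of categories (even).
#' @slot M number of output units, K/2.
#' @export
setClass("GrayCode",
  representation(code = "matrix", K = "integer", M = "integer"))

setValidity("GrayCode", function(object) {
  msgs <- character()
  code <- object@code
  if (object@K %% 2L != 0L) msgs <- c(msgs, "K must be even")
  if (object@M != object@K %/% 2L) msgs <- c(msgs, "M must equal K/2")
  if (!all(code %in% c(-1, 1))) msgs <- c(msgs, "entries must be -1 or +1")
  if (nrow(code) != object@M || ncol(code) != object@K)
    msgs <- c(msgs, "code must be M x K")
  if (ncol(code) >= 2L) {
    for (b in seq_len(ncol(code))) {
      nb <- if (b == ncol(code)) 1L else b + 1L
      if (sum(code[, b] != code[, nb]) != 1L) {
        msgs <- c(msgs, "cyclically adjacent columns must differ in one row")
        break
      }
    }
    if (anyDuplicated(t(code)))
      msgs <- c(msgs, "all category codewords must be distinct")
  }
  if (length(msgs)) msgs else TRUE
})

#' PositionDecoder: Gray-code bank of linear classifiers
#'
#' One L2-regularized linear hinge-loss unit per code row, trained on
#' calcium trace vectors against the row's -1/+1 targets. Prediction takes
#' the category whose codeword has the largest inner product with the
#' real-valued unit scores.
#'
#' @slot units list of fitted binary units (one per code row).
#' @slot code the \linkS4class{GrayCode} used.
#' @slot scaling input standardization parameters.
#' @slot nInputs number of trace inputs N.
#' @export
setClass("PositionDecoder",
  representation(units = "list", code = "GrayCode", scaling = "list",
                 nInputs = "integer"))

setValidity("PositionDecoder", function(object) {
  if (length(object@units) != object@code@M)
    "one fitted unit per code row is required" else TRUE
})

#' BehaviorTree: binary-tree classifier over behavior categories
#'
#' Ordered internal nodes, each a binary linear classifier separating one
#' category from the remaining set; leaves are the five behavior categories.
#'
#' @slot nodes list of nodes (`positive` category, `rest` set, fitted unit).
#' @slot categories character vector of category labels.
#' @slot scaling input standardization parameters.
#' @slot smoothingWindow causal majority-smoothing window in frames.
#' @export
setClass("BehaviorTree",
  representation(nodes = "list", categories = "character", scaling = "list",
                 smoothingWindow = "integer"))

# ---------------------------------------------------------------------------
# Latency report
# ---------------------------------------------------------------------------

#' LatencyReport: closed-loop feedback latency budget
#'
#' @slot tauL light-gathering delay (ms), half the frame interval.
#' @slot tauT frame transmission delay (ms), P x pixel clock.
#' @slot tauI image processing delay (ms), FPGA intercept plus ARM slope
#'   times the number of output units.
#' @slot tauF total feedback latency (ms), tauL + tauT + tauI.
#' @slot P effective transmitted pixels per frame.
#' @slot exposure_ms sensor exposure time (frame interval minus ~1 ms A/D).
#' @slot params input parameter list.
#' @export
setClass("LatencyReport",
  representation(tauL = "numeric", tauT = "numeric", tauI = "numeric",
                 tauF = "numeric", P = "numeric", exposure_ms = "numeric",
                 params = "list"))

setValidity("LatencyReport", function(object) {
  if (abs(object@tauF - (object@tauL + object@tauT + object@tauI)) > 1e-9)
    "tauF must equal tauL + tauT + tauI" else TRUE
})
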