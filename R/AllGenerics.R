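#' Accessors for CalciumStream objects
#'
#' @param object a CalciumStream S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sessionFrames", function(object) standardGeneric("sessionFrames"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("trajectory", function(object) standardGeneric("trajectory"))

#' @rdname accessors
#' @export
setGeneric("motionScriptOf", function(object) standardGeneric("motionScriptOf"))

#' @rdname accessors
#' @export
setGeneric("trueTraces", function(object) standardGeneric("trueTraces"))

#' @rdname accessors
#' @export
setGeneric("behaviorLabels", function(object) standardGeneric("behaviorLabels"))

#' @rdname accessors
#' @export
setGeneric("maskSizes", function(object) standardGeneric("maskSizes"))

#' @rdname accessors
#' @export
setGeneric("maskCount", function(object) standardGeneric("maskCount"))

#' @rdname accessors
#' @export
setGeneric("rawTraces", function(object) standardGeneric("rawTraces"))

#' @rdname accessors
#' @export
setGeneric("filteredTraces", function(object) standardGeneric("filteredTraces"))

#' Trace matrix handed to decoders: the drop-filtered assay when present,
#' otherwise the raw sums.
#' @rdname accessors
#' @export
setGeneric("decodingInput", function(object) standardGeneric("decodingInput"))

#' @rdname accessors
#' @export
setGeneric("codeMatrix", function(object) standardGeneric("codeMatrix"))

setMethod("sessionFrames", "MiniscopeSession", function(object) object@frames)
setMethod("nFrames", "MiniscopeSession", function(object)
  dim(object@frames)[3])
setMethod("trajectory", "MiniscopeSession", function(object) object@trajectory)
setMethod("motionScriptOf", "MiniscopeSession", function(object) object@motion)
setMethod("trueTraces", "MiniscopeSession", function(object) object@trueTraces)
setMethod("behaviorLabels", "MiniscopeSession", function(object)
  object@behaviorLabels)

setMethod("maskCount", "PixelMaskSet", function(object) length(object@masks))
setMethod("maskSizes", "PixelMaskSet", function(object)
  vapply(object@masks, function(m) m$C, integer(1)))

setMethod("rawTraces", "CalciumTraces", function(object)
  assay(object, "raw"))
setMethod("filteredTraces", "CalciumTraces", function(object) {
  if ("filtered" %in% names(assays(object))) assay(object, "filtered")
  else NULL
})
setMethod("decodingInput", "CalciumTraces", function(object) {
  f <- filteredTraces(object)
  if (is.null(f)) rawTraces(object) else f
})
setMethod("maskSizes", "CalciumTraces", function(object)
  rowData(object)$maskSize)
setMethod("nFrames", "CalciumTraces", function(object) ncol(object))

setMethod("codeMatrix", "GrayCode", function(object) object@code)

# ------------------------------ show methods -------------------------------

setMethod("show", "MiniscopeSession", function(object) {
  d <- dim(object@frames)
  kind <- if (length(object@behaviorLabels)) "behavior" else "linear-track"
  cat(sprintf("MiniscopeSession (%s): %d x %d pixels, %d frames @ %.1f fps\n",
              kind, d[1], d[2], d[3], object@fps))
  cat(sprintf("  cells: %d | seed: %d\n", length(object@cells), object@seed))
  if (nrow(object@trajectory))
    cat(sprintf("  track: %.0f cm, %d bins\n", object@trackLength,
                object@nBins))
  mt <- object@motion
  cat(sprintf("  motion: %d frame(s) displaced\n",
              sum(mt$dx != 0 | mt$dy != 0)))
})

setMethod("show", "PixelMaskSet", function(object) {
  cat(sprintf("PixelMaskSet: %d %s mask(s) on a %d x %d frame\n",
              maskCount(object), object@kind,
              object@frameDim[1], object@frameDim[2]))
  cs <- maskSizes(object)
  cat(sprintf("  pixels per mask: min %d, median %.0f, max %d\n",
              min(cs), median(cs), max(cs)))
})

setMethod("show", "GrayCode", function(object) {
  cat(sprintf("GrayCode: %d output units x %d categories (cyclic)\n",
              object@M, object@K))
})

setMethod("show", "PositionDecoder", function(object) {
  cat(sprintf(
    "PositionDecoder: %d linear units over %d trace inputs, %d bins\n",
    object@code@M, object@nInputs, object@code@K))
})

setMethod("show", "BehaviorTree", function(object) {
  cat(sprintf("BehaviorTree: %d node(s) over categories: %s\n",
              length(object@nodes),
              paste(object@categories, collapse = ", ")))
  cat(sprintf("  causal majority smoothing window: %d frames\n",
              object@smoothingWindow))
})

setMethod("show", "LatencyReport", function(object) {
  # presentation rounding to 0.1 ms; stored values keep full precision
  cat("Closed-loop latency budget:\n")
  cat(sprintf("  effective pixels per frame P : %d\n", object@P))
  cat(sprintf("  exposure time                : %.1f ms\n",
              object@exposure_ms))
  cat(sprintf("  light-gathering delay  tauL  : %.1f ms\n", object@tauL))
  cat(sprintf("  frame transmission     tauT  : %.1f ms\n", object@tauT))
  cat(sprintf("  image processing       tauI  : %.1f ms\n", object@tauI))
  cat(sprintf("  total feedback latency tauF  : %.1f ms\n", object@tauF))
})
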