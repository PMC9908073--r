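# Stage 3: ROI pixel masks, fluorescence summation T(f) = sum_i p_i(f),
# drop filtering of small contour masks, and threshold spike inference.

#' Contour-free tile masks
#'
#' Covers the working frame with a uniform grid of square tiles and keeps
#' only the interior tiles (every tile touching the frame border is
#' excluded to avoid edge contamination from motion stabilization), in
#' raster (row-major) order. For the default 512-pixel frame and 16-pixel
#' tiles this yields a 32 x 32 grid, 124 excluded border tiles, and
#' 1024 - 124 = 900 masks of 256 pixels each.
#'
#' @param frameSize side of the square working frame (default 512).
#' @param tile tile side in pixels (default 16); must divide `frameSize`.
#' @return a \linkS4class{PixelMaskSet} of kind "tile".
#' @export
makeTileMasks <- function(frameSize = 512L, tile = 16L) {
  if (frameSize %% tile != 0L)
    stop("frameSize must be divisible by the tile size")
  g <- frameSize %/% tile
  if (g < 3L) stop("the tile grid has no interior tiles")
  masks <- list()
  for (tr in 2:(g - 1L)) {       # raster order over interior tiles
    for (tc in 2:(g - 1L)) {
      rows <- ((tr - 1L) * tile + 1L):(tr * tile)
      cols <- ((tc - 1L) * tile + 1L):(tc * tile)
      px <- expand.grid(row = rows, col = cols)
      masks[[length(masks) + 1L]] <- list(
        rows = as.integer(px$row), cols = as.integer(px$col),
        C = as.integer(tile * tile), kind = "tile",
        center = c(mean(rows), mean(cols)))
    }
  }
  new("PixelMaskSet", masks = masks,
      frameDim = c(as.integer(frameSize), as.integer(frameSize)),
      kind = "tile")
}

#' Contour masks from a label image
#'
#' One mask per positive label. Each mask is confined to the 25 x 25 square
#' bounding region centered on its centroid; pixels falling outside that
#' region are discarded with a warning. Empty labels are skipped with a
#' warning.
#'
#' @param labelImage integer matrix the size of the working frame; 0 is
#'   background, positive integers are ROI labels.
#' @param regionSize bounding-region side (default 25).
#' @return a \linkS4class{PixelMaskSet} of kind "contour".
#' @export
makeContourMasks <- function(labelImage, regionSize = 25L) {
  labs <- sort(unique(labelImage[labelImage > 0]))
  frameDim <- dim(labelImage)
  half <- regionSize %/% 2L
  masks <- list()
  for (lb in labs) {
    idx <- which(labelImage == lb, arr.ind = TRUE)
    if (nrow(idx) == 0L) { warning("label ", lb, " is empty; skipped"); next }
    ctr <- round(colMeans(idx))
    keep <- abs(idx[, 1] - ctr[1]) <= half & abs(idx[, 2] - ctr[2]) <= half
    if (!all(keep))
      warning("label ", lb, ": ", sum(!keep), " pixel(s) outside the ",
              regionSize, " x ", regionSize, " bounding region discarded")
    idx <- idx[keep, , drop = FALSE]
    masks[[length(masks) + 1L]] <- list(
      rows = as.integer(idx[, 1]), cols = as.integer(idx[, 2]),
      C = nrow(idx), kind = "contour",
      center = as.numeric(ctr))
  }
  new("PixelMaskSet", masks = masks, frameDim = as.integer(frameDim),
      kind = "contour")
}

#' Contour masks from ground-truth footprints
#'
#' Thresholds each synthetic cell footprint at a fraction of its maximum to
#' build the label image a source-extraction step would have produced, then
#' derives contour masks from it. Overlapping footprints are resolved in
#' favour of the stronger weight.
#'
#' @param cells ground-truth cell list.
#' @param frameDim working-frame dimensions.
#' @param threshold footprint threshold as a fraction of the peak
#'   (default 0.5, half-max).
#' @return a \linkS4class{PixelMaskSet} of kind "contour".
#' @export
masksFromFootprints <- function(cells, frameDim, threshold = 0.5) {
  lab <- matrix(0L, frameDim[1], frameDim[2])
  wt <- matrix(0, frameDim[1], frameDim[2])
  for (i in seq_along(cells)) {
    cl <- cells[[i]]
    r <- (nrow(cl$footprint) - 1L) %/% 2L
    rows <- (cl$center[1] - r):(cl$center[1] + r)
    cols <- (cl$center[2] - r):(cl$center[2] + r)
    fp <- cl$footprint
    sel <- fp >= threshold * max(fp)
    sub <- wt[rows, cols]
    lab[rows, cols][sel & fp > sub] <- i
    wt[rows, cols] <- pmax(sub, fp * sel)
  }
  makeContourMasks(lab)
}

#' Sum fluorescence within each mask for one frame
#'
#' `T_roi(f) = sum of enhanced pixel intensities over the mask's pixels`;
#' causal, no demixing.
#'
#' @param enhanced enhanced frame (numeric matrix).
#' @param masks a \linkS4class{PixelMaskSet}.
#' @return numeric vector, one sum per mask.
#' @export
extractTraces <- function(enhanced, masks) {
  vapply(masks@masks, function(m)
    sum(enhanced[cbind(m$rows, m$cols)]), numeric(1))
}

#' Sum fluorescence within each mask across a stack
#'
#' @param frames enhanced frames, height x width x frames.
#' @param masks a \linkS4class{PixelMaskSet}.
#' @return a \linkS4class{CalciumTraces} object (assay "raw"; no drop
#'   filtering applied).
#' @export
extractTraceMatrix <- function(frames, masks) {
  d <- dim(frames)
  flat <- frames
  dim(flat) <- c(d[1] * d[2], d[3])
  nm <- maskCount(masks)
  raw <- matrix(0, nm, d[3])
  for (i in seq_len(nm)) {
    m <- masks@masks[[i]]
    lin <- (m$cols - 1L) * d[1] + m$rows
    raw[i, ] <- colSums(flat[lin, , drop = FALSE])
  }
  CalciumTraces(raw, maskSizes = maskSizes(masks),
                kind = vapply(masks@masks, function(m) m$kind, character(1)))
}

#' Construct a CalciumTraces object
#'
#' @param raw ROIs x frames matrix of fluorescence sums T(f).
#' @param filtered optional drop-filtered matrix F(f).
#' @param maskSizes per-ROI pixel counts C.
#' @param kind per-ROI mask kind ("tile"/"contour"), recycled.
#' @return a \linkS4class{CalciumTraces}.
#' @export
CalciumTraces <- function(raw, filtered = NULL, maskSizes, kind = "tile") {
  assays <- list(raw = raw)
  if (!is.null(filtered)) assays$filtered <- filtered
  rd <- S4Vectors::DataFrame(
    maskSize = as.integer(maskSizes),
    kind = rep_len(kind, nrow(raw)))
  new("CalciumTraces",
      SummarizedExperiment::SummarizedExperiment(assays = assays,
                                                 rowData = rd))
}

#' Drop-filter a fluorescence trace
#'
#' Limits the frame-to-frame decrease of traces from small contour masks:
#' with `delta = G * C * q`, `F(1) = T(1)` and
#' `F(f) = max(T(f), F(f-1) - delta)`. Traces from masks with
#' `C >= smallMaskLimit` pixels pass through unchanged.
#'
#' @param trace numeric vector T(f).
#' @param C mask pixel count.
#' @param G maximum single-pixel intensity (255 for 8-bit frames).
#' @param q sensitivity threshold (default 0.9).
#' @param smallMaskLimit masks at or above this pixel count are not
#'   filtered (default 50).
#' @return filtered series F(f).
#' @export
dropFilter <- function(trace, C, G = 255, q = 0.9, smallMaskLimit = 50L) {
  if (C >= smallMaskLimit) return(trace)
  delta <- G * C * q
  out <- trace
  for (f in seq_along(trace)[-1])
    out[f] <- max(trace[f], out[f - 1] - delta)
  out
}

#' Apply the drop filter to every contour trace of a trace matrix
#'
#' Adds (or replaces) the "filtered" assay. Tile traces and contour traces
#' with `C >= smallMaskLimit` are passed through unchanged.
#'
#' @param traces a \linkS4class{CalciumTraces}.
#' @inheritParams dropFilter
#' @return the updated \linkS4class{CalciumTraces}.
#' @export
dropFilterTraces <- function(traces, G = 255, q = 0.9, smallMaskLimit = 50L) {
  raw <- rawTraces(traces)
  flt <- raw
  sizes <- maskSizes(traces)
  kinds <- rowData(traces)$kind
  for (i in seq_len(nrow(raw)))
    if (kinds[i] == "contour")
      flt[i, ] <- dropFilter(raw[i, ], sizes[i], G, q, smallMaskLimit)
  assays(traces)$filtered <- flt
  metadata(traces)$dropFilter <- list(G = G, q = q,
                                      smallMaskLimit = smallMaskLimit)
  traces
}

#' Threshold spike inference
#'
#' The per-trace threshold Phi is 2.5 times the standard deviation of
#' successive-frame differences over the training epoch. An event is
#' emitted for frame f when `T(f) - T(f-1) > Phi` (strict). With
#' `mode = "count"` the event magnitude is `floor(max(0, dT) / Phi)`.
#' A constant training trace gives Phi = 0, is flagged, and emits no
#' events.
#'
#' @param trace numeric vector (one trace).
#' @param trainingRange integer frame indices of the training epoch (must
#'   precede inference frames).
#' @param mode "binary" (default) or "count".
#' @param k threshold multiplier (default 2.5).
#' @return list(threshold, events, degenerate).
#' @export
inferSpikes <- function(trace, trainingRange, mode = c("binary", "count"),
                        k = 2.5) {
  mode <- match.arg(mode)
  if (length(trainingRange) < 2L)
    stop("the training range must contain at least two frames")
  phi <- k * sd(diff(trace[trainingRange]))
  dT <- c(0, diff(trace))
  degenerate <- !is.finite(phi) || phi == 0
  events <- if (degenerate) integer(length(trace))
            else if (mode == "binary") as.integer(dT > phi)
            else as.integer(floor(pmax(0, dT) / phi))
  list(threshold = if (degenerate) 0 else phi, events = events,
       degenerate = degenerate)
}
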