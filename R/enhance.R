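# Stage 2: per-frame background removal. Smooth with a 3x3 mean filter,
# estimate the background by grayscale morphological opening (erosion then
# dilation with a flat 19x19 square structuring element), subtract, clip at
# zero. Both filters use edge replication, which for min/max filtering is
# exactly the restricted-window semantics of EBImage's grayscale morphology.

#' Enhancement configuration
#'
#' @param meanKernel side of the square mean smoothing kernel (odd,
#'   default 3).
#' @param structuringElement side of the flat square structuring element
#'   used for the opening (odd, default 19; must exceed the mean kernel).
#' @return validated config list.
#' @export
enhanceConfig <- function(meanKernel = 3L, structuringElement = 19L) {
  if (meanKernel %% 2L != 1L || structuringElement %% 2L != 1L)
    stop("kernel and structuring element sizes must be odd")
  if (structuringElement <= meanKernel)
    stop("the structuring element must be larger than the mean kernel")
  list(meanKernel = as.integer(meanKernel),
       structuringElement = as.integer(structuringElement))
}

#' Morphological opening with a flat square structuring element
#'
#' Grayscale erosion followed by dilation; idempotent and anti-extensive
#' (the opening never exceeds its input).
#'
#' @param x numeric matrix.
#' @param size structuring-element side (odd).
#' @return opened matrix.
#' @export
morphOpen <- function(x, size = 19L) {
  se <- EBImage::makeBrush(size, shape = "box")
  # EBImage grayscale morphology expects unit-range intensities; opening
  # commutes with positive scaling, so rescale around the call
  s <- max(x, 1)
  EBImage::dilate(EBImage::erode(x / s, se), se) * s
}

#' Enhance a motion-corrected frame
#'
#' `smoothed = mean3x3(frame)`; `background = opening(smoothed, SE19)`;
#' `enhanced = max(smoothed - background, 0)`. The output stays within the
#' 8-bit range and never exceeds the smoothed image.
#'
#' @param frame motion-corrected working frame (numeric matrix).
#' @param config from [enhanceConfig()].
#' @return real-valued enhanced frame, same dimensions, values >= 0.
#' @export
enhanceFrame <- function(frame, config = enhanceConfig()) {
  k <- config$meanKernel
  smoothed <- EBImage::filter2(frame, matrix(1 / (k * k), k, k),
                               boundary = "replicate")
  background <- morphOpen(smoothed, config$structuringElement)
  pmin(pmax(smoothed - background, 0), 255)
}

#' Enhance every frame of a stack
#'
#' @param frames array height x width x frames.
#' @param config from [enhanceConfig()].
#' @return numeric array of enhanced frames.
#' @export
enhanceStack <- function(frames, config = enhanceConfig()) {
  out <- array(0, dim(frames))
  for (f in seq_len(dim(frames)[3]))
    out[, , f] <- enhanceFrame(frames[, , f], config)
  out
}
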