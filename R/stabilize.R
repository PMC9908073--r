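# Stage 1: causal rigid motion stabilization. Each frame's stabilization
# window is contrast-filtered and cross-correlated (zero-padded FFT, i.e.
# linear correlation) against a fixed reference template; the integer argmax
# within the search radius is the frame's displacement.

#' Stabilization configuration
#'
#' @param windowOrigin 1-based (row, col) of the top-left corner of the
#'   stabilization window inside the working frame.
#' @param windowSize side length of the square stabilization window
#'   (default 128).
#' @param kernelSize contrast-filter kernel side (odd, default 17).
#' @param nReferenceFrames frames averaged into the reference template
#'   (default 1000).
#' @param searchRadius maximum displacement magnitude searched, pixels.
#' @param frameDim working-frame dimensions the window must fit inside.
#' @return validated config list.
#' @export
stabilizationConfig <- function(windowOrigin = c(193L, 193L),
                                windowSize = 128L, kernelSize = 17L,
                                nReferenceFrames = 1000L, searchRadius = 16L,
                                frameDim = c(512L, 512L)) {
  if (kernelSize %% 2L != 1L) stop("kernelSize must be odd")
  if (any(windowOrigin < 1L) ||
      windowOrigin[1] + windowSize - 1L > frameDim[1] ||
      windowOrigin[2] + windowSize - 1L > frameDim[2])
    stop("stabilization window must fit inside the working frame")
  if (windowSize <= kernelSize)
    stop("window must be larger than the contrast kernel")
  list(windowOrigin = as.integer(windowOrigin),
       windowSize = as.integer(windowSize),
       kernelSize = as.integer(kernelSize),
       nReferenceFrames = as.integer(nReferenceFrames),
       searchRadius = as.integer(searchRadius),
       frameDim = as.integer(frameDim))
}

#' Zero-sum contrast kernel (difference of Gaussians)
#'
#' A centre-surround difference-of-Gaussians kernel (surround sd twice the
#' centre sd), renormalized to an exactly zero sum so the response to any
#' constant image is identically zero.
#'
#' @param size kernel side (odd, default 17).
#' @param sigma centre Gaussian sd in pixels.
#' @return size x size numeric kernel with `sum(k) == 0`.
#' @export
contrastKernel <- function(size = 17L, sigma = 2.5) {
  if (size %% 2L != 1L) stop("kernel size must be odd")
  d <- seq(-(size %/% 2L), size %/% 2L)
  r2 <- outer(d^2, d^2, "+")
  g1 <- exp(-r2 / (2 * sigma^2));      g1 <- g1 / sum(g1)
  g2 <- exp(-r2 / (2 * (2 * sigma)^2)); g2 <- g2 / sum(g2)
  k <- g1 - g2
  k - mean(k)
}

#' Contrast-filter an image window
#'
#' Linear shift-equivariant filtering with the zero-sum contrast kernel;
#' edge-replicated boundary. A constant window maps to an all-zero response.
#'
#' @param window numeric matrix, at least kernel-sized.
#' @param kernel filter kernel (default [contrastKernel()]).
#' @return real-valued response matrix of the same size.
#' @export
contrastFilter <- function(window, kernel = contrastKernel()) {
  if (nrow(window) < nrow(kernel) || ncol(window) < ncol(kernel))
    stop("window must be at least kernel-sized")
  EBImage::filter2(window, kernel, boundary = "replicate")
}

.cropWindow <- function(frame, config) {
  r0 <- config$windowOrigin[1]; c0 <- config$windowOrigin[2]
  frame[r0:(r0 + config$windowSize - 1L), c0:(c0 + config$windowSize - 1L)]
}

# contrast-filtered stabilization window; the convolution draws on frame
# context around the window where available, so the filtered window moves
# rigidly with the scene instead of acquiring static crop-boundary ridges
.filteredWindow <- function(frame, config, kernel) {
  r <- (config$kernelSize - 1L) %/% 2L
  r0 <- config$windowOrigin[1]; c0 <- config$windowOrigin[2]
  r1 <- r0 + config$windowSize - 1L; c1 <- c0 + config$windowSize - 1L
  er0 <- max(1L, r0 - r); ec0 <- max(1L, c0 - r)
  er1 <- min(nrow(frame), r1 + r); ec1 <- min(ncol(frame), c1 + r)
  filtered <- EBImage::filter2(frame[er0:er1, ec0:ec1], kernel,
                               boundary = "replicate")
  filtered[(r0 - er0 + 1L):(r1 - er0 + 1L),
           (c0 - ec0 + 1L):(c1 - ec0 + 1L)]
}

#' Build the reference template
#'
#' Per-pixel mean of the contrast-filtered stabilization windows of the
#' first `nReferenceFrames` frames. Later frames never alter the template.
#'
#' @param frames integer array (height x width x frames) or list of frames.
#' @param config from [stabilizationConfig()].
#' @return list with `template` (windowSize^2 matrix), `nFramesUsed`, and
#'   the config.
#' @export
buildReference <- function(frames, config = stabilizationConfig()) {
  n <- dim(frames)[3]
  if (is.null(n) || n < config$nReferenceFrames)
    stop("need at least ", config$nReferenceFrames,
         " frames to build the reference template (got ", n, ")")
  k <- contrastKernel(config$kernelSize)
  acc <- matrix(0, config$windowSize, config$windowSize)
  for (f in seq_len(config$nReferenceFrames))
    acc <- acc + .filteredWindow(frames[, , f], config, k)
  list(template = acc / config$nReferenceFrames,
       nFramesUsed = config$nReferenceFrames, config = config)
}

# Zero-normalized linear cross-correlation of a with b over integer lags
# within +/- radius, computed with zero-padded FFTs (Lewis running-sum
# form). For lag (v, u) the score is the Pearson correlation between the
# overlapping parts of a[y, x] and b[y - v, x - u]; normalizing over the
# valid overlap removes the small-lag bias a raw padded correlation has on
# smooth textures. Returned as a (2R+1)^2 matrix, lag v in rows, u in cols.
.xcorrLags <- function(a, b, radius) {
  n <- nrow(a); S <- n + 2L * radius
  pad <- function(x) { P <- matrix(0, S, S); P[seq_len(n), seq_len(n)] <- x; P }
  corrFFT <- function(FA, FB) Re(fft(FA * Conj(FB), inverse = TRUE)) / (S * S)
  ones <- pad(matrix(1, n, n))
  fOnes <- fft(ones)
  fA <- fft(pad(a)); fA2 <- fft(pad(a * a))
  fB <- fft(pad(b)); fB2 <- fft(pad(b * b))
  idx <- function(l) ((l %% S) + S) %% S + 1L
  sel <- idx(-radius:radius)
  Swt <- corrFFT(fA, fB)[sel, sel]
  Sw  <- corrFFT(fA, fOnes)[sel, sel]
  St  <- corrFFT(fOnes, fB)[sel, sel]
  Sww <- corrFFT(fA2, fOnes)[sel, sel]
  Stt <- corrFFT(fOnes, fB2)[sel, sel]
  N <- outer(n - abs(-radius:radius), n - abs(-radius:radius))
  num <- Swt - Sw * St / N
  den2 <- pmax(Sww - Sw^2 / N, 0) * pmax(Stt - St^2 / N, 0)
  out <- num / sqrt(pmax(den2, .Machine$double.eps))
  out[den2 <= 0] <- -Inf   # degenerate overlap cannot win the argmax
  out
}

#' Estimate the rigid displacement of a frame against the reference
#'
#' The contrast-filtered stabilization window is cross-correlated with the
#' stored template by zero-padded FFT (linear correlation); the displacement
#' is the integer argmax within the search radius. Ties are broken toward
#' the smallest |dx| + |dy|, then the smallest dy, then dx. A textureless
#' (all-zero) filtered window returns (0, 0) flagged low-confidence.
#'
#' @param frame working frame containing the stabilization window.
#' @param reference from [buildReference()].
#' @param config optional override of the reference's config.
#' @return list(dx, dy, lowConfidence).
#' @export
estimateDisplacement <- function(frame, reference, config = reference$config) {
  w <- .filteredWindow(frame, config, contrastKernel(config$kernelSize))
  if (all(abs(w) < 1e-9))
    return(list(dx = 0L, dy = 0L, lowConfidence = TRUE))
  R <- config$searchRadius
  cc <- .xcorrLags(w, reference$template, R)
  lags <- -R:R
  best <- which(cc >= max(cc) - 1e-9, arr.ind = TRUE)  # scores are in [-1,1]
  dy <- lags[best[, 1]]; dx <- lags[best[, 2]]
  ord <- order(abs(dx) + abs(dy), dy, dx)
  list(dx = as.integer(dx[ord[1]]), dy = as.integer(dy[ord[1]]),
       lowConfidence = FALSE)
}

#' Apply a rigid motion correction
#'
#' Translates the frame by (-dx, -dy); vacated border pixels are zero.
#'
#' @param frame working frame.
#' @param displacement list or data.frame row with dx, dy.
#' @return corrected frame.
#' @export
applyCorrection <- function(frame, displacement) {
  translateMatrix(frame, -displacement$dx, -displacement$dy, fill = 0)
}

#' Stabilize a frame stack causally
#'
#' Builds the reference template from the first `nReferenceFrames` frames
#' (unless one is supplied), then estimates and corrects the displacement of
#' every frame in order. The estimate for frame f uses only frame f and the
#' fixed template.
#'
#' @param frames integer array height x width x frames.
#' @param config from [stabilizationConfig()].
#' @param reference optional prebuilt reference.
#' @return list(frames = corrected stack, displacement = data.frame(dx, dy,
#'   lowConfidence), reference).
#' @export
stabilizeStack <- function(frames, config = stabilizationConfig(),
                           reference = NULL) {
  if (is.null(reference)) reference <- buildReference(frames, config)
  n <- dim(frames)[3]
  dx <- integer(n); dy <- integer(n); lc <- logical(n)
  out <- frames
  for (f in seq_len(n)) {
    d <- estimateDisplacement(frames[, , f], reference, config)
    dx[f] <- d$dx; dy[f] <- d$dy; lc[f] <- d$lowConfidence
    if (d$dx != 0L || d$dy != 0L)
      out[, , f] <- applyCorrection(frames[, , f], d)
  }
  list(frames = out,
       displacement = data.frame(dx = dx, dy = dy, lowConfidence = lc),
       reference = reference)
}

#' Displacement-derived motion features
#'
#' From per-frame (dx, dy) derives d = sqrt(dx^2 + dy^2), the frame-to-frame
#' change delta d (0 for the first frame), and |delta d| -- the five-element
#' per-frame motion ("Mot") predictor used as a control decoder input.
#'
#' @param displacement data.frame with dx, dy.
#' @return matrix frames x 5 with columns dx, dy, d, dd, abs_dd.
#' @export
motionFeatures <- function(displacement) {
  d <- sqrt(displacement$dx^2 + displacement$dy^2)
  dd <- c(0, diff(d))
  cbind(dx = displacement$dx, dy = displacement$dy, d = d, dd = dd,
        abs_dd = abs(dd))
}
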