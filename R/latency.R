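# Closed-loop feedback latency budget: light gathering, frame transmission,
# and image processing delays, and their total.

#' Effective transmitted pixels per frame
#'
#' Pixels are transmitted in raster order; decoding can start once the
#' bottom-right pixel of the imaging subwindow has arrived, so the
#' effective count is `P = W * (B - 1) + R`, with 1-based bottom-most row B
#' and right-most column R of the subwindow on a sensor of width W.
#'
#' @param W sensor width in pixels.
#' @param B bottom-most subwindow row (1-based).
#' @param R right-most subwindow column (1-based).
#' @param H sensor height (defaults to W) for bounds checking.
#' @return effective pixel count P.
#' @export
pixelsPerFrame <- function(W, B, R, H = W) {
  if (!.isWholeNumber(W) || !.isWholeNumber(B) || !.isWholeNumber(R))
    stop("W, B and R must be whole numbers")
  if (B < 1 || B > H) stop("B must lie in 1..H")
  if (R < 1 || R > W) stop("R must lie in 1..W")
  W * (B - 1) + R
}

#' Closed-loop latency budget
#'
#' The total feedback latency is the sum of three sequential delays:
#' the light-gathering delay `tauL = I/2` (boxcar integration over the
#' frame interval I), the frame transmission delay `tauT = P * C` (effective
#' pixels times the pixel clock period), and the image processing delay
#' `tauI`, affine in the number of decoder output units M
#' (`tauI = fpgaIntercept + armSlope * M`, or a fixed worst-case bound when
#' `tauI_ms` is supplied). The sensor exposure time is about 1 ms shorter
#' than the frame interval (A/D conversion).
#'
#' @param frameInterval_ms frame interval I in ms (e.g. 50 at 20 Hz).
#' @param W sensor width (pixels); default 608 (V4 sensor).
#' @param H sensor height; default 608.
#' @param subwindow side of the square imaging subwindow (default 512).
#' @param B,R 1-based bottom row / right column of the subwindow; default:
#'   subwindow centered on the sensor.
#' @param pixelClock_ns pixel clock period in ns (default 60.24, V4).
#' @param nOutputUnits decoder output unit count M (default 12).
#' @param fpgaIntercept_ms FPGA processing delay (default 0.888 ms).
#' @param armSlope_us_per_unit ARM decoding slope (default 47.3 us/unit).
#' @param tauI_ms optional fixed processing delay overriding the affine
#'   model (e.g. a worst-case bound).
#' @return a \linkS4class{LatencyReport}.
#' @export
latencyBudget <- function(frameInterval_ms = 50, W = 608L, H = W,
                          subwindow = 512L,
                          B = H / 2 + subwindow / 2,
                          R = W / 2 + subwindow / 2,
                          pixelClock_ns = 60.24, nOutputUnits = 12L,
                          fpgaIntercept_ms = 0.888,
                          armSlope_us_per_unit = 47.3, tauI_ms = NULL) {
  if (frameInterval_ms <= 0 || pixelClock_ns <= 0)
    stop("frame interval and pixel clock must be positive")
  P <- pixelsPerFrame(W, B, R, H)
  tauL <- frameInterval_ms / 2
  tauT <- P * pixelClock_ns * 1e-6
  tauI <- if (!is.null(tauI_ms)) tauI_ms
          else fpgaIntercept_ms + armSlope_us_per_unit * nOutputUnits / 1000
  new("LatencyReport",
      tauL = tauL, tauT = tauT, tauI = tauI, tauF = tauL + tauT + tauI,
      P = P, exposure_ms = frameInterval_ms - 1,
      params = list(frameInterval_ms = frameInterval_ms, W = W, H = H,
                    B = B, R = R, pixelClock_ns = pixelClock_ns,
                    nOutputUnits = nOutputUnits,
                    fpgaIntercept_ms = fpgaIntercept_ms,
                    armSlope_us_per_unit = armSlope_us_per_unit))
}
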