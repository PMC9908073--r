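#' @import methods
#' @importFrom stats cor cor.test fft rnorm runif sd quantile median
#' @importFrom utils head tail write.csv read.csv modifyList
NULL

#' Translate a matrix by an integer pixel offset
#'
#' Shifts matrix content by `dx` columns (positive = rightward) and `dy`
#' rows (positive = downward). Vacated pixels are filled with `fill`.
#'
#' @param m numeric matrix (rows = y, columns = x).
#' @param dx,dy integer shifts in pixels.
#' @param fill value for vacated border pixels.
#' @return matrix of the same dimensions.
#' @export
translateMatrix <- function(m, dx, dy, fill = 0) {
  stopifnot(is.matrix(m), dx == round(dx), dy == round(dy))
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  if (abs(dx) >= nc || abs(dy) >= nr) return(out)
  srcR <- seq_len(nr) - dy
  srcC <- seq_len(nc) - dx
  okR <- srcR >= 1L & srcR <= nr
  okC <- srcC >= 1L & srcC <= nc
  out[okR, okC] <- m[srcR[okR], srcC[okC]]
  out
}

# clip to the 8-bit sensor range
.clip8 <- function(x) pmin(pmax(x, 0), 255)

# derive a child seed from a base seed and an integer salt, kept < 2^31
.childSeed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 7919 + salt * 104729) %% 2147483647)
}

.isWholeNumber <- function(x, tol = 1e-8) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && abs(x - round(x)) < tol
}
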