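# Binary morphology with the chessboard ball (square structuring element),
# implemented with running sums: a pixel survives erosion by the
# (2k+1)x(2k+1) square iff the window sum equals the window area, and is set
# by dilation iff the window sum is positive. Both passes are separable, so
# the cost is O(pixels) independent of k.

movingWindowSum <- function(x, k) {
  # column-wise moving sum over rows with window 2k+1, zero-padded
  n <- nrow(x)
  cs <- rbind(0, apply(x, 2, cumsum))
  hi <- pmin(n, seq_len(n) + k)
  lo <- pmax(0, seq_len(n) - k - 1)
  cs[hi + 1, , drop = FALSE] - cs[lo + 1, , drop = FALSE]
}

#' Binary dilation and erosion by a chessboard ball
#'
#' Dilation/erosion of a binary mask by the square structuring element of
#' radius `k` (the `(2k+1) x (2k+1)` box, i.e. the ball of the 8-neighbour
#' chessboard metric). `padValue` controls how pixels outside the image frame
#' are treated during erosion (`TRUE` = foreground, so that a mask touching
#' the frame is not eaten from outside).
#'
#' @param mask logical (or 0/1) matrix.
#' @param k structuring-element radius in pixels (`k = 0` is the identity).
#' @param padValue assumed value outside the frame for erosion.
#' @return logical matrix of the same dimensions.
#' @examples
#' m <- matrix(FALSE, 7, 7); m[4, 4] <- TRUE
#' sum(boxDilate(m, 1))  # 3 x 3 block
#' @export
boxDilate <- function(mask, k) {
  stopifnot(k >= 0)
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (k == 0) return(m > 0)
  m <- movingWindowSum(m, k)
  m <- t(movingWindowSum(t(m), k))
  m > 0
}

#' @rdname boxDilate
#' @export
boxErode <- function(mask, k, padValue = FALSE) {
  stopifnot(k >= 0)
  if (k == 0) return(mask > 0)
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(as.numeric(padValue), nr + 2 * k, nc + 2 * k)
  p[(k + 1):(k + nr), (k + 1):(k + nc)] <- as.numeric(mask)
  s <- movingWindowSum(p, k)
  s <- t(movingWindowSum(t(s), k))
  e <- s == (2 * k + 1)^2
  e[(k + 1):(k + nr), (k + 1):(k + nc)]
}

#' Label connected components (8-connectivity)
#'
#' Deterministic 8-connected component labelling; labels follow the
#' raster-scan order of each component's first pixel.
#'
#' @param mask logical (or 0/1) matrix.
#' @return integer matrix of labels (0 = background).
#' @export
labelComponents <- function(mask) {
  cpp_label8(matrix(as.logical(mask), nrow(mask), ncol(mask)))
}

#' Fill interior holes of a binary mask
#'
#' Background regions not connected to the image frame are turned into
#' foreground (hole closing).
#'
#' @param mask logical (or 0/1) matrix.
#' @return logical matrix.
#' @export
fillHoles <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  EBImage::fillHull(m) > 0
}
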