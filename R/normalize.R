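# Quantile normalization of linear intensities across arrays, and the
# log2 transform feeding the t tests and heatmaps.  Normalization is done
# on the linear scale and fold changes are computed from linear
# normalized values, so the FC > 2 / FC < 0.5 thresholds stay on the
# scale the screening criteria are stated on.

#' Quantile normalization
#'
#' Forces every column (array) to share one intensity distribution: the
#' value at rank r in column c is replaced by the across-column mean of
#' the rank-r values.  Ties within a column receive the mean of the
#' reference values over their tied rank span, which keeps the transform
#' deterministic and symmetric under column permutation.  After
#' normalization all columns hold identical multisets of values.
#'
#' @param matrix numeric probe x sample matrix, non-negative, no missing
#'   values, at least one column.
#' @return matrix of the same shape and dimnames.
#' @export
#' @examples
#' m <- cbind(a = c(2, 1, 3), b = c(4, 3, 5))
#' quantile_normalize(m)  # both columns become (3, 2, 4)
quantile_normalize <- function(matrix) {
  m <- as.matrix(matrix)
  if (ncol(m) < 1) input_error("quantile normalization needs >= 1 column")
  if (anyNA(m)) input_error("missing values are not supported")
  if (any(m < 0)) input_error("negative intensity")
  if (ncol(m) == 1) return(m)
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    y <- numeric(length(x))
    y[order(x)] <- ref
    # tied values share the mean reference value over their rank span
    out[, j] <- ave(y, x, FUN = mean)
  }
  out
}

#' Log2 transform with offset
#'
#' Elementwise `log2(value + offset)`.  The offset (default 1, linear
#' fluorescence units) guards zero intensities; it is recorded in the
#' result's provenance attribute.
#'
#' @param matrix numeric matrix with `matrix + offset > 0`.
#' @param offset small positive real added before taking logs.
#' @param method provenance tag describing how `matrix` was normalized.
#' @return matrix of log2 values with attribute `provenance`, a list
#'   with `method` and `log2_offset`.
#' @export
log2_transform <- function(matrix, offset = 1, method = "quantile") {
  m <- as.matrix(matrix)
  if (any(m + offset <= 0)) input_error("values + offset must be positive")
  out <- log2(m + offset)
  attr(out, "provenance") <- list(method = method, log2_offset = offset)
  out
}
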