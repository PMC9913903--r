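#' Standard normal variate (SNV) preprocessing
#'
#' Centers and scales each spectrum (row) to zero mean and unit standard
#' deviation. SNV is the standard chemometric correction for per-sample
#' multiplicative scatter and additive baseline offsets: it is exactly
#' invariant to the row-wise affine map `a * x + b` for `a > 0`.
#'
#' The scale uses the sample (n-1 denominator) standard deviation by
#' default, the common SNV convention; set `denominator = "n"` for the
#' population form. Either way the transform is idempotent up to
#' floating-point error.
#'
#' @param x a numeric matrix (samples in rows) or a [spectra_set()].
#' @param denominator `"n-1"` (default) or `"n"`.
#' @return An object of the same type as `x` with each row standardized.
#' @examples
#' snv(matrix(c(1, 2, 3), 1))  # -1 0 1
#' @export
snv <- function(x, denominator = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  if (inherits(x, "spectra_set")) {
    x$absorbance <- snv(x$absorbance, denominator)
    return(x)
  }
  x <- as.matrix(x)
  d <- ncol(x)
  if (d < 2L) stop("SNV requires at least 2 channels per spectrum")
  mu <- rowMeans(x)
  cx <- x - mu
  ss <- rowSums(cx^2)
  div <- if (denominator == "n-1") d - 1L else d
  sd_row <- sqrt(ss / div)
  zero <- sd_row <= 0
  if (any(zero))
    stop("zero-variance (constant) spectrum in row(s): ",
         paste(which(zero)[seq_len(min(5, sum(zero)))], collapse = ", "))
  cx / sd_row
}
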