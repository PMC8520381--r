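#' Pair an original raster with its reconstruction
#'
#' The operand of the reconstruction-quality metrics. Both rasters must
#' have identical dimensions and finite entries.
#'
#' @param original Numeric matrix (or vector) `t` of pixel densities.
#' @param reconstructed Numeric matrix (or vector) `r`, same dimensions.
#' @param max_value Dynamic-range ceiling used by PSNR. Default: 255 when
#'   the original looks like an 8-bit raster (integer-valued in
#'   `[0, 255]` with a value above 1), otherwise the original's maximum
#'   absolute value. Always overridable.
#' @return An object of class `image_pair`.
#' @export
image_pair <- function(original, reconstructed, max_value = NULL) {
  t_ <- as.matrix(original)
  r_ <- as.matrix(reconstructed)
  if (!identical(dim(t_), dim(r_)))
    stop_domain("original and reconstructed images must have identical dimensions")
  if (!all(is.finite(t_)) || !all(is.finite(r_)))
    stop_domain("images must have finite entries")
  if (is.null(max_value)) {
    eight_bit <- all(t_ >= 0 & t_ <= 255) && all(t_ == round(t_)) && max(t_) > 1
    max_value <- if (eight_bit) 255 else max(abs(t_))
    if (max_value == 0) max_value <- 1
  }
  if (max_value <= 0) stop_domain("`max_value` must be > 0")
  structure(list(original = t_, reconstructed = r_, max_value = max_value),
            class = "image_pair")
}

#' Normalized mean square distance (l)
#'
#' `l = sqrt( sum (t - r)^2 / sum (t - tbar)^2 )` with `tbar` the mean
#' density of the original: the root-mean-square deviation of the
#' reconstruction, normalized by the original's own variation. Zero iff
#' the images are identical; larger means greater deviation.
#'
#' @param pair An [image_pair()]. The original must not be constant
#'   (positive normalizer).
#' @return Nonnegative scalar.
#' @export
metric_l <- function(pair) {
  stopifnot(inherits(pair, "image_pair"))
  t_ <- pair$original; r_ <- pair$reconstructed
  denom <- sum((t_ - mean(t_))^2)
  if (denom <= 0)
    stop_domain("original image is constant: normalized distance is undefined")
  sqrt(sum((t_ - r_)^2) / denom)
}

#' Normalized mean absolute distance (f)
#'
#' `f = sum |t - r| / sum |t|`: the total absolute error relative to the
#' total density of the original. Zero iff identical; larger means larger
#' error.
#'
#' @param pair An [image_pair()]. The original must have positive total
#'   absolute density.
#' @return Nonnegative scalar.
#' @export
metric_f <- function(pair) {
  stopifnot(inherits(pair, "image_pair"))
  t_ <- pair$original; r_ <- pair$reconstructed
  denom <- sum(abs(t_))
  if (denom <= 0)
    stop_domain("original image is all zero: normalized distance is undefined")
  sum(abs(t_ - r_)) / denom
}

#' Mean square error and peak signal-to-noise ratio
#'
#' `MSE = mean((t - r)^2)`; `PSNR = 10 log10(max_value^2 / MSE)` in dB.
#' Identical images return `MSE = 0` and the `+Inf` PSNR sentinel. Larger
#' PSNR means less distortion.
#'
#' @param pair An [image_pair()].
#' @return List with components `mse` and `psnr_db`.
#' @export
mse_psnr <- function(pair) {
  stopifnot(inherits(pair, "image_pair"))
  mse <- mean((pair$original - pair$reconstructed)^2)
  psnr <- if (mse > 0) 10 * log10(pair$max_value^2 / mse) else Inf
  list(mse = mse, psnr_db = psnr)
}

#' Full reconstruction-quality report
#'
#' Computes all three indices — normalized mean square distance `l`,
#' normalized mean absolute distance `f`, and PSNR (with MSE) — for one
#' image pair.
#'
#' @param pair An [image_pair()].
#' @return An object of class `metric_report`: list with `metric_l`,
#'   `metric_f`, `mse`, `psnr_db`.
#' @export
recon_metrics <- function(pair) {
  mp <- mse_psnr(pair)
  structure(
    list(metric_l = metric_l(pair), metric_f = metric_f(pair),
         mse = mp$mse, psnr_db = mp$psnr_db),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("l (NMSD)  = %.6g\nf (NMAD)  = %.6g\nMSE       = %.6g\nPSNR (dB) = %.6g\n",
              x$metric_l, x$metric_f, x$mse, x$psnr_db))
  invisible(x)
}
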