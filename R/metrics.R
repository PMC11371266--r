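# Reconstruction quality metrics.

#' Peak signal-to-noise ratio
#'
#' `10 log10(peak^2 / MSE)` in decibels; `Inf` when the images coincide.
#'
#' @param x,ref images of identical shape.
#' @param peak peak signal value (> 0; default 1 for intensities in [0, 1]).
#' @return PSNR in dB.
#' @export
psnr <- function(x, ref, peak = 1) {
  if (!all(dim(x) == dim(ref))) stop("psnr: shape mismatch")
  if (peak <= 0) stop("peak must be positive")
  mse <- mean((x - ref)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Structural similarity index
#'
#' Standard windowed SSIM with an 11x11 Gaussian window (sd 1.5), the
#' conventional stabilization constants `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`,
#' and data range `L = 1`. Local statistics are computed with
#' border-normalized window weights, so constant images reduce exactly to the
#' closed-form luminance term. Symmetric in its arguments.
#'
#' @param x,ref images of identical shape.
#' @param dataRange dynamic range L of the data (default 1).
#' @return mean SSIM over the image, in `[-1, 1]`.
#' @export
ssim <- function(x, ref, dataRange = 1) {
  if (!all(dim(x) == dim(ref))) stop("ssim: shape mismatch")
  C1 <- (0.01 * dataRange)^2
  C2 <- (0.03 * dataRange)^2
  g <- exp(-((-5:5)^2) / (2 * 1.5^2))
  win <- outer(g, g); win <- win / sum(win)
  kern <- array(win, dim = c(11, 11, 1, 1))
  filt <- function(a) {
    f <- cpp_conv2d(array(a, dim = c(dim(a), 1L)), kern, 11L, 1L, 1L, 1L, 1L,
                    0L, FALSE)[, , 1]
    f
  }
  wsum <- filt(matrix(1, nrow(x), ncol(x)))  # border re-normalization
  mu1 <- filt(x) / wsum
  mu2 <- filt(ref) / wsum
  s11 <- filt(x * x) / wsum - mu1^2
  s22 <- filt(ref * ref) / wsum - mu2^2
  s12 <- filt(x * ref) / wsum - mu1 * mu2
  num <- (2 * mu1 * mu2 + C1) * (2 * s12 + C2)
  den <- (mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)
  mean(num / den)
}
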