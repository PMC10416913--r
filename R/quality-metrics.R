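# Full-reference and no-reference image quality measures used to judge the
# contrast enhancement. All functions take grayscale matrices on the 0-255
# scale; full-reference measures require equal dimensions.

check_pair <- function(reference, test) {
  check_gray_image(reference)
  check_gray_image(test)
  if (!all(dim(reference) == dim(test)))
    stop("reference and test images must have identical dimensions",
         call. = FALSE)
}

#' Peak signal-to-noise ratio
#'
#' \eqn{10 \log_{10}(255^2 / \mathrm{MSE})} in decibels. Identical images
#' have zero MSE and return `Inf`.
#'
#' @param reference,test grayscale matrices of equal size, 0-255 scale.
#' @return PSNR in dB (`Inf` for identical images).
#' @export
psnr <- function(reference, test) {
  check_pair(reference, test)
  mse <- mean((reference - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(255^2 / mse)
}

#' Structural similarity index
#'
#' Mean SSIM with the standard stabilizing constants
#' \eqn{A_1 = (0.01 \cdot 255)^2} and \eqn{A_2 = (0.03 \cdot 255)^2}.
#' Local means, variances and covariance are computed under an 11x11
#' Gaussian window (sigma 1.5) and the per-pixel SSIM map is averaged;
#' `global = TRUE` instead evaluates the statistic once over the whole
#' image (single-window form).
#'
#' @param reference,test grayscale matrices of equal size, 0-255 scale.
#' @param global evaluate a single global window instead of the windowed
#'   mean (default FALSE).
#' @return SSIM in [-1, 1]; 1 for identical images.
#' @export
ssim <- function(reference, test, global = FALSE) {
  check_pair(reference, test)
  a1 <- (0.01 * 255)^2
  a2 <- (0.03 * 255)^2
  if (global) {
    mx <- mean(reference); my <- mean(test)
    vx <- mean((reference - mx)^2); vy <- mean((test - my)^2)
    cxy <- mean((reference - mx) * (test - my))
    return(((2 * mx * my + a1) * (2 * cxy + a2)) /
             ((mx^2 + my^2 + a1) * (vx + vy + a2)))
  }
  half <- 5L
  x <- -half:half
  g <- exp(-x^2 / (2 * 1.5^2))
  w <- outer(g, g); w <- w / sum(w)
  f <- function(m) EBImage::filter2(m, w, boundary = "replicate")
  mx <- f(reference); my <- f(test)
  vx <- f(reference^2) - mx^2
  vy <- f(test^2) - my^2
  cxy <- f(reference * test) - mx * my
  ssim_map <- ((2 * mx * my + a1) * (2 * cxy + a2)) /
    ((mx^2 + my^2 + a1) * (vx + vy + a2))
  mean(ssim_map)
}

#' Gradient magnitude similarity deviation
#'
#' GMSD: Prewitt gradient magnitudes of both images are compared through the
#' pointwise similarity \eqn{(2 g_r g_t + c)/(g_r^2 + g_t^2 + c)} with
#' \eqn{c = 170}, and the score is the population standard deviation of the
#' similarity map. 0 for identical images; larger values mean stronger
#' structural distortion.
#'
#' @param reference,test grayscale matrices of equal size, 0-255 scale.
#' @param c stabilizing constant (default 170).
#' @return nonnegative deviation score.
#' @export
gmsd <- function(reference, test, c = 170) {
  check_pair(reference, test)
  px <- matrix(c(1, 0, -1, 1, 0, -1, 1, 0, -1), 3, 3) / 3
  grad_mag <- function(m) {
    gx <- EBImage::filter2(m, px, boundary = "replicate")
    gy <- EBImage::filter2(m, t(px), boundary = "replicate")
    sqrt(gx^2 + gy^2)
  }
  gr <- grad_mag(reference)
  gt <- grad_mag(test)
  gms <- (2 * gr * gt + c) / (gr^2 + gt^2 + c)
  sqrt(mean((gms - mean(gms))^2))
}

#' Patch-based contrast quality index
#'
#' PCQI-style patch score rewarding faithful or increased local contrast.
#' Each 11x11 patch is decomposed into mean intensity, signal strength
#' (deviation norm) and structure; the patch score is the product of a
#' contrast-change term \eqn{(4/\pi)\arctan(s_t/s_r)} (saturating reward for
#' contrast gain), a structure-fidelity term (normalized correlation of the
#' mean-removed patches) and a mean-shift penalty \eqn{\exp(-|\mu_t -
#' \mu_r|/255)}. The index is the average patch score: 1 for identical
#' images, above 1 for structure-preserving contrast amplification.
#'
#' @param reference,test grayscale matrices of equal size, 0-255 scale.
#' @param window patch edge length (default 11).
#' @param eps stabilizing constant for the strength and structure ratios.
#' @return nonnegative index; 1 for identical images.
#' @export
pcqi <- function(reference, test, window = 11L, eps = 1e-3) {
  check_pair(reference, test)
  w <- matrix(1 / window^2, window, window)
  f <- function(m) EBImage::filter2(m, w, boundary = "replicate")
  mr <- f(reference); mt <- f(test)
  sr <- sqrt(pmax(f(reference^2) - mr^2, 0))
  st <- sqrt(pmax(f(test^2) - mt^2, 0))
  crt <- f(reference * test) - mr * mt
  q_contrast <- (4 / pi) * atan((st + eps) / (sr + eps))
  q_structure <- (crt + eps) / (sr * st + eps)
  q_mean <- exp(-abs(mt - mr) / 255)
  mean(q_contrast * q_structure * q_mean)
}

#' All quality scores for an image pair
#'
#' @param reference,test grayscale matrices of equal size, 0-255 scale.
#' @return list of class `quality_scores` with `entropy_bits` (of the test
#'   image), `psnr_db`, `ssim`, `gmsd` and `pcqi`.
#' @export
quality_scores <- function(reference, test) {
  check_pair(reference, test)
  structure(list(entropy_bits = image_entropy(test),
                 psnr_db = psnr(reference, test),
                 ssim = ssim(reference, test),
                 gmsd = gmsd(reference, test),
                 pcqi = pcqi(reference, test)),
            class = "quality_scores")
}

#' @export
print.quality_scores <- function(x, ...) {
  cat("Image quality scores\n")
  cat(sprintf("  entropy : %.4f bits\n", x$entropy_bits))
  cat(sprintf("  PSNR    : %s dB\n",
              if (is.infinite(x$psnr_db)) "Inf" else sprintf("%.2f", x$psnr_db)))
  cat(sprintf("  SSIM    : %.4f\n", x$ssim))
  cat(sprintf("  GMSD    : %.4f\n", x$gmsd))
  cat(sprintf("  PCQI    : %.4f\n", x$pcqi))
  invisible(x)
}
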