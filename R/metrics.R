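# Evaluation metrics: PSNR and single-scale SSIM, plus dataset-level
# aggregation against a trained model.

.as_hw11 <- function(x) array(as.matrix(x), c(nrow(x), ncol(x), 1L, 1L))

# Normalized 2-D Gaussian window as a conv kernel (KH, KW, 1, 1).
.gauss_kernel <- function(size = 11L, sigma = 1.5) {
  r <- seq_len(size) - (size + 1) / 2
  g <- exp(-r^2 / (2 * sigma^2))
  k <- outer(g, g)
  array(k / sum(k), c(size, size, 1L, 1L))
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(MAX^2 / MSE)` over all pixels. When the images are identical
#' (zero MSE) the configured `cap` is returned (`Inf` by default).
#'
#' @param x,y Numeric matrices of identical shape.
#' @param max_value Peak intensity MAX (1 for normalized images).
#' @param cap Value returned when MSE is exactly zero.
#' @return PSNR in decibels.
#' @export
psnr <- function(x, y, max_value = 1, cap = Inf) {
  if (!all(dim(as.matrix(x)) == dim(as.matrix(y))))
    stop("psnr: images must have identical shape", call. = FALSE)
  if (max_value <= 0) stop("psnr: max_value must be positive", call. = FALSE)
  mse <- mean((as.matrix(x) - as.matrix(y))^2)
  if (mse == 0) return(cap)
  10 * log10(max_value^2 / mse)
}

#' Structural similarity index (single scale)
#'
#' Mean local SSIM with an 11x11 Gaussian window (sigma 1.5), valid-region
#' windowing, and stability constants `c1 = (0.01 MAX)^2`,
#' `c2 = (0.03 MAX)^2`.
#'
#' @param x,y Numeric matrices of identical shape, min side at least
#'   `window_size`.
#' @param max_value Peak intensity MAX.
#' @param window_size,window_sigma Gaussian window parameters.
#' @return SSIM in `[-1, 1]`; exactly 1 for identical images.
#' @export
ssim <- function(x, y, max_value = 1, window_size = 11L, window_sigma = 1.5) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!all(dim(x) == dim(y)))
    stop("ssim: images must have identical shape", call. = FALSE)
  if (min(dim(x)) < window_size)
    stop("ssim: image smaller than the local window; reduce window_size",
         call. = FALSE)
  k <- .gauss_kernel(window_size, window_sigma)
  zb <- numeric(1)
  cv <- function(a) cpp_conv2d(.as_hw11(a), k, zb, 0L)
  mu_x <- cv(x); mu_y <- cv(y)
  sxx <- cv(x * x) - mu_x^2
  syy <- cv(y * y) - mu_y^2
  sxy <- cv(x * y) - mu_x * mu_y
  c1 <- (0.01 * max_value)^2
  c2 <- (0.03 * max_value)^2
  smap <- ((2 * mu_x * mu_y + c1) * (2 * sxy + c2)) /
    ((mu_x^2 + mu_y^2 + c1) * (sxx + syy + c2))
  mean(smap)
}

#' Evaluate a model over a dataset of pairs
#'
#' Runs the model in eval mode on every pair and reports per-image and mean
#' PSNR/SSIM both for the raw low-dose input and for the denoised output,
#' each against the normal-dose reference.
#'
#' @param model A [build_model()] result.
#' @param pairs List of [image_pair()] objects.
#' @param max_value Peak intensity for the metrics.
#' @param csv Optional path; when given the per-image table is written as CSV.
#' @return A list with `per_image` (data frame) and `mean` (named numeric).
#' @export
evaluate <- function(model, pairs, max_value = 1, csv = NULL) {
  if (length(pairs) == 0)
    stop("evaluate: empty dataset", call. = FALSE)
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    den <- denoise(model, p$ldct)
    data.frame(image = i,
               psnr_ldct = psnr(p$ldct, p$ndct, max_value),
               ssim_ldct = ssim(p$ldct, p$ndct, max_value),
               psnr_denoised = psnr(den, p$ndct, max_value),
               ssim_denoised = ssim(den, p$ndct, max_value))
  })
  per_image <- do.call(rbind, rows)
  means <- colMeans(per_image[, -1, drop = FALSE])
  if (!is.null(csv)) utils::write.csv(per_image, csv, row.names = FALSE)
  list(per_image = per_image, mean = means)
}
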