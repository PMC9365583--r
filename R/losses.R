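# Training losses: MSE, multi-scale structural similarity (MS-SSIM), and a
# gradient loss built on a fixed 3x3 high-pass kernel, combined as
# L = lambda1 * L_MSE + lambda2 * L_MS-SSIM + lambda3 * L_grad, with the
# two-pass total L_total = L_original + L_correct.
#
# Each loss exists in two forms: a tape builder (tl_*) used inside training
# graphs, and a numeric wrapper exported for users; the wrapper evaluates the
# same tape code, so there is a single implementation of each formula.

#' Loss term weights
#'
#' @param lambda1 Weight of the MSE term (default 1).
#' @param lambda2 Weight of the MS-SSIM term (default 0.15).
#' @param lambda3 Weight of the gradient term (default 0.8).
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(lambda1 = 1, lambda2 = 0.15, lambda3 = 0.8) {
  w <- c(lambda1, lambda2, lambda3)
  if (any(!is.finite(w)) || any(w < 0))
    stop("loss_weights: weights must be finite and non-negative", call. = FALSE)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3),
            class = "loss_weights")
}

#' MS-SSIM parameters
#'
#' Defaults are the standard five-scale exponents (used as printed; their sum
#' is 1.0001) with an 11x11 Gaussian window of sigma 1.5. For fewer scales
#' the first `n_scales` exponents are renormalized to sum to one. Stability
#' constants follow `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`, `C3 = C2 / 2`,
#' where `L` is the dynamic range (1 for normalized images).
#'
#' @param scale_weights Per-scale exponents (luminance/contrast/structure
#'   share one exponent per scale).
#' @param n_scales Number of dyadic scales M; defaults to
#'   `length(scale_weights)`. Small test images need a reduced M.
#' @param window_size,window_sigma Gaussian window for local statistics.
#' @param dynamic_range Intensity range L of the images.
#' @return An object of class `msssim_params`.
#' @export
msssim_params <- function(scale_weights = c(0.0448, 0.2856, 0.3001, 0.2363,
                                            0.1333),
                          n_scales = length(scale_weights),
                          window_size = 11L, window_sigma = 1.5,
                          dynamic_range = 1) {
  if (n_scales < 1 || n_scales > length(scale_weights))
    stop("msssim_params: n_scales must be between 1 and the number of scale weights",
         call. = FALSE)
  w <- scale_weights[seq_len(n_scales)]
  if (n_scales < length(scale_weights)) w <- w / sum(w)
  structure(list(scale_weights = w, n_scales = as.integer(n_scales),
                 window_size = as.integer(window_size),
                 window_sigma = window_sigma,
                 c1 = (0.01 * dynamic_range)^2,
                 c2 = (0.03 * dynamic_range)^2,
                 c3 = (0.03 * dynamic_range)^2 / 2,
                 dynamic_range = dynamic_range),
            class = "msssim_params")
}

#' The fixed high-pass gradient kernel
#'
#' A 3x3 zero-sum kernel (rows -1, 0, +1) applied by cross-correlation in
#' place of the Sobel operator; constants produce zero response.
#'
#' @return A 3x3 numeric matrix.
#' @export
gradient_kernel <- function() {
  rbind(c(-1, -1, -1), c(0, 0, 0), c(1, 1, 1))
}

# Coerce a matrix / (H,W,N) / (H,W,C,N) input to the tape layout (H,W,C,N).
.as_batch <- function(x) {
  if (is.matrix(x)) return(array(x, c(dim(x), 1L, 1L)))
  d <- dim(x)
  if (length(d) == 3L) return(array(x, c(d[1], d[2], 1L, d[3])))
  if (length(d) == 4L) return(x)
  stop("expected a matrix or an (H, W, N) / (H, W, C, N) array", call. = FALSE)
}

.check_same_shape <- function(a, b, what) {
  if (!identical(dim(.as_batch(a)), dim(.as_batch(b))))
    stop(what, ": images must have identical shape", call. = FALSE)
}

# --- tape builders ----------------------------------------------------------

tl_mse <- function(tp, a, b) {
  d <- tp_sub(tp, a, b)
  tp_mean(tp, tp_mul(tp, d, d))
}

tl_gradient <- function(tp, a, b, kernel = gradient_kernel()) {
  k <- tp_leaf(tp, array(kernel, c(dim(kernel), 1L, 1L)))
  zb <- tp_leaf(tp, numeric(1))
  ga <- tp_conv2d(tp, a, k, zb, 0L)
  gb <- tp_conv2d(tp, b, k, zb, 0L)
  tl_mse(tp, ga, gb)
}

# 1 - MS-SSIM. Per scale j < M the mean contrast-structure statistic is
# raised to its exponent; the coarsest scale contributes mean(l * cs) (the
# luminance term enters only there). Scale means are floored at a small
# positive value so fractional powers stay defined.
tl_msssim <- function(tp, a, b, p = msssim_params(), floor_eps = 1e-6) {
  d <- dim(tp_val(tp, a))
  need <- p$window_size * 2L^(p$n_scales - 1L)
  if (min(d[1], d[2]) < need)
    stop(sprintf(paste0("ms_ssim_loss: a %dx%d image cannot support %d scales ",
                        "with a %d-pixel window; reduce n_scales"),
                 d[1], d[2], p$n_scales, p$window_size), call. = FALSE)
  gk <- tp_leaf(tp, .gauss_kernel(p$window_size, p$window_sigma))
  zb <- tp_leaf(tp, numeric(1))
  msssim <- NULL
  for (j in seq_len(p$n_scales)) {
    mu_x <- tp_conv2d(tp, a, gk, zb, 0L)
    mu_y <- tp_conv2d(tp, b, gk, zb, 0L)
    sxx <- tp_sub(tp, tp_conv2d(tp, tp_mul(tp, a, a), gk, zb, 0L),
                  tp_mul(tp, mu_x, mu_x))
    syy <- tp_sub(tp, tp_conv2d(tp, tp_mul(tp, b, b), gk, zb, 0L),
                  tp_mul(tp, mu_y, mu_y))
    sxy <- tp_sub(tp, tp_conv2d(tp, tp_mul(tp, a, b), gk, zb, 0L),
                  tp_mul(tp, mu_x, mu_y))
    cs <- tp_div(tp, tp_add_const(tp, tp_mul_const(tp, sxy, 2), p$c2),
                 tp_add_const(tp, tp_add(tp, sxx, syy), p$c2))
    if (j < p$n_scales) {
      term <- tp_clamp_min(tp, tp_mean(tp, cs), floor_eps)
    } else {
      lum <- tp_div(tp,
                    tp_add_const(tp, tp_mul_const(tp, tp_mul(tp, mu_x, mu_y), 2), p$c1),
                    tp_add_const(tp, tp_add(tp, tp_mul(tp, mu_x, mu_x),
                                            tp_mul(tp, mu_y, mu_y)), p$c1))
      term <- tp_clamp_min(tp, tp_mean(tp, tp_mul(tp, lum, cs)), floor_eps)
    }
    pw <- tp_pow_const(tp, term, p$scale_weights[j])
    msssim <- if (is.null(msssim)) pw else tp_mul(tp, msssim, pw)
    if (j < p$n_scales) {
      a <- tp_avgpool2(tp, a)
      b <- tp_avgpool2(tp, b)
    }
  }
  tp_add_const(tp, tp_mul_const(tp, msssim, -1), 1)
}

# Weighted combination; returns scalar node ids for the total and each
# unweighted term.
tl_composite <- function(tp, a, b, w = loss_weights(), p = msssim_params(),
                         kernel = gradient_kernel()) {
  t_mse <- tl_mse(tp, a, b)
  t_ms <- tl_msssim(tp, a, b, p)
  t_gr <- tl_gradient(tp, a, b, kernel)
  total <- tp_add(tp, tp_add(tp, tp_mul_const(tp, t_mse, w$lambda1),
                             tp_mul_const(tp, t_ms, w$lambda2)),
                  tp_mul_const(tp, t_gr, w$lambda3))
  list(total = total, mse = t_mse, msssim = t_ms, grad = t_gr)
}

# --- numeric API ------------------------------------------------------------

.eval_pair_loss <- function(pred, target, build) {
  tp <- tape_new()
  a <- tp_leaf(tp, .as_batch(pred))
  b <- tp_leaf(tp, .as_batch(target))
  as.numeric(tp_val(tp, build(tp, a, b)))
}

#' Mean squared error loss
#'
#' Mean of squared pixel differences over all pixels and batch images.
#'
#' @param pred,target Matrices or (H, W, C, N) arrays of identical shape.
#' @return A non-negative scalar.
#' @export
mse_loss <- function(pred, target) {
  .check_same_shape(pred, target, "mse_loss")
  .eval_pair_loss(pred, target, function(tp, a, b) tl_mse(tp, a, b))
}

#' MS-SSIM loss
#'
#' Returns `1 - MS-SSIM(pred, target)`: multi-scale structural similarity
#' with Gaussian local statistics, 2x2 average-pooling between dyadic scales,
#' contrast/structure statistics at every scale and the luminance term at the
#' coarsest scale only.
#'
#' @param pred,target Matrices or arrays of identical shape.
#' @param params A [msssim_params()].
#' @return Scalar in `[0, 1]`; 0 when the images are identical.
#' @export
ms_ssim_loss <- function(pred, target, params = msssim_params()) {
  .check_same_shape(pred, target, "ms_ssim_loss")
  .eval_pair_loss(pred, target, function(tp, a, b) tl_msssim(tp, a, b, params))
}

#' Gradient loss
#'
#' Cross-correlates both images with the fixed high-pass kernel
#' (valid region, no padding) and returns the MSE of the two response maps.
#'
#' @param pred,target Matrices or arrays of identical shape, min side >= 3.
#' @param kernel A 3x3 numeric matrix, by default [gradient_kernel()].
#' @return A non-negative scalar; 0 for identical or both-constant images.
#' @export
gradient_loss <- function(pred, target, kernel = gradient_kernel()) {
  .check_same_shape(pred, target, "gradient_loss")
  .eval_pair_loss(pred, target,
                  function(tp, a, b) tl_gradient(tp, a, b, kernel))
}

#' Composite denoising loss
#'
#' `lambda1 * MSE + lambda2 * (1 - MS-SSIM) + lambda3 * L_grad`, with the
#' unweighted per-term breakdown for logging.
#'
#' @param pred,target Matrices or arrays of identical shape.
#' @param weights A [loss_weights()].
#' @param params A [msssim_params()].
#' @param kernel The gradient-loss kernel.
#' @return A list with `total` and `terms` (named: mse, msssim, grad).
#' @export
composite_loss <- function(pred, target, weights = loss_weights(),
                           params = msssim_params(),
                           kernel = gradient_kernel()) {
  .check_same_shape(pred, target, "composite_loss")
  tp <- tape_new()
  a <- tp_leaf(tp, .as_batch(pred))
  b <- tp_leaf(tp, .as_batch(target))
  parts <- tl_composite(tp, a, b, weights, params, kernel)
  list(total = as.numeric(tp_val(tp, parts$total)),
       terms = c(mse = as.numeric(tp_val(tp, parts$mse)),
                 msssim = as.numeric(tp_val(tp, parts$msssim)),
                 grad = as.numeric(tp_val(tp, parts$grad))))
}

#' Two-pass total loss
#'
#' The training objective of the mask-guided schedule: the sum of the
#' original-pass and correction-pass losses.
#'
#' @param original,correction Finite scalars.
#' @return Their sum.
#' @export
total_loss <- function(original, correction) {
  if (!is.finite(original) || !is.finite(correction))
    stop("total_loss: inputs must be finite", call. = FALSE)
  original + correction
}
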