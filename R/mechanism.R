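# The mask-guided correction-loss mechanism and the two-phase training
# schedule. One mechanism step: denoise the low-dose image (I1), form the
# difference image D1 = N1 - I1 against the normal-dose image, threshold
# |D1| into a binary mask (1 = poorly restored pixel, retained), zero out
# the well-restored regions of both images (L2 = L1 * mask, N2 = N1 * mask),
# denoise the filtered low-dose image (I2), and minimize
# composite(I1, N1) + composite(I2, N2). The mask is recomputed every step
# from the current model and treated as a constant during differentiation.

#' Mechanism configuration
#'
#' @param threshold Mask threshold on the normalized intensity scale. The
#'   reference choices are 0.04 (chest regime) and 0.004 (brain regime).
#' @param enabled If `FALSE` the second phase trains exactly like the first.
#' @param pretrain_epochs Epochs of phase 1 (no mechanism; default 80).
#' @param mechanism_epochs Additional epochs of phase 2 (default 160).
#' @return An object of class `mechanism_config`.
#' @export
mechanism_config <- function(threshold = 0.04, enabled = TRUE,
                             pretrain_epochs = 80L, mechanism_epochs = 160L) {
  if (threshold < 0)
    stop("mechanism_config: threshold must be non-negative", call. = FALSE)
  if (pretrain_epochs < 0 || mechanism_epochs < 0)
    stop("mechanism_config: epoch counts must be non-negative", call. = FALSE)
  structure(list(threshold = as.numeric(threshold), enabled = isTRUE(enabled),
                 pretrain_epochs = as.integer(pretrain_epochs),
                 mechanism_epochs = as.integer(mechanism_epochs)),
            class = "mechanism_config")
}

#' Optimizer and schedule configuration
#'
#' Defaults mirror the reference training setup: batch size 8, Adam with
#' betas (0.9, 0.999), learning rate 1e-4 dropping to 5e-5 at epoch 130 of
#' the mechanism phase.
#'
#' @param batch_size Images per optimization step.
#' @param lr Initial learning rate.
#' @param lr_drop_epoch Epoch (counted within phase 2) at which the rate
#'   drops; `Inf` disables the drop.
#' @param lr_after_drop Learning rate from `lr_drop_epoch` on.
#' @param beta1,beta2,epsilon Adam moment decay rates and stabilizer.
#' @param shuffle Reshuffle the pair order every epoch.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 8L, lr = 1e-4, lr_drop_epoch = 130,
                         lr_after_drop = 5e-5, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-8, shuffle = TRUE) {
  if (batch_size < 1) stop("train_config: batch_size must be >= 1", call. = FALSE)
  if (lr <= 0 || lr_after_drop <= 0)
    stop("train_config: learning rates must be positive", call. = FALSE)
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 lr_drop_epoch = lr_drop_epoch, lr_after_drop = lr_after_drop,
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 shuffle = isTRUE(shuffle)),
            class = "train_config")
}

#' Difference image
#'
#' Pixelwise `ndct - denoised` (N1 minus I1).
#'
#' @param ndct,denoised Matrices or arrays of identical shape.
#' @return Array of the same shape.
#' @export
difference_image <- function(ndct, denoised) {
  if (!identical(dim(.as_batch(ndct)), dim(.as_batch(denoised))))
    stop("difference_image: images must have identical shape", call. = FALSE)
  ndct - denoised
}

#' Threshold a difference image into a binary mask
#'
#' A pixel is retained (mask 1) where `|diff| > threshold`: both over- and
#' under-estimated regions count as poorly restored; ties are filtered.
#'
#' @param diff Difference image.
#' @param threshold Non-negative scalar.
#' @return Binary array of the same shape (values 0/1).
#' @export
make_mask <- function(diff, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0)
    stop("make_mask: threshold must be a non-negative scalar", call. = FALSE)
  (abs(diff) > threshold) * 1
}

#' Apply a binary mask elementwise
#'
#' @param image Image or batch.
#' @param mask Mask of the same shape; filtered pixels become exactly 0.
#' @return Masked image.
#' @export
apply_mask <- function(image, mask) {
  if (!identical(dim(.as_batch(image)), dim(.as_batch(mask))))
    stop("apply_mask: image and mask must have identical shape", call. = FALSE)
  image * mask
}

# Stack a list of image_pair objects into (H, W, 1, N) arrays.
.stack_pairs <- function(pairs) {
  n <- length(pairs)
  d <- dim(pairs[[1]]$ldct)
  L <- array(0, c(d[1], d[2], 1L, n))
  N <- array(0, c(d[1], d[2], 1L, n))
  for (i in seq_len(n)) {
    L[, , 1L, i] <- pairs[[i]]$ldct
    N[, , 1L, i] <- pairs[[i]]$ndct
  }
  list(L = L, N = N)
}

#' One mechanism step
#'
#' Executes the full two-pass procedure on a pair (or batch) without
#' updating the model, returning every intermediate of the mechanism plus
#' the loss terms.
#'
#' @param model A [build_model()] result; its `mode` controls batch-norm
#'   behaviour.
#' @param pair An [image_pair()] or a list of them (stacked into one batch).
#' @param mech A [mechanism_config()].
#' @param weights,params,kernel Loss context as in [composite_loss()].
#' @return A list: `denoised` (I1), `difference` (D1), `mask`,
#'   `filtered_ldct` (L2), `filtered_ndct` (N2), `filtered_denoised` (I2),
#'   `original_loss`, `correction_loss`, `total`.
#' @export
mechanism_step <- function(model, pair, mech = mechanism_config(),
                           weights = loss_weights(), params = msssim_params(),
                           kernel = gradient_kernel()) {
  pairs <- if (inherits(pair, "image_pair")) list(pair) else pair
  st <- .stack_pairs(pairs)
  training <- identical(model$mode, "train")
  tp <- tape_new()
  L1 <- tp_leaf(tp, st$L)
  N1 <- tp_leaf(tp, st$N)
  f1 <- .model_forward(tp, model, L1, training)
  I1 <- tp_val(tp, f1$out)
  orig <- tl_composite(tp, f1$out, N1, weights, params, kernel)
  D1 <- st$N - I1
  mask <- make_mask(D1, mech$threshold)
  L2v <- st$L * mask
  N2v <- st$N * mask
  L2 <- tp_leaf(tp, L2v)
  N2 <- tp_leaf(tp, N2v)
  f2 <- .model_forward(tp, model, L2, training)
  corr <- tl_composite(tp, f2$out, N2, weights, params, kernel)
  list(denoised = I1,
       difference = D1,
       mask = mask,
       filtered_ldct = L2v,
       filtered_ndct = N2v,
       filtered_denoised = tp_val(tp, f2$out),
       original_loss = as.numeric(tp_val(tp, orig$total)),
       correction_loss = as.numeric(tp_val(tp, corr$total)),
       total = as.numeric(tp_val(tp, orig$total)) +
         as.numeric(tp_val(tp, corr$total)))
}

#' Group pairs into shuffled batches
#'
#' Every pair appears exactly once; order is a deterministic function of the
#' shuffle seed.
#'
#' @param pairs List of [image_pair()] objects.
#' @param batch_size Maximum batch size.
#' @param shuffle_seed Integer seed; `NULL` keeps the input order.
#' @return List of lists of pairs (possibly empty).
#' @export
batch_pairs <- function(pairs, batch_size, shuffle_seed = NULL) {
  if (batch_size < 1) stop("batch_pairs: batch_size must be >= 1", call. = FALSE)
  n <- length(pairs)
  if (n == 0) return(list())
  ord <- if (is.null(shuffle_seed)) seq_len(n) else
    with_seed(shuffle_seed, sample.int(n))
  split(pairs[ord], ceiling(seq_len(n) / batch_size))
}

# --- Adam -------------------------------------------------------------------

.adam_new <- function() new.env(parent = emptyenv())

.adam_update <- function(state, name, par, grad, lr) {
  key_m <- paste0(name, ".m"); key_v <- paste0(name, ".v")
  m <- if (is.null(state[[key_m]])) grad * 0 else state[[key_m]]
  v <- if (is.null(state[[key_v]])) grad * 0 else state[[key_v]]
  m <- state$beta1 * m + (1 - state$beta1) * grad
  v <- state$beta2 * v + (1 - state$beta2) * grad^2
  state[[key_m]] <- m
  state[[key_v]] <- v
  mhat <- m / (1 - state$beta1^state$t)
  vhat <- v / (1 - state$beta2^state$t)
  par - lr * mhat / (sqrt(vhat) + state$epsilon)
}

# One optimization step on a stacked batch. Returns the updated model and the
# loss breakdown. With `mechanism = FALSE` only the original pass runs.
.train_step <- function(model, Lb, Nb, mechanism, threshold, weights, params,
                        kernel, tc, lr, adam, bn_momentum = 0.1) {
  tp <- tape_new()
  L1 <- tp_leaf(tp, Lb)
  N1 <- tp_leaf(tp, Nb)
  f1 <- .model_forward(tp, model, L1, training = TRUE)
  orig <- tl_composite(tp, f1$out, N1, weights, params, kernel)
  ids2 <- NULL
  if (mechanism) {
    mask <- make_mask(Nb - tp_val(tp, f1$out), threshold)
    L2 <- tp_leaf(tp, Lb * mask)
    N2 <- tp_leaf(tp, Nb * mask)
    f2 <- .model_forward(tp, model, L2, training = TRUE)
    corr <- tl_composite(tp, f2$out, N2, weights, params, kernel)
    loss <- tp_add(tp, orig$total, corr$total)
    ids2 <- f2$ids
  } else {
    loss <- orig$total
  }
  grads <- tape_backward(tp, loss)
  # Gradients of a parameter are summed over the two passes (each pass holds
  # its own leaf for the same array).
  adam$t <- (if (is.null(adam$t)) 0L else adam$t) + 1L
  for (nm in names(f1$ids)) {
    g <- grads[[f1$ids[[nm]]]]
    if (!is.null(ids2) && !is.null(grads[[ids2[[nm]]]]))
      g <- g + grads[[ids2[[nm]]]]
    if (is.null(g)) next
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    tgt <- parts[1]; fld <- parts[2]
    if (fld %in% c("w", "b")) {
      model$params[[tgt]][[fld]] <-
        .adam_update(adam, nm, model$params[[tgt]][[fld]], g, lr)
    } else {
      model$bn[[tgt]][[fld]] <-
        .adam_update(adam, nm, model$bn[[tgt]][[fld]], g, lr)
    }
  }
  # Running statistics update once per step, from the first pass only.
  for (nm in ls(f1$bn_stats)) {
    s <- f1$bn_stats[[nm]]
    model$bn[[nm]]$mean <- (1 - bn_momentum) * model$bn[[nm]]$mean +
      bn_momentum * s$mean
    model$bn[[nm]]$var <- (1 - bn_momentum) * model$bn[[nm]]$var +
      bn_momentum * s$var
  }
  list(model = model,
       loss = as.numeric(tp_val(tp, loss)),
       original = as.numeric(tp_val(tp, orig$total)),
       mse = as.numeric(tp_val(tp, orig$mse)),
       msssim = as.numeric(tp_val(tp, orig$msssim)),
       grad = as.numeric(tp_val(tp, orig$grad)))
}

.adam_pass_tc <- function(tc, state) {
  state$beta1 <- tc$beta1; state$beta2 <- tc$beta2; state$epsilon <- tc$epsilon
  state
}

#' Train a model with the two-phase schedule
#'
#' Phase 1 minimizes the composite loss of the plain pass for
#' `pretrain_epochs` epochs; phase 2 adds the mask-guided correction pass
#' for `mechanism_epochs` further epochs (or continues plain training when
#' the mechanism is disabled). Adam throughout; the learning rate drops at
#' `lr_drop_epoch` of phase 2. Fully deterministic given `seed`.
#'
#' @param model A [build_model()] result.
#' @param pairs Non-empty list of [image_pair()] objects.
#' @param mech A [mechanism_config()].
#' @param tc A [train_config()].
#' @param weights,params,kernel Loss context as in [composite_loss()].
#' @param val_pairs Optional held-out pairs; PSNR/SSIM of the denoised
#'   output are logged per epoch.
#' @param seed Integer seed controlling batch shuffling.
#' @param log_csv Optional path for the per-epoch CSV log.
#' @param verbose Print one line per epoch.
#' @return A list: `model` (trained, eval mode) and `log` (data frame with
#'   one row per epoch).
#' @export
train <- function(model, pairs, mech = mechanism_config(),
                  tc = train_config(), weights = loss_weights(),
                  params = msssim_params(), kernel = gradient_kernel(),
                  val_pairs = NULL, seed = 1L, log_csv = NULL,
                  verbose = FALSE) {
  if (length(pairs) == 0)
    stop("train: the training dataset is empty", call. = FALSE)
  model$mode <- "train"
  adam <- .adam_pass_tc(tc, .adam_new())
  log <- list()
  row <- 0L
  run_epoch <- function(phase, epoch, lr, mechanism) {
    shuffle_seed <- if (tc$shuffle)
      as.integer((seed * 1000L + phase * 500L + epoch) %% .Machine$integer.max)
    else NULL
    batches <- batch_pairs(pairs, tc$batch_size, shuffle_seed)
    acc <- c(loss = 0, original = 0, mse = 0, msssim = 0, grad = 0)
    for (b in batches) {
      st <- .stack_pairs(b)
      res <- .train_step(model, st$L, st$N, mechanism, mech$threshold,
                         weights, params, kernel, tc, lr, adam)
      model <<- res$model
      acc <- acc + c(res$loss, res$original, res$mse, res$msssim, res$grad)
    }
    acc <- acc / length(batches)
    val_psnr <- NA_real_; val_ssim <- NA_real_
    if (!is.null(val_pairs)) {
      ev <- evaluate(set_mode(model, "eval"), val_pairs)
      val_psnr <- unname(ev$mean["psnr_denoised"])
      val_ssim <- unname(ev$mean["ssim_denoised"])
    }
    row <<- row + 1L
    log[[row]] <<- data.frame(phase = phase, epoch = epoch, lr = lr,
                              loss_total = acc[1], loss_original = acc[2],
                              loss_mse = acc[3], loss_msssim = acc[4],
                              loss_grad = acc[5], val_psnr = val_psnr,
                              val_ssim = val_ssim)
    if (verbose)
      message(sprintf("phase %d epoch %3d  loss %.5f  val PSNR %s",
                      phase, epoch, acc[1],
                      if (is.na(val_psnr)) "-" else sprintf("%.2f", val_psnr)))
  }
  for (epoch in seq_len(mech$pretrain_epochs))
    run_epoch(1L, epoch, tc$lr, mechanism = FALSE)
  for (epoch in seq_len(mech$mechanism_epochs)) {
    lr <- if (epoch >= tc$lr_drop_epoch) tc$lr_after_drop else tc$lr
    run_epoch(2L, epoch, lr, mechanism = mech$enabled)
  }
  log <- if (row > 0) do.call(rbind, log) else
    data.frame(phase = integer(0), epoch = integer(0))
  rownames(log) <- NULL
  if (!is.null(log_csv)) utils::write.csv(log, log_csv, row.names = FALSE)
  list(model = set_mode(model, "eval"), log = log)
}

#' Scan mask thresholds on a pretrained model
#'
#' For each threshold, denoises every pair with the current model and
#' reports the fraction of pixels the mask would retain, plus per-image
#' summary statistics. The suggested threshold is the smallest grid value
#' whose retained fraction falls inside (or below the top of) the target
#' band, mirroring the guidance to filter most low-frequency area while
#' keeping the subtle structures.
#'
#' @param model A [build_model()] result (typically phase-1 pretrained).
#' @param pairs List of [image_pair()] objects.
#' @param thresholds Non-empty numeric vector; the reference grid is
#'   `c(0.01, 0.04, 0.07, 0.10)`.
#' @param target_band Retained-fraction band used for the suggestion.
#' @return A list: `table` (data frame threshold / retained_fraction /
#'   mean & sd of per-image fractions) and `suggested` (scalar or `NA`).
#' @export
threshold_scan <- function(model, pairs, thresholds = c(0.01, 0.04, 0.07, 0.10),
                           target_band = c(0.05, 0.20)) {
  if (length(thresholds) == 0)
    stop("threshold_scan: empty threshold list", call. = FALSE)
  model <- set_mode(model, "eval")
  diffs <- lapply(pairs, function(p) p$ndct - denoise(model, p$ldct))
  rows <- lapply(sort(thresholds), function(t) {
    fr <- vapply(diffs, function(d) mean(abs(d) > t), numeric(1))
    data.frame(threshold = t, retained_fraction = mean(fr),
               min_fraction = min(fr), max_fraction = max(fr))
  })
  tab <- do.call(rbind, rows)
  ok <- tab$retained_fraction <= target_band[2]
  list(table = tab,
       suggested = if (any(ok)) tab$threshold[which(ok)[1]] else NA_real_)
}
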