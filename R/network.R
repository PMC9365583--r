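# The denoising network: a DenseNet-with-deconvolution encoder/decoder. A
# 7x7 stem is followed by n_levels encoder stages (2x2 max-pool + one
# improved residual dense block) and n_levels decoder stages (x2 nearest
# upsampling, concatenation with the equal-scale encoder features, then two
# deconvolution layers each with ReLU + batch normalization), closed by a
# 1x1 single-channel head. "Deconvolution" here is stride-1 transposed
# convolution, which preserves spatial size and is algebraically an ordinary
# convolution; all spatial resizing happens in the dedicated pool/upsample
# layers.

#' Network configuration
#'
#' Defaults give the full-size network: 16-channel stem, improved residual
#' dense blocks (IRDB) of four 16-channel dense layers whose 80-channel
#' concatenation is fused by a 1x1 layer, four scales, 32-channel first
#' decoder deconvolutions. All sizes scale down for tests.
#'
#' @param stem_channels Channels of the 7x7 stem convolution.
#' @param growth_channels Channels added by each dense layer.
#' @param dense_layers_per_block Dense 3x3 layers per block.
#' @param bottleneck_channels Width of the dense concatenation fed to the 1x1
#'   local-fusion layer. Computed as
#'   `stem_channels + dense_layers_per_block * growth_channels` when `NULL`;
#'   if supplied it must equal that value.
#' @param n_levels Encoder/decoder scale count; inputs must be divisible by
#'   `2^n_levels`.
#' @param decoder_channels Channels of each decoder's first (5x5)
#'   deconvolution; the second (1x1) returns to `stem_channels`.
#' @param use_irdb If `FALSE` the enhanced-residual sub-block and the block's
#'   identity skip are dropped, leaving the plain dense block of the original
#'   DenseNet-deconvolution network (ablation toggle).
#' @param init_std Standard deviation of the zero-mean Gaussian weight
#'   initialization (variance `init_std^2`).
#' @return An object of class `network_config`.
#' @export
network_config <- function(stem_channels = 16L, growth_channels = 16L,
                           dense_layers_per_block = 4L,
                           bottleneck_channels = NULL, n_levels = 4L,
                           decoder_channels = 32L, use_irdb = TRUE,
                           init_std = 0.1) {
  counts <- c(stem_channels, growth_channels, dense_layers_per_block,
              n_levels, decoder_channels)
  if (any(counts < 1))
    stop("network_config: all counts must be at least 1", call. = FALSE)
  dense_out <- stem_channels + dense_layers_per_block * growth_channels
  if (is.null(bottleneck_channels)) bottleneck_channels <- dense_out
  if (bottleneck_channels != dense_out)
    stop(sprintf(paste0("network_config: bottleneck_channels (%d) must equal ",
                        "stem_channels + dense_layers_per_block * ",
                        "growth_channels (%d)"),
                 bottleneck_channels, dense_out), call. = FALSE)
  if (init_std <= 0)
    stop("network_config: init_std must be positive", call. = FALSE)
  structure(list(stem_channels = as.integer(stem_channels),
                 growth_channels = as.integer(growth_channels),
                 dense_layers_per_block = as.integer(dense_layers_per_block),
                 bottleneck_channels = as.integer(bottleneck_channels),
                 n_levels = as.integer(n_levels),
                 decoder_channels = as.integer(decoder_channels),
                 use_irdb = isTRUE(use_irdb),
                 init_std = as.numeric(init_std)),
            class = "network_config")
}

.conv_init <- function(kh, kw, ci, co, std) {
  list(w = array(stats::rnorm(kh * kw * ci * co, 0, std), c(kh, kw, ci, co)),
       b = numeric(co))
}

.bn_init <- function(c) {
  list(gamma = rep(1, c), beta = rep(0, c), mean = rep(0, c), var = rep(1, c))
}

#' Build a denoising model
#'
#' Allocates and initializes all parameters: convolution and deconvolution
#' weights from a zero-mean Gaussian with standard deviation
#' `cfg$init_std`, zero biases, batch-norm scale 1 / shift 0. Deterministic
#' given the seed.
#'
#' @param cfg A [network_config()].
#' @param seed Integer RNG seed for the initialization.
#' @return An object of class `denoising_model` with fields `config`,
#'   `params` (named list), `bn` (running statistics) and `mode`
#'   (`"train"` or `"eval"`).
#' @export
build_model <- function(cfg = network_config(), seed = 1L) {
  stopifnot(inherits(cfg, "network_config"))
  sc <- cfg$stem_channels
  params <- list()
  bn <- list()
  with_seed(seed, {
    params$stem <- .conv_init(7, 7, 1, sc, cfg$init_std)
    for (lvl in seq_len(cfg$n_levels)) {
      key <- function(part) sprintf("enc%d_%s", lvl, part)
      cin <- sc
      for (j in seq_len(cfg$dense_layers_per_block)) {
        params[[key(sprintf("dense%d", j))]] <-
          .conv_init(3, 3, cin + (j - 1L) * cfg$growth_channels,
                     cfg$growth_channels, cfg$init_std)
      }
      params[[key("fusion")]] <-
        .conv_init(1, 1, cfg$bottleneck_channels, cin, cfg$init_std)
      if (cfg$use_irdb) {
        params[[key("eres1")]] <- .conv_init(3, 3, cin, cin, cfg$init_std)
        params[[key("eres2")]] <- .conv_init(3, 3, cin, cin, cfg$init_std)
      }
    }
    for (lvl in seq_len(cfg$n_levels)) {
      key <- function(part) sprintf("dec%d_%s", lvl, part)
      params[[key("deconv1")]] <-
        .conv_init(5, 5, 2L * sc, cfg$decoder_channels, cfg$init_std)
      bn[[key("bn1")]] <- .bn_init(cfg$decoder_channels)
      params[[key("deconv2")]] <-
        .conv_init(1, 1, cfg$decoder_channels, sc, cfg$init_std)
      bn[[key("bn2")]] <- .bn_init(sc)
    }
    params$head <- .conv_init(1, 1, sc, 1, cfg$init_std)
  })
  structure(list(config = cfg, params = params, bn = bn, mode = "train"),
            class = "denoising_model")
}

#' Switch a model between train and eval mode
#'
#' In eval mode batch normalization uses the stored running statistics and
#' the forward pass is a deterministic function of the input.
#'
#' @param model A [build_model()] result.
#' @param mode `"train"` or `"eval"`.
#' @return The model with the mode set.
#' @export
set_mode <- function(model, mode = c("train", "eval")) {
  model$mode <- match.arg(mode)
  model
}

# Build the forward graph on a tape. Parameter leaves require gradients only
# when `training`. Returns the output node, the parameter leaf ids (named
# like model$params with $w / $b, and BN $gamma / $beta), and an environment
# collecting batch statistics of every BN layer when training.
.model_forward <- function(tp, model, x_id, training, momentum = 0.1) {
  cfg <- model$config
  P <- model$params
  ids <- list()
  leaf <- function(name, part) {
    id <- tp_leaf(tp, P[[name]][[part]], requires_grad = training)
    ids[[paste(name, part, sep = ".")]] <<- id
    id
  }
  bn_stats <- new.env(parent = emptyenv())
  conv <- function(x, name, pad) {
    tp_conv2d(tp, x, leaf(name, "w"), leaf(name, "b"), pad)
  }
  bnorm <- function(x, name) {
    g <- tp_leaf(tp, model$bn[[name]]$gamma, requires_grad = training)
    b <- tp_leaf(tp, model$bn[[name]]$beta, requires_grad = training)
    ids[[paste(name, "gamma", sep = ".")]] <<- g
    ids[[paste(name, "beta", sep = ".")]] <<- b
    st <- new.env(parent = emptyenv())
    out <- tp_batchnorm(tp, x, g, b, model$bn[[name]]$mean,
                        model$bn[[name]]$var, training, state_out = st)
    if (training) bn_stats[[name]] <- list(mean = st$mean, var = st$var)
    out
  }
  irdb <- function(x, lvl) {
    key <- function(part) sprintf("enc%d_%s", lvl, part)
    feats <- x
    for (j in seq_len(cfg$dense_layers_per_block)) {
      d <- tp_relu(tp, conv(feats, key(sprintf("dense%d", j)), 1L))
      feats <- tp_concat_c(tp, feats, d)
    }
    fused <- conv(feats, key("fusion"), 0L)
    if (!cfg$use_irdb) return(fused)
    e <- conv(tp_relu(tp, conv(fused, key("eres1"), 1L)), key("eres2"), 1L)
    tp_add(tp, x, tp_add(tp, fused, e))
  }
  stem <- tp_relu(tp, conv(x_id, "stem", 3L))
  skips <- list(stem)
  feat <- stem
  for (lvl in seq_len(cfg$n_levels)) {
    feat <- irdb(tp_maxpool2(tp, feat), lvl)
    if (lvl < cfg$n_levels) skips[[lvl + 1L]] <- feat
  }
  for (lvl in seq_len(cfg$n_levels)) {
    key <- function(part) sprintf("dec%d_%s", lvl, part)
    up <- tp_upsample2(tp, feat)
    cat_in <- tp_concat_c(tp, up, skips[[cfg$n_levels - lvl + 1L]])
    d1 <- bnorm(tp_relu(tp, conv(cat_in, key("deconv1"), 2L)), key("bn1"))
    feat <- bnorm(tp_relu(tp, conv(d1, key("deconv2"), 0L)), key("bn2"))
  }
  out <- conv(feat, "head", 0L)
  list(out = out, ids = ids, bn_stats = bn_stats)
}

.check_divisible <- function(d, n_levels) {
  div <- 2L^n_levels
  if (d[1] %% div != 0L || d[2] %% div != 0L)
    stop(sprintf("forward: input %dx%d must have height and width divisible by %d",
                 d[1], d[2], div), call. = FALSE)
}

#' Forward pass
#'
#' Runs the network on a batch. In eval mode the result is a deterministic
#' function of the input; in train mode batch statistics are used by the
#' batch-norm layers (but running statistics are only updated by the
#' training loop, not here).
#'
#' @param model A [build_model()] result.
#' @param batch Matrix, `(H, W, N)` or `(H, W, 1, N)` array with spatial
#'   dims divisible by `2^n_levels`.
#' @return Denoised batch with the same shape as the (coerced) input.
#' @export
forward <- function(model, batch) {
  x <- .as_batch(batch)
  .check_divisible(dim(x), model$config$n_levels)
  tp <- tape_new()
  xid <- tp_leaf(tp, x)
  f <- .model_forward(tp, model, xid, training = identical(model$mode, "train"))
  out <- tp_val(tp, f$out)
  if (is.matrix(batch)) matrix(out, nrow(batch), ncol(batch)) else out
}

#' Denoise a single slice
#'
#' Eval-mode convenience wrapper around [forward()].
#'
#' @param model A [build_model()] result.
#' @param img Numeric matrix.
#' @return Denoised matrix of the same size.
#' @export
denoise <- function(model, img) {
  forward(set_mode(model, "eval"), as.matrix(img))
}

#' One improved-residual-dense-block forward pass
#'
#' Exposes a single encoder block for inspection: the dense 3x3 chain (each
#' layer sees the concatenation of the block input and all previous outputs,
#' no batch normalization), the 1x1 local fusion back to the block's channel
#' count, the enhanced-residual sub-block (two 3x3 convolutions with ReLU
#' between and a local skip), and the identity skip from block input to
#' output.
#'
#' @param model A [build_model()] result.
#' @param features `(H, W, C, N)` array with `C = stem_channels`.
#' @param level Encoder level whose block weights to use.
#' @return Array of the same shape as `features`.
#' @export
irdb_forward <- function(model, features, level = 1L) {
  d <- dim(features)
  if (is.null(d) || length(d) != 4L || d[3] != model$config$stem_channels)
    stop(sprintf("irdb_forward: features must be (H, W, %d, N)",
                 model$config$stem_channels), call. = FALSE)
  tp <- tape_new()
  xid <- tp_leaf(tp, features)
  cfg <- model$config
  P <- model$params
  key <- function(part) sprintf("enc%d_%s", level, part)
  conv <- function(x, name, pad) {
    tp_conv2d(tp, x, tp_leaf(tp, P[[name]]$w), tp_leaf(tp, P[[name]]$b), pad)
  }
  feats <- xid
  for (j in seq_len(cfg$dense_layers_per_block))
    feats <- tp_concat_c(tp, feats,
                         tp_relu(tp, conv(feats, key(sprintf("dense%d", j)), 1L)))
  fused <- conv(feats, key("fusion"), 0L)
  out <- if (cfg$use_irdb) {
    e <- conv(tp_relu(tp, conv(fused, key("eres1"), 1L)), key("eres2"), 1L)
    tp_add(tp, xid, tp_add(tp, fused, e))
  } else fused
  tp_val(tp, out)
}

#' Layer census and parameter count
#'
#' @param model A [build_model()] result.
#' @return A list with the counts of each layer kind, the head geometry and
#'   the total trainable parameter count.
#' @export
layer_census <- function(model) {
  cfg <- model$config
  n_par <- sum(vapply(model$params, function(p) length(p$w) + length(p$b),
                      numeric(1))) +
    sum(vapply(model$bn, function(s) length(s$gamma) + length(s$beta),
               numeric(1)))
  list(stem_convolutions = 1L,
       stem_kernel = c(7L, 7L),
       max_pools = cfg$n_levels,
       irdbs = cfg$n_levels,
       upsamplings = cfg$n_levels,
       deconvolutions = 2L * cfg$n_levels,
       head_kernel = c(1L, 1L),
       head_channels = 1L,
       n_parameters = as.integer(n_par))
}

#' @export
print.denoising_model <- function(x, ...) {
  cen <- layer_census(x)
  cat(sprintf(paste0("<denoising_model> %d levels, %s mode\n",
                     "  stem 7x7 (%d ch) | %d max-pools | %d %s | ",
                     "%d upsamplings | %d deconvolutions | 1x1 head\n",
                     "  parameters: %d\n"),
              x$config$n_levels, x$mode, x$config$stem_channels,
              cen$max_pools, cen$irdbs,
              if (x$config$use_irdb) "IRDBs" else "dense blocks",
              cen$upsamplings, cen$deconvolutions, cen$n_parameters))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint holds the configuration, all parameters and batch-norm
#' running statistics.
#'
#' @param model A [build_model()] result.
#' @param path File path (`.rds`).
#' @return `save_checkpoint` returns the path invisibly; `load_checkpoint`
#'   returns the model.
#' @export
save_checkpoint <- function(model, path) {
  obj <- unclass(model)
  obj$rng_state <- if (exists(".Random.seed", envir = globalenv(),
                             inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  obj$config <- structure(obj$config, class = "network_config")
  structure(obj, class = "denoising_model")
}
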