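# Shared fixtures. Expensive objects (simulated pair sets, the scaled
# training run) are cached in a session-level environment so several test
# files can reuse them without recomputation.

.ct_cache <- local({
  key <- "..ctdenoise_test_cache"
  if (!exists(key, envir = globalenv(), inherits = FALSE))
    assign(key, new.env(parent = emptyenv()), envir = globalenv())
  get(key, envir = globalenv())
})

cached <- function(key, expr) {
  if (is.null(.ct_cache[[key]])) .ct_cache[[key]] <- force(expr)
  .ct_cache[[key]]
}

tiny_cfg <- function() {
  network_config(stem_channels = 4L, growth_channels = 4L,
                 dense_layers_per_block = 2L, n_levels = 2L,
                 decoder_channels = 8L)
}

tiny_model <- function(seed = 7L) {
  cached(sprintf("tiny_model_%d", seed), build_model(tiny_cfg(), seed = seed))
}

test_pairs <- function(n, base_seed = 1L, image_size = 64L) {
  cached(sprintf("pairs_%d_%d_%d", n, base_seed, image_size),
         simulate_pairs(n, phantom_spec(image_size = image_size),
                        sim_config(), base_seed = base_seed))
}

# A small random pair whose difference image is strictly nonzero everywhere
# against a given model's prediction (premise of the all-pass identity).
strict_pair <- function(model, seed = 5L, size = 32L) {
  cached(sprintf("strict_pair_%d_%d", seed, size), {
    set.seed(seed)
    l <- matrix(runif(size * size, 0.05, 0.95), size, size)
    n <- matrix(runif(size * size, 0.05, 0.95), size, size)
    p <- image_pair(l, n)
    d <- p$ndct - denoise(model, p$ldct)
    stopifnot(all(d != 0))
    p
  })
}

# The scaled-down end-to-end study: 40 training pairs + 8 held-out 64x64
# pairs at the default 10%-dose regime, tiny model, 5 pretraining epochs +
# 10 mechanism epochs, reference loss weights.
scaled_run_config <- function() {
  list(mech = mechanism_config(threshold = 0.04, pretrain_epochs = 5L,
                               mechanism_epochs = 10L),
       tc = train_config(batch_size = 4L, lr = 2e-3, lr_drop_epoch = 7,
                         lr_after_drop = 5e-4),
       params = msssim_params(n_scales = 3L),
       model_seed = 7L, train_seed = 11L,
       train_base_seed = 1L, val_base_seed = 900L)
}

run_scaled_training <- function(cache_key = "scaled_run") {
  sc <- scaled_run_config()
  run_once <- function() {
    tr <- test_pairs(40, sc$train_base_seed)
    va <- test_pairs(8, sc$val_base_seed)
    model <- build_model(tiny_cfg(), seed = sc$model_seed)
    res <- train(model, tr, mech = sc$mech, tc = sc$tc, params = sc$params,
                 seed = sc$train_seed)
    ev <- evaluate(res$model, va)
    list(result = res, eval = ev)
  }
  if (is.null(cache_key)) run_once() else cached(cache_key, run_once())
}
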