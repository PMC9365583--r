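# Architecture contracts: layer census, shape preservation, determinism,
# closed-form parameter count and the block-level algebraic identities.

test_that("the default configuration reproduces the published layer census", {
  m <- cached("default_model", build_model(network_config(), seed = 1L))
  cen <- layer_census(m)
  expect_equal(cen$stem_convolutions, 1L)
  expect_equal(cen$stem_kernel, c(7L, 7L))
  expect_equal(cen$max_pools, 4L)
  expect_equal(cen$irdbs, 4L)
  expect_equal(cen$upsamplings, 4L)
  expect_equal(cen$deconvolutions, 8L)
  expect_equal(cen$head_kernel, c(1L, 1L))
  expect_equal(cen$head_channels, 1L)
  # head weights: 1x1 kernel, one output channel
  expect_equal(dim(m$params$head$w), c(1L, 1L, 16L, 1L))
})

test_that("output shape equals input shape and indivisible inputs are rejected", {
  m <- cached("default_model", build_model(network_config(), seed = 1L))
  m <- set_mode(m, "eval")
  for (s in c(64L, 96L, 128L)) {
    x <- matrix(seq(0, 1, length.out = s * s), s, s)
    y <- forward(m, x)
    expect_equal(dim(y), c(s, s))
    expect_true(all(is.finite(y)))
  }
  expect_error(forward(m, matrix(0, 56, 56)), "divisible by 16")
})

test_that("builds and eval-mode forwards are deterministic given the seed", {
  m1 <- build_model(tiny_cfg(), seed = 42L)
  m2 <- build_model(tiny_cfg(), seed = 42L)
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params,
                         build_model(tiny_cfg(), seed = 43L)$params))
  me <- set_mode(m1, "eval")
  x <- matrix(runif(32 * 32), 32, 32)
  expect_identical(forward(me, x), forward(me, x))
})

test_that("weight initialization matches the configured Gaussian", {
  m <- cached("default_model", build_model(network_config(), seed = 1L))
  w <- unlist(lapply(m$params, function(p) as.vector(p$w)))
  expect_lt(abs(mean(w)), 0.005)
  expect_lt(abs(sd(w) - 0.1), 0.005)
  expect_true(all(vapply(m$params, function(p) all(p$b == 0), logical(1))))
})

test_that("the parameter count matches the closed-form layer sum", {
  # stem 4 ch, growth 4, 2 dense layers, 2 levels, decoder 8: hand count.
  conv_n <- function(k, ci, co) k * k * ci * co + co
  irdb_n <- conv_n(3, 4, 4) + conv_n(3, 8, 4) +  # dense chain
    conv_n(1, 12, 4) +                           # 1x1 fusion of 12-ch concat
    conv_n(3, 4, 4) + conv_n(3, 4, 4)            # enhanced residual
  dec_n <- conv_n(5, 8, 8) + 2 * 8 +             # 5x5 deconv + BN
    conv_n(1, 8, 4) + 2 * 4                      # 1x1 deconv + BN
  expected <- conv_n(7, 1, 4) + 2 * irdb_n + 2 * dec_n + conv_n(1, 4, 1)
  expect_equal(layer_census(tiny_model())$n_parameters, expected)
  expect_lt(expected, 50000)
})

test_that("block identities: zero input/weights and the zeroed-residual case", {
  cfg <- network_config(stem_channels = 3L, growth_channels = 2L,
                        dense_layers_per_block = 2L, n_levels = 1L,
                        decoder_channels = 4L)
  m <- build_model(cfg, seed = 2L)
  # output channels equal input channels
  x <- array(rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  expect_equal(dim(irdb_forward(m, x)), dim(x))
  # zero input with zeroed weights -> zero output (identity skip of zero)
  mz <- m
  for (nm in grep("^enc1_", names(mz$params), value = TRUE)) {
    mz$params[[nm]]$w[] <- 0
    mz$params[[nm]]$b[] <- 0
  }
  z <- array(0, c(8, 8, 3, 1))
  expect_true(all(irdb_forward(mz, z) == 0))
  # zeroed enhanced-residual weights -> input + dense-path output
  mr <- m
  mr$params$enc1_eres1$w[] <- 0; mr$params$enc1_eres1$b[] <- 0
  mr$params$enc1_eres2$w[] <- 0; mr$params$enc1_eres2$b[] <- 0
  md <- mr
  md$config$use_irdb <- FALSE  # plain dense block = dense path only
  expect_equal(irdb_forward(mr, x), x + irdb_forward(md, x), tolerance = 1e-12)
  # channel mismatch is a shape error
  expect_error(irdb_forward(m, array(0, c(8, 8, 5, 1))), "features")
})

test_that("checkpoints round-trip through disk", {
  m <- tiny_model()
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  back <- load_checkpoint(f)
  expect_identical(back$params, m$params)
  expect_identical(back$config, m$config)
  x <- matrix(runif(16 * 16), 16, 16)
  expect_identical(denoise(back, x), denoise(m, x))
})
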