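# Loss formulas: exact identities, hand-derived values, oracle agreement and
# the invariances guaranteed by the definitions.

test_that("MSE loss: identities and hand-derived value", {
  a <- matrix(runif(16), 4, 4)
  expect_equal(mse_loss(a, a), 0)
  expect_equal(mse_loss(matrix(0, 4, 4), matrix(1, 4, 4)), 1)
  pred <- matrix(0, 2, 2)
  target <- matrix(c(0.5, 0, 0, 0), 2, 2)
  expect_equal(mse_loss(pred, target), 0.0625)  # 0.5^2 / 4
  expect_equal(mse_loss(pred, target), mse_loss(target, pred))
  expect_error(mse_loss(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("gradient loss: kernel properties, derived value and invariances", {
  k <- gradient_kernel()
  expect_equal(sum(k), 0)
  expect_equal(dim(k), c(3L, 3L))
  # identical and constant images give zero
  a <- matrix(runif(64), 8, 8)
  expect_equal(gradient_loss(a, a), 0)
  expect_equal(gradient_loss(matrix(0.2, 6, 6), matrix(0.9, 6, 6)), 0)
  # two-band target against zero: valid responses are all 3, loss 9
  tgt <- rbind(rep(0, 4), rep(0, 4), rep(1, 4), rep(1, 4))
  expect_equal(gradient_loss(matrix(0, 4, 4), tgt), 9)
  # symmetry and global-constant invariance
  b <- matrix(runif(64), 8, 8)
  expect_equal(gradient_loss(a, b), gradient_loss(b, a))
  expect_equal(gradient_loss(a + 0.17, b + 0.17), gradient_loss(a, b),
               tolerance = 1e-12)
})

test_that("MS-SSIM loss: perfect-similarity zero, bounds and scale handling", {
  set.seed(10)
  a <- matrix(runif(64 * 64), 64, 64)
  b <- matrix(runif(64 * 64), 64, 64)
  p <- msssim_params(n_scales = 3L)
  expect_equal(ms_ssim_loss(a, a, p), 0, tolerance = 1e-12)
  l <- ms_ssim_loss(a, b, p)
  expect_gte(l, 0)
  expect_lte(l, 1)
  # printed five weights kept as printed; truncations renormalize to 1
  expect_equal(sum(msssim_params()$scale_weights), 1.0001, tolerance = 1e-12)
  expect_equal(sum(p$scale_weights), 1, tolerance = 1e-12)
  expect_equal(msssim_params()$c1, 1e-4)
  expect_equal(msssim_params()$c2, 9e-4)
  expect_equal(msssim_params()$c3, msssim_params()$c2 / 2)
  # an image too small for the requested number of scales is rejected
  expect_error(ms_ssim_loss(matrix(0.5, 32, 32), matrix(0.4, 32, 32),
                            msssim_params(n_scales = 5L)),
               "reduce n_scales")
})

test_that("losses match the independent brute-force oracles on random pairs", {
  p3 <- msssim_params(n_scales = 3L)
  for (s in 1:5) {
    set.seed(s)
    a <- matrix(runif(64 * 64), 64, 64)
    b <- pmin(pmax(a + rnorm(64 * 64, 0, 0.1), 0), 1)
    expect_equal(mse_loss(a, b), oracle_mse(a, b), tolerance = 1e-9)
    expect_equal(gradient_loss(a, b),
                 oracle_gradient_loss(a, b, gradient_kernel()),
                 tolerance = 1e-8)
    expect_equal(ms_ssim_loss(a, b, p3), oracle_msssim_loss(a, b, 3L),
                 tolerance = 1e-6)
  }
})

test_that("composite loss respects degenerate weights and its breakdown", {
  set.seed(11)
  a <- matrix(runif(48 * 48), 48, 48)
  b <- matrix(runif(48 * 48), 48, 48)
  p <- msssim_params(n_scales = 2L)
  expect_equal(composite_loss(a, b, loss_weights(1, 0, 0), p)$total,
               mse_loss(a, b))
  z <- composite_loss(a, a, params = p)
  expect_equal(z$total, 0, tolerance = 1e-12)
  expect_true(all(z$terms == 0))
  cl <- composite_loss(a, b, params = p)
  expect_equal(cl$total,
               1 * cl$terms[["mse"]] + 0.15 * cl$terms[["msssim"]] +
                 0.8 * cl$terms[["grad"]])
})

test_that("total loss is plain addition with finiteness checks", {
  expect_equal(total_loss(0.5, 0.25), 0.75)
  expect_equal(total_loss(0.37, 0), 0.37)
  expect_error(total_loss(NaN, 1), "finite")
  expect_error(loss_weights(-0.1, 1, 1), "non-negative")
})
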