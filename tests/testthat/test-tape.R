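# Finite-difference checks of the reverse-mode tape: every structured
# operation's analytic gradient must match central differences.

fd_check <- function(build, xdim = c(4, 4, 2, 2), n_probe = 12L,
                     seed = 2L, eps = 1e-6) {
  set.seed(seed)
  xv <- array(rnorm(prod(xdim)), xdim)
  go <- function(a) {
    tp <- tape_new()
    xi <- tp_leaf(tp, a, requires_grad = TRUE)
    s <- build(tp, xi)
    list(v = tp_val(tp, s), g = tape_backward(tp, s)[[xi]])
  }
  base <- go(xv)
  idx <- round(seq(1, length(xv), length.out = n_probe))
  err <- vapply(idx, function(i) {
    a1 <- xv; a1[i] <- a1[i] + eps
    a2 <- xv; a2[i] <- a2[i] - eps
    (go(a1)$v - go(a2)$v) / (2 * eps) - base$g[i]
  }, numeric(1))
  max(abs(err))
}

test_that("convolution gradients match finite differences (input, weight, bias)", {
  set.seed(1)
  x <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  w <- array(rnorm(3 * 3 * 2 * 3) * 0.3, c(3, 3, 2, 3))
  b <- rnorm(3)
  run <- function(xv, wv, bv) {
    tp <- tape_new()
    xi <- tp_leaf(tp, xv, TRUE); wi <- tp_leaf(tp, wv, TRUE)
    bi <- tp_leaf(tp, bv, TRUE)
    y <- tp_conv2d(tp, xi, wi, bi, pad = 1L)
    s <- tp_mean(tp, tp_mul(tp, y, y))
    list(tp = tp, s = s, ids = c(xi, wi, bi))
  }
  r <- run(x, w, b)
  gr <- tape_backward(r$tp, r$s)
  num <- function(f, arr, i) {
    e <- 1e-6
    a1 <- arr; a1[i] <- a1[i] + e
    a2 <- arr; a2[i] <- a2[i] - e
    (f(a1) - f(a2)) / (2 * e)
  }
  fx <- function(a) tp_val(run(a, w, b)$tp, run(a, w, b)$s)
  fw <- function(a) tp_val(run(x, a, b)$tp, run(x, a, b)$s)
  fb <- function(a) tp_val(run(x, w, a)$tp, run(x, w, a)$s)
  for (i in c(1, 17, 60))
    expect_lt(abs(num(fx, x, i) - gr[[r$ids[1]]][i]), 1e-7)
  for (i in c(1, 9, 30))
    expect_lt(abs(num(fw, w, i) - gr[[r$ids[2]]][i]), 1e-7)
  for (i in 1:3)
    expect_lt(abs(num(fb, b, i) - gr[[r$ids[3]]][i]), 1e-7)
})

test_that("pooling, resampling, concatenation and batch-norm gradients are exact", {
  sq <- function(tp, u) tp_mean(tp, tp_mul(tp, u, u))
  expect_lt(fd_check(function(tp, x) sq(tp, tp_maxpool2(tp, x))), 1e-7)
  expect_lt(fd_check(function(tp, x) sq(tp, tp_upsample2(tp, x))), 1e-7)
  expect_lt(fd_check(function(tp, x) sq(tp, tp_avgpool2(tp, x))), 1e-7)
  expect_lt(fd_check(function(tp, x) sq(tp, tp_concat_c(tp, x, x))), 1e-7)
  gam <- c(1.2, 0.8); bet <- c(0.1, -0.2)
  expect_lt(fd_check(function(tp, x) {
    gi <- tp_leaf(tp, gam); bi <- tp_leaf(tp, bet)
    sq(tp, tp_batchnorm(tp, x, gi, bi, NULL, NULL, training = TRUE))
  }), 1e-6)
  expect_lt(fd_check(function(tp, x) {
    gi <- tp_leaf(tp, gam); bi <- tp_leaf(tp, bet)
    sq(tp, tp_batchnorm(tp, x, gi, bi, c(0.1, 0.2), c(1.1, 0.9),
                        training = FALSE))
  }), 1e-7)
})

test_that("composite loss gradient (incl. MS-SSIM and gradient terms) is exact", {
  set.seed(3)
  tgt <- array(runif(24 * 24), c(24, 24, 1, 1))
  err <- fd_check(function(tp, x) {
    b <- tp_leaf(tp, tgt)
    tl_composite(tp, x, b, loss_weights(), msssim_params(n_scales = 1L),
                 gradient_kernel())$total
  }, xdim = c(24, 24, 1, 1), n_probe = 10L)
  expect_lt(err, 1e-6)
})
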