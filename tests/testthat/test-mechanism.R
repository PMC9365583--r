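# The mask-guided correction mechanism: elementwise building blocks, the
# two-pass step, gradient coupling and the threshold scan.

test_that("difference image is the plain subtraction with antisymmetry", {
  a <- matrix(runif(16), 4, 4); b <- matrix(runif(16), 4, 4)
  expect_true(all(difference_image(a, a) == 0))
  expect_equal(difference_image(matrix(1, 3, 3), matrix(0.25, 3, 3)),
               matrix(0.75, 3, 3))
  expect_equal(difference_image(a, b), -difference_image(b, a))
  expect_error(difference_image(a, matrix(0, 5, 5)), "shape")
})

test_that("mask thresholding retains |diff| > t with strict inequality", {
  d <- matrix(c(0.05, -0.06, 0.01, 0.0), 2, 2)
  expect_equal(make_mask(d, 0.04), matrix(c(1, 1, 0, 0), 2, 2))
  expect_true(all(make_mask(d, 1) == 0))            # above max |diff|
  dn <- matrix(c(0.2, -0.3, 0.1, 0.4), 2, 2)
  expect_true(all(make_mask(dn, 0) == 1))           # strictly nonzero diffs
  expect_equal(make_mask(matrix(0.04, 2, 2), 0.04), matrix(0, 2, 2))  # ties
  expect_error(make_mask(d, -0.01), "non-negative")
})

test_that("mask application is elementwise, exact and idempotent", {
  img <- matrix(c(0.2, 0.6, 0.4, 0.8), 2, 2)
  mk <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(apply_mask(img, mk), matrix(c(0.2, 0, 0, 0.8), 2, 2))
  expect_identical(apply_mask(img, matrix(1, 2, 2)), img)
  expect_true(all(apply_mask(img, matrix(0, 2, 2)) == 0))
  expect_identical(apply_mask(apply_mask(img, mk), mk), apply_mask(img, mk))
})

test_that("the all-pass mechanism step reproduces the doubled original loss", {
  m <- set_mode(tiny_model(), "eval")
  p <- strict_pair(m)
  p2 <- msssim_params(n_scales = 2L)
  st <- mechanism_step(m, p, mechanism_config(threshold = 0), params = p2)
  expect_true(all(st$mask == 1))
  expect_identical(st$filtered_ldct[, , 1, 1], p$ldct)
  expect_identical(st$filtered_denoised, st$denoised)  # I2 == I1 bitwise
  expect_equal(st$correction_loss, st$original_loss)
  expect_equal(st$total, 2 * st$original_loss)
})

test_that("a threshold above max |D1| filters everything", {
  m <- set_mode(tiny_model(), "eval")
  p <- strict_pair(m)
  st <- mechanism_step(m, p, mechanism_config(threshold = 10),
                       params = msssim_params(n_scales = 2L))
  expect_true(all(st$mask == 0))
  expect_true(all(st$filtered_ldct == 0))
  expect_true(all(st$filtered_ndct == 0))
  expect_equal(st$total, st$original_loss + st$correction_loss)
})

test_that("step losses agree with independent recomputation from I1 and I2", {
  m <- set_mode(tiny_model(), "eval")
  p <- test_pairs(1, base_seed = 70)[[1]]
  p2 <- msssim_params(n_scales = 2L)
  st <- mechanism_step(m, p, mechanism_config(threshold = 0.04), params = p2)
  orig <- composite_loss(st$denoised[, , 1, 1], p$ndct, params = p2)$total
  corr <- composite_loss(st$filtered_denoised[, , 1, 1],
                         st$filtered_ndct[, , 1, 1], params = p2)$total
  expect_equal(st$original_loss, orig, tolerance = 1e-12)
  expect_equal(st$correction_loss, corr, tolerance = 1e-12)
  expect_equal(st$total, total_loss(orig, corr), tolerance = 1e-12)
  # the mask marks exactly the pixels whose difference exceeds the threshold
  expect_identical(st$mask, make_mask(st$difference, 0.04))
})

test_that("mechanism gradients differ from plain gradients for a mixed mask", {
  m <- tiny_model()
  p <- test_pairs(1, base_seed = 70)[[1]]
  st0 <- ctdenoise:::.stack_pairs(list(p))
  p2 <- msssim_params(n_scales = 2L)
  grad_of <- function(mechanism, threshold) {
    tc <- train_config(batch_size = 1L)
    adam <- ctdenoise:::.adam_pass_tc(tc, ctdenoise:::.adam_new())
    res <- ctdenoise:::.train_step(m, st0$L, st0$N, mechanism, threshold,
                                   loss_weights(), p2, gradient_kernel(), tc,
                                   1e-3, adam)
    res$model$params$stem$w
  }
  # confirm the mask is mixed at this threshold
  stc <- mechanism_step(set_mode(m, "eval"), p,
                        mechanism_config(threshold = 0.04), params = p2)
  expect_gt(mean(stc$mask), 0)
  expect_lt(mean(stc$mask), 1)
  expect_false(isTRUE(all.equal(grad_of(TRUE, 0.04), grad_of(FALSE, 0.04))))
})

test_that("two epochs of descent reduce the training loss on one pair", {
  p <- test_pairs(1, base_seed = 70)
  m <- build_model(tiny_cfg(), seed = 9L)
  res <- train(m, p, mechanism_config(pretrain_epochs = 2L,
                                      mechanism_epochs = 0L),
               train_config(batch_size = 1L, lr = 1e-3, lr_drop_epoch = Inf),
               params = msssim_params(n_scales = 2L), seed = 1L)
  expect_lte(res$log$loss_total[2], res$log$loss_total[1])
  expect_error(train(m, list()), "empty")
})

test_that("disabling the mechanism makes phase 2 plain continued training", {
  p <- test_pairs(2, base_seed = 75)
  m <- build_model(tiny_cfg(), seed = 9L)
  p2 <- msssim_params(n_scales = 2L)
  tc <- train_config(batch_size = 2L, lr = 1e-3, lr_drop_epoch = Inf)
  off <- train(m, p, mechanism_config(enabled = FALSE, pretrain_epochs = 1L,
                                      mechanism_epochs = 1L),
               tc, params = p2, seed = 4L)
  on4 <- train(m, p, mechanism_config(pretrain_epochs = 2L,
                                      mechanism_epochs = 0L),
               tc, params = p2, seed = 4L)
  expect_equal(off$log$loss_total, on4$log$loss_total, tolerance = 1e-12)
  expect_identical(off$model$params, on4$model$params)
})

test_that("retained fraction is monotone over the reference threshold grid", {
  m <- tiny_model()
  pairs <- test_pairs(3, base_seed = 80)
  sc <- threshold_scan(m, pairs)
  expect_equal(sc$table$threshold, c(0.01, 0.04, 0.07, 0.10))
  expect_true(all(diff(sc$table$retained_fraction) <= 0))
  expect_true(all(sc$table$retained_fraction >= 0 &
                    sc$table$retained_fraction <= 1))
  # threshold 0 retains everything when differences are strictly nonzero
  sp <- strict_pair(set_mode(m, "eval"))
  sc0 <- threshold_scan(m, list(sp), thresholds = 0)
  expect_equal(sc0$table$retained_fraction, 1)
  expect_error(threshold_scan(m, pairs, numeric(0)), "empty")
})
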