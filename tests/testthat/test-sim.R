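# Synthetic paired-slice simulator: phantom rendering, projection and
# reconstruction geometry, photon-noise behaviour, fixture reproducibility.

test_that("empty and background-only phantoms render as expected", {
  z <- generate_phantom(phantom_spec(n_ellipses = 0L, background = 0))
  expect_true(all(z == 0))
  b <- generate_phantom(phantom_spec(n_ellipses = 0L, background = 0.3))
  n <- nrow(b)
  cc <- seq_len(n) - (n + 1) / 2
  inner <- outer(cc^2, cc^2, "+") <= (0.7 * n / 2)^2  # deep inside the FOV disc
  expect_true(all(abs(b[inner] - 0.3) < 1e-12))
  # outside the FOV disc only negligible PSF tails remain
  expect_lt(max(abs(b[outer(cc^2, cc^2, "+") > (0.95 * n / 2)^2])), 1e-4)
})

test_that("phantom generation is deterministic and range-bounded", {
  sp <- phantom_spec(seed = 7L)
  p1 <- generate_phantom(sp)
  p2 <- generate_phantom(sp)
  expect_identical(p1, p2)
  expect_gte(min(p1), 0)
  expect_lte(max(p1), 1)
  expect_false(identical(p1, generate_phantom(phantom_spec(seed = 8L))))
})

test_that("spec validation rejects invalid phantom and sim parameters", {
  expect_error(phantom_spec(image_size = 8), "at least 16")
  expect_error(phantom_spec(n_ellipses = -1), "non-negative")
  expect_error(sim_config(dose_fraction = 0), "dose_fraction")
  expect_error(sim_config(incident_photons = -5), "positive")
  expect_error(sim_config(n_angles = 1), "n_angles")
})

test_that("noise-free reconstruction is faithful and pairs stay in [0, 1]", {
  ph <- generate_phantom(phantom_spec(seed = 3L))
  pr <- simulate_pair(ph, sim_config(noise_free = TRUE, n_angles = 128L))
  expect_s3_class(pr, "image_pair")
  expect_identical(dim(pr$ldct), dim(pr$ndct))
  expect_gte(psnr(pr$ldct, pr$ndct), 40)
  expect_lt(mean(abs(pr$ldct - pr$ndct)), 0.01)
  expect_true(all(pr$ldct >= 0 & pr$ldct <= 1))
  expect_true(all(pr$ndct >= 0 & pr$ndct <= 1))
})

test_that("an empty phantom reconstructs to a near-zero low-dose image", {
  ph <- matrix(0, 64, 64)
  pr <- simulate_pair(ph, sim_config(seed = 9L))
  expect_lt(mean(abs(pr$ldct)), 0.05)
})

test_that("photon noise is seed-deterministic and dose-dependent", {
  ph <- generate_phantom(phantom_spec(seed = 4L))
  cfg <- sim_config(seed = 21L)
  expect_identical(simulate_pair(ph, cfg)$ldct, simulate_pair(ph, cfg)$ldct)
  # lower dose is visibly noisier on a single seed-matched pair
  lo <- simulate_pair(ph, sim_config(dose_fraction = 0.1, seed = 5L))
  hi <- simulate_pair(ph, sim_config(dose_fraction = 1, seed = 5L))
  expect_gt(psnr(hi$ldct, hi$ndct), psnr(lo$ldct, lo$ndct))
})

test_that("radon/FBP geometry round-trips an off-center impulse region", {
  img <- matrix(0, 64, 64)
  img[20:24, 38:42] <- 1
  img <- ctdenoise:::.gauss_blur(img, 1)
  rec <- ct_fbp(ct_radon(img, 128L))
  expect_equal(which.max(rec), which.max(img))
  expect_lt(mean(abs(rec - img)), 0.01)
})

test_that("fixture sets are reproducible byte for byte and round-trip", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  sp <- phantom_spec(image_size = 32L)
  cf <- sim_config(n_angles = 48L)
  m0 <- make_fixture_set(0L, sp, cf, d1)
  expect_equal(nrow(m0), 0)
  expect_length(list.files(d1, pattern = "rds$"), 0)
  m1 <- make_fixture_set(3L, sp, cf, d1, base_seed = 5L)
  m2 <- make_fixture_set(3L, sp, cf, d2, base_seed = 5L)
  expect_equal(nrow(m1), 3)
  for (f in c(m1$ldct, m1$ndct, "manifest.json"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  back <- read_fixture_set(d1)
  direct <- simulate_pairs(3L, sp, cf, base_seed = 5L)
  expect_equal(back[[2]]$ldct, direct[[2]]$ldct, tolerance = 1e-12)
})
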