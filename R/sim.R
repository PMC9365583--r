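# Synthetic paired-slice simulator: random ellipse phantoms, line-integral
# projection, Poisson photon statistics at a dose fraction, and ramp-filtered
# backprojection. Provides seed-deterministic LDCT/NDCT pairs so the denoiser
# is testable without clinical data.

# Run code under a fixed RNG seed and restore the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify a random ellipse phantom
#'
#' A phantom is a square image in `[0, 1]` made of `n_ellipses` randomly
#' placed, sized, oriented and weighted ellipses on a constant-background
#' disc, mimicking the piecewise-constant anatomy CT reconstructions are
#' benchmarked on. All structures lie inside the inscribed circle (the
#' scanner field of view), so filtered backprojection can represent them.
#'
#' @param image_size Pixels per side (square image), at least 16.
#' @param n_ellipses Number of random ellipses (0 gives the bare background).
#' @param intensity_range Length-2 numeric, min/max additive ellipse
#'   intensity on the `[0, 1]` scale.
#' @param background Constant intensity of the field-of-view disc.
#' @param psf_sigma Standard deviation (pixels) of the Gaussian point-spread
#'   function applied when rendering, emulating finite scanner resolution.
#'   The band-limited image is the ground truth; 0 disables smoothing.
#' @param seed Integer RNG seed; identical specs give bit-identical phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 64L, n_ellipses = 6L,
                         intensity_range = c(0.15, 0.5), background = 0.2,
                         psf_sigma = 0.8, seed = 1L) {
  if (!is.numeric(image_size) || image_size < 16)
    stop("phantom_spec: image_size must be at least 16", call. = FALSE)
  if (!is.numeric(n_ellipses) || n_ellipses < 0)
    stop("phantom_spec: n_ellipses must be non-negative", call. = FALSE)
  if (length(intensity_range) != 2 || intensity_range[1] > intensity_range[2])
    stop("phantom_spec: intensity_range must be c(min, max)", call. = FALSE)
  structure(list(image_size = as.integer(image_size),
                 n_ellipses = as.integer(n_ellipses),
                 intensity_range = as.numeric(intensity_range),
                 background = as.numeric(background),
                 psf_sigma = as.numeric(psf_sigma),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Simulation configuration for paired low-/normal-dose slices
#'
#' @param dose_fraction Fraction of the routine dose in `(0, 1]`; the
#'   clinical regimes emulated are 10% (chest) and 25% (brain).
#' @param incident_photons Expected photon count per detector bin at full
#'   dose (blank scan).
#' @param n_angles Number of projection angles over 180 degrees.
#' @param noise_free If `TRUE`, photon statistics are bypassed and the
#'   low-dose image is the plain filtered-backprojection reconstruction.
#' @param attenuation Attenuation per unit intensity per pixel traversed;
#'   converts phantom line integrals to optical depth for the photon model.
#' @param ndct_reconstruction If `TRUE`, the normal-dose image is a
#'   noise-free reconstruction instead of the phantom itself.
#' @param seed Integer RNG seed for the photon noise.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dose_fraction = 0.1, incident_photons = 3000,
                       n_angles = 180L, noise_free = FALSE,
                       attenuation = 0.05, ndct_reconstruction = FALSE,
                       seed = 1L) {
  if (!is.numeric(dose_fraction) || dose_fraction <= 0 || dose_fraction > 1)
    stop("sim_config: dose_fraction must be in (0, 1]", call. = FALSE)
  if (!is.numeric(incident_photons) || incident_photons <= 0)
    stop("sim_config: incident_photons must be positive", call. = FALSE)
  if (!is.numeric(n_angles) || n_angles < 2)
    stop("sim_config: n_angles must be at least 2", call. = FALSE)
  structure(list(dose_fraction = as.numeric(dose_fraction),
                 incident_photons = as.numeric(incident_photons),
                 n_angles = as.integer(n_angles),
                 noise_free = isTRUE(noise_free),
                 attenuation = as.numeric(attenuation),
                 ndct_reconstruction = isTRUE(ndct_reconstruction),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a random ellipse phantom
#'
#' Renders the phantom described by a [phantom_spec()] at 2x supersampling
#' (pixel-area averaging), clipped to `[0, 1]`. Deterministic given the
#' spec's seed.
#'
#' @param spec A [phantom_spec()].
#' @return A square numeric matrix with values in `[0, 1]`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$image_size
  ns <- 2L * n  # supersampled grid
  cc <- seq(-1 + 1 / ns, 1 - 1 / ns, length.out = ns)
  X <- matrix(cc, ns, ns, byrow = TRUE)
  Y <- matrix(cc, ns, ns)
  img <- matrix(0, ns, ns)
  fov <- (X^2 + Y^2) <= 0.85^2
  img[fov] <- spec$background
  if (spec$n_ellipses > 0) {
    pars <- with_seed(spec$seed, {
      data.frame(cx = runif(spec$n_ellipses, -0.45, 0.45),
                 cy = runif(spec$n_ellipses, -0.45, 0.45),
                 a = runif(spec$n_ellipses, 0.08, 0.3),
                 b = runif(spec$n_ellipses, 0.08, 0.3),
                 phi = runif(spec$n_ellipses, 0, pi),
                 val = runif(spec$n_ellipses, spec$intensity_range[1],
                             spec$intensity_range[2]))
    })
    for (i in seq_len(spec$n_ellipses)) {
      p <- pars[i, ]
      u <- cos(p$phi) * (X - p$cx) + sin(p$phi) * (Y - p$cy)
      v <- -sin(p$phi) * (X - p$cx) + cos(p$phi) * (Y - p$cy)
      inside <- (u / p$a)^2 + (v / p$b)^2 <= 1
      img[inside] <- img[inside] + p$val
    }
  }
  # 2x2 pixel-area average down to the target grid
  o <- seq(1L, ns, by = 2L)
  img <- (img[o, o] + img[o + 1L, o] + img[o, o + 1L] + img[o + 1L, o + 1L]) / 4
  pmin(pmax(.gauss_blur(img, spec$psf_sigma), 0), 1)
}

# Separable Gaussian smoothing with reflected-to-zero padding via conv2d.
.gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- ceiling(3 * sigma)
  g <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- outer(g, g)
  k <- array(k / sum(k), c(2L * r + 1L, 2L * r + 1L, 1L, 1L))
  y <- cpp_conv2d(array(img, c(nrow(img), ncol(img), 1L, 1L)), k,
                  numeric(1), as.integer(r))
  matrix(y, nrow(img), ncol(img))
}

# Bilinear sampling of matrix `img` at (row, col) positions; zero outside.
.bilinear <- function(img, r, c) {
  n <- nrow(img); m <- ncol(img)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  pick <- function(ri, ci) {
    v <- numeric(length(ri))
    ok <- ri >= 1 & ri <= n & ci >= 1 & ci <= m
    v[ok] <- img[cbind(ri[ok], ci[ok])]
    v
  }
  pick(r0, c0) * (1 - fr) * (1 - fc) + pick(r0 + 1, c0) * fr * (1 - fc) +
    pick(r0, c0 + 1) * (1 - fr) * fc + pick(r0 + 1, c0 + 1) * fr * fc
}

#' Line-integral (Radon) projection of a square image
#'
#' Parallel-beam forward projection: for each angle the image is resampled on
#' a rotated grid (bilinear interpolation) and summed along rays. Detector
#' spacing and ray-step equal one pixel.
#'
#' @param img Square numeric matrix.
#' @param n_angles Number of angles, equally spaced over `[0, pi)`.
#' @return A `image_size x n_angles` sinogram matrix.
#' @export
ct_radon <- function(img, n_angles) {
  n <- nrow(img)
  stopifnot(ncol(img) == n)
  center <- (n + 1) / 2
  coords <- seq_len(n) - center
  thetas <- seq(0, pi, length.out = n_angles + 1)[seq_len(n_angles)]
  Tm <- matrix(coords, n, n, byrow = TRUE)  # detector coordinate t (columns)
  Sm <- matrix(coords, n, n)                # ray parameter s (rows)
  sino <- matrix(0, n, n_angles)
  for (k in seq_len(n_angles)) {
    th <- thetas[k]
    xs <- cos(th) * Tm - sin(th) * Sm
    ys <- sin(th) * Tm + cos(th) * Sm
    v <- .bilinear(img, ys + center, xs + center)
    sino[, k] <- colSums(matrix(v, n, n))
  }
  sino
}

# Discrete ramp (Ram-Lak) filter in the Fourier domain for a padded length,
# built from its exact space-domain form to avoid the DC bias of sampling
# |f| directly.
.ramp_filter <- function(len) {
  nn <- c(seq(1, len / 2 - 1, by = 2))
  f <- numeric(len)
  f[1] <- 0.25
  f[1 + nn] <- -1 / (pi * nn)^2
  f[len + 1 - nn] <- -1 / (pi * nn)^2
  2 * Re(stats::fft(f))
}

#' Filtered backprojection of a sinogram
#'
#' Ramp-filters each projection (FFT with zero padding to the next power of
#' two at least twice the detector length) and backprojects with linear
#' interpolation, using the same geometry as [ct_radon()]. Pixels outside the
#' inscribed-circle field of view, where parallel-beam data cannot determine
#' the image, are set to zero.
#'
#' @param sino Sinogram matrix (`detector_bins x n_angles`).
#' @return Square reconstruction matrix of side `nrow(sino)`.
#' @export
ct_fbp <- function(sino) {
  n <- nrow(sino)
  n_angles <- ncol(sino)
  pad <- max(64L, 2L^ceiling(log2(2L * n)))
  filt <- .ramp_filter(pad)
  fsino <- matrix(0, n, n_angles)
  for (k in seq_len(n_angles)) {
    p <- c(sino[, k], numeric(pad - n))
    fp <- Re(stats::fft(stats::fft(p) * filt, inverse = TRUE)) / pad
    fsino[, k] <- fp[seq_len(n)]
  }
  center <- (n + 1) / 2
  coords <- seq_len(n) - center
  X <- matrix(coords, n, n, byrow = TRUE)
  Y <- matrix(coords, n, n)
  thetas <- seq(0, pi, length.out = n_angles + 1)[seq_len(n_angles)]
  recon <- matrix(0, n, n)
  for (k in seq_len(n_angles)) {
    t <- cos(thetas[k]) * X + sin(thetas[k]) * Y + center
    t0 <- floor(t)
    ft <- t - t0
    inb <- t0 >= 1 & t0 <= n - 1
    vals <- matrix(0, n, n)
    vals[inb] <- fsino[t0[inb], k] * (1 - ft[inb]) +
      fsino[t0[inb] + 1, k] * ft[inb]
    recon <- recon + vals
  }
  recon <- recon * pi / (2 * n_angles)
  recon[outer(coords^2, coords^2, "+") > (n / 2)^2] <- 0
  recon
}

#' Simulate a paired low-dose / normal-dose slice
#'
#' The phantom is forward-projected; transmitted photon counts per detector
#' bin are drawn as `Poisson(N0 * dose_fraction * exp(-mu * p))` (floored at
#' one count before the log transform), log-converted back to line integrals
#' and reconstructed by filtered backprojection. The normal-dose image is
#' the clean phantom by default, giving exact ground truth. Both images are
#' renormalized to `[0, 1]` with the normal-dose min/max so the pair shares
#' one intensity scale, then clipped.
#'
#' @param phantom Square matrix in `[0, 1]` (see [generate_phantom()]).
#' @param cfg A [sim_config()].
#' @return An [image_pair()] with provenance `"synthetic"`.
#' @export
simulate_pair <- function(phantom, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (min(phantom) < 0 || max(phantom) > 1)
    stop("simulate_pair: phantom must lie in [0, 1]", call. = FALSE)
  sino <- ct_radon(phantom, cfg$n_angles)
  if (cfg$noise_free) {
    ldct <- ct_fbp(sino)
  } else {
    mu <- cfg$attenuation
    n0 <- cfg$incident_photons * cfg$dose_fraction
    expected <- n0 * exp(-mu * sino)
    counts <- with_seed(cfg$seed,
                        matrix(stats::rpois(length(expected), expected),
                               nrow(expected), ncol(expected)))
    counts <- pmax(counts, 1)           # photon floor before the log
    noisy_sino <- -log(counts / n0) / mu
    ldct <- ct_fbp(noisy_sino)
  }
  ndct <- if (cfg$ndct_reconstruction) ct_fbp(sino) else phantom
  rng <- range(ndct)
  if (diff(rng) > 1e-12) {
    ndct <- (ndct - rng[1]) / diff(rng)
    ldct <- (ldct - rng[1]) / diff(rng)
  }
  image_pair(ldct = pmin(pmax(ldct, 0), 1), ndct = pmin(pmax(ndct, 0), 1),
             provenance = "synthetic")
}

#' A registered low-dose / normal-dose slice pair
#'
#' @param ldct,ndct Numeric matrices of identical shape with finite values
#'   in `[0, 1]`.
#' @param pixel_size Physical spacing (arbitrary units).
#' @param provenance One of `"synthetic"`, `"dicom"`, `"file"`.
#' @return An object of class `image_pair`.
#' @export
image_pair <- function(ldct, ndct, pixel_size = 1,
                       provenance = c("synthetic", "dicom", "file")) {
  provenance <- match.arg(provenance)
  ldct <- as.matrix(ldct); ndct <- as.matrix(ndct)
  if (!all(dim(ldct) == dim(ndct)))
    stop("image_pair: ldct and ndct must have identical shape", call. = FALSE)
  if (!all(is.finite(ldct)) || !all(is.finite(ndct)))
    stop("image_pair: intensities must be finite", call. = FALSE)
  if (min(ldct) < -1e-9 || max(ldct) > 1 + 1e-9 ||
      min(ndct) < -1e-9 || max(ndct) > 1 + 1e-9)
    stop("image_pair: intensities must lie in [0, 1]", call. = FALSE)
  structure(list(ldct = ldct, ndct = ndct, pixel_size = pixel_size,
                 provenance = provenance),
            class = "image_pair")
}

#' @export
print.image_pair <- function(x, ...) {
  cat(sprintf("<image_pair> %d x %d, provenance: %s\n",
              nrow(x$ldct), ncol(x$ldct), x$provenance))
  invisible(x)
}

#' Generate a set of simulated pairs
#'
#' Convenience wrapper: draws `n_pairs` phantoms and pairs with seeds
#' `base_seed + 0 .. n_pairs-1` applied to both the phantom and the photon
#' noise, so the set is reproducible from a single integer.
#'
#' @param n_pairs Number of pairs.
#' @param spec A [phantom_spec()] template (its seed field is overridden).
#' @param cfg A [sim_config()] template (its seed field is overridden).
#' @param base_seed First seed of the sequence.
#' @return List of [image_pair()] objects.
#' @export
simulate_pairs <- function(n_pairs, spec = phantom_spec(),
                           cfg = sim_config(), base_seed = 1L) {
  lapply(seq_len(n_pairs), function(i) {
    s <- as.integer(base_seed + i - 1L)
    spec$seed <- s
    cfg$seed <- s + 500000L
    simulate_pair(generate_phantom(spec), cfg)
  })
}

#' Write a reproducible fixture set of simulated pairs
#'
#' Writes `n_pairs` simulated pairs in the array-container format of
#' [write_pair()] plus a JSON manifest listing files and seeds. Re-running
#' with identical arguments reproduces byte-identical files.
#'
#' @param n_pairs Number of pairs (0 writes an empty manifest).
#' @param spec,cfg Templates as in [simulate_pairs()].
#' @param out_dir Output directory (created if needed).
#' @param base_seed First seed.
#' @return Invisibly, the manifest as a data frame.
#' @export
make_fixture_set <- function(n_pairs, spec = phantom_spec(),
                             cfg = sim_config(), out_dir, base_seed = 1L) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("make_fixture_set: cannot create directory: ", out_dir, call. = FALSE)
  pairs <- simulate_pairs(n_pairs, spec, cfg, base_seed)
  manifest <- data.frame(index = integer(0), seed = integer(0),
                         ldct = character(0), ndct = character(0))
  for (i in seq_len(n_pairs)) {
    fl <- sprintf("pair%03d_ldct.rds", i)
    fn <- sprintf("pair%03d_ndct.rds", i)
    write_pair(pairs[[i]], file.path(out_dir, fl), file.path(out_dir, fn))
    manifest <- rbind(manifest,
                      data.frame(index = i, seed = as.integer(base_seed + i - 1L),
                                 ldct = fl, ndct = fn))
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  invisible(manifest)
}
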