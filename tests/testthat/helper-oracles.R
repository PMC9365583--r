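# Independent brute-force reference implementations used to cross-check the
# package's losses and metrics. These deliberately avoid the package's conv
# machinery: local statistics come from explicit sliding-window loops and
# downsampling from explicit index arithmetic.

oracle_mse <- function(a, b) mean((a - b)^2)

oracle_psnr <- function(a, b, max_value = 1) {
  10 * log10(max_value^2 / mean((a - b)^2))
}

# Valid-region cross-correlation with a 3x3 kernel by explicit loops.
oracle_corr3 <- function(x, k) {
  n <- nrow(x) - 2L; m <- ncol(x) - 2L
  out <- matrix(0, n, m)
  for (i in seq_len(n))
    for (j in seq_len(m))
      out[i, j] <- sum(k * x[i:(i + 2L), j:(j + 2L)])
  out
}

oracle_gradient_loss <- function(a, b, k) {
  mean((oracle_corr3(a, k) - oracle_corr3(b, k))^2)
}

.oracle_gwin <- function(win, sigma) {
  r <- seq_len(win) - (win + 1) / 2
  g <- exp(-r^2 / (2 * sigma^2))
  w <- outer(g, g)
  w / sum(w)
}

# Per-window SSIM statistics; returns the mean luminance*cs map and the mean
# cs map separately so both single-scale SSIM and MS-SSIM reuse it.
.oracle_ssim_stats <- function(x, y, max_value, win, sigma) {
  w <- .oracle_gwin(win, sigma)
  n <- nrow(x) - win + 1L; m <- ncol(x) - win + 1L
  c1 <- (0.01 * max_value)^2; c2 <- (0.03 * max_value)^2
  lcs <- matrix(0, n, m); cs <- matrix(0, n, m)
  for (i in seq_len(n))
    for (j in seq_len(m)) {
      px <- x[i:(i + win - 1L), j:(j + win - 1L)]
      py <- y[i:(i + win - 1L), j:(j + win - 1L)]
      mx <- sum(w * px); my <- sum(w * py)
      vx <- sum(w * px^2) - mx^2
      vy <- sum(w * py^2) - my^2
      cxy <- sum(w * px * py) - mx * my
      l <- (2 * mx * my + c1) / (mx^2 + my^2 + c1)
      cc <- (2 * cxy + c2) / (vx + vy + c2)
      lcs[i, j] <- l * cc
      cs[i, j] <- cc
    }
  list(lcs = lcs, cs = cs)
}

oracle_ssim <- function(x, y, max_value = 1, win = 11L, sigma = 1.5) {
  mean(.oracle_ssim_stats(x, y, max_value, win, sigma)$lcs)
}

.oracle_down2 <- function(x) {
  h <- 2L * (nrow(x) %/% 2L); w <- 2L * (ncol(x) %/% 2L)
  o1 <- seq(1L, h, 2L); p1 <- seq(1L, w, 2L)
  (x[o1, p1] + x[o1 + 1L, p1] + x[o1, p1 + 1L] + x[o1 + 1L, p1 + 1L]) / 4
}

oracle_msssim_loss <- function(x, y, n_scales = 3L, max_value = 1,
                               win = 11L, sigma = 1.5, floor_eps = 1e-6) {
  w5 <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)
  w <- w5[seq_len(n_scales)]
  if (n_scales < 5L) w <- w / sum(w)
  acc <- 1
  for (j in seq_len(n_scales)) {
    st <- .oracle_ssim_stats(x, y, max_value, win, sigma)
    term <- if (j < n_scales) mean(st$cs) else mean(st$lcs)
    acc <- acc * max(term, floor_eps)^w[j]
    if (j < n_scales) {
      x <- .oracle_down2(x)
      y <- .oracle_down2(y)
    }
  }
  1 - acc
}
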