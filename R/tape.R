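#' @useDynLib ctdenoise, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# ---------------------------------------------------------------------------
# A minimal reverse-mode automatic-differentiation tape.
#
# Every tensor lives on a tape as a node holding its value (an R array, with
# feature maps laid out (H, W, C, N)) and a closure that maps the upstream
# gradient to gradients for the node's parents. tape_backward() walks the
# nodes in reverse creation order, which is a valid topological order because
# parents are always created before children.
#
# This engine exists because the network and its training procedure are the
# package's subject matter; only the inner convolution loops are in C++.
# ---------------------------------------------------------------------------

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$vals <- list()
  tp$nodes <- list()
  tp$n <- 0L
  tp
}

tp_val <- function(tp, id) {
  force(id)
  tp$vals[[id]]
}

# Register a node. `backward(g, tp)` returns a list of gradients aligned with
# `parents` (NULL entries allowed). Nodes with no grad-requiring ancestor are
# skipped during the backward sweep.
tp_node <- function(tp, value, parents = integer(0), backward = NULL,
                    requires = NULL) {
  if (is.null(requires)) {
    requires <- FALSE
    for (p in parents) if (tp$nodes[[p]]$requires) { requires <- TRUE; break }
  }
  tp$n <- tp$n + 1L
  id <- tp$n
  tp$vals[[id]] <- value
  tp$nodes[[id]] <- list(parents = parents, backward = backward,
                         requires = requires)
  id
}

tp_leaf <- function(tp, value, requires_grad = FALSE) {
  tp_node(tp, value, requires = requires_grad)
}

# Backward sweep from scalar node `id`; returns the list of gradients indexed
# by node id (non-NULL only where reached).
tape_backward <- function(tp, id) {
  grads <- vector("list", tp$n)
  seed <- tp$vals[[id]]
  grads[[id]] <- array(1, dim = if (is.null(dim(seed))) length(seed) else dim(seed))
  for (k in seq(id, 1L)) {
    g <- grads[[k]]
    if (is.null(g)) next
    node <- tp$nodes[[k]]
    if (is.null(node$backward) || !node$requires) next
    pg <- node$backward(g, tp)
    for (i in seq_along(node$parents)) {
      p <- node$parents[i]
      if (is.null(pg[[i]]) || !tp$nodes[[p]]$requires) next
      grads[[p]] <- if (is.null(grads[[p]])) pg[[i]] else grads[[p]] + pg[[i]]
    }
  }
  grads
}

# --- elementwise arithmetic -------------------------------------------------

# Gradient of a broadcast operand: length-1 operands absorb a summed gradient.
.reduce_like <- function(g, v) if (length(v) == 1L) sum(g) else g

tp_add <- function(tp, a, b) {
  force(a); force(b)
  tp_node(tp, tp$vals[[a]] + tp$vals[[b]], c(a, b), function(g, tp)
    list(.reduce_like(g, tp$vals[[a]]), .reduce_like(g, tp$vals[[b]])))
}

tp_sub <- function(tp, a, b) {
  force(a); force(b)
  tp_node(tp, tp$vals[[a]] - tp$vals[[b]], c(a, b), function(g, tp)
    list(.reduce_like(g, tp$vals[[a]]), .reduce_like(-g, tp$vals[[b]])))
}

tp_mul <- function(tp, a, b) {
  force(a); force(b)
  tp_node(tp, tp$vals[[a]] * tp$vals[[b]], c(a, b), function(g, tp)
    list(.reduce_like(g * tp$vals[[b]], tp$vals[[a]]),
         .reduce_like(g * tp$vals[[a]], tp$vals[[b]])))
}

tp_div <- function(tp, a, b) {
  force(a); force(b)
  tp_node(tp, tp$vals[[a]] / tp$vals[[b]], c(a, b), function(g, tp) {
    av <- tp$vals[[a]]; bv <- tp$vals[[b]]
    list(.reduce_like(g / bv, av), .reduce_like(-g * av / (bv * bv), bv))
  })
}

tp_mul_const <- function(tp, a, k) {
  force(a)
  tp_node(tp, tp$vals[[a]] * k, a, function(g, tp) list(.reduce_like(g * k, tp$vals[[a]])))
}

tp_add_const <- function(tp, a, k) {
  force(a)
  tp_node(tp, tp$vals[[a]] + k, a, function(g, tp) list(g))
}

# x^p for elementwise positive x (exponents of MS-SSIM scale statistics).
tp_pow_const <- function(tp, a, p) {
  force(a)
  tp_node(tp, tp$vals[[a]]^p, a, function(g, tp)
    list(g * p * tp$vals[[a]]^(p - 1)))
}

tp_clamp_min <- function(tp, a, lo) {
  force(a)
  tp_node(tp, pmax(tp$vals[[a]], lo), a, function(g, tp)
    list(g * (tp$vals[[a]] > lo)))
}

tp_relu <- function(tp, a) {
  force(a)
  tp_node(tp, pmax(tp$vals[[a]], 0), a, function(g, tp)
    list(g * (tp$vals[[a]] > 0)))
}

# --- reductions -------------------------------------------------------------

tp_mean <- function(tp, a) {
  force(a)
  tp_node(tp, mean(tp$vals[[a]]), a, function(g, tp) {
    v <- tp$vals[[a]]
    list(array(as.numeric(g) / length(v),
               dim = if (is.null(dim(v))) length(v) else dim(v)))
  })
}

tp_sum <- function(tp, a) {
  force(a)
  tp_node(tp, sum(tp$vals[[a]]), a, function(g, tp) {
    v <- tp$vals[[a]]
    list(array(as.numeric(g), dim = if (is.null(dim(v))) length(v) else dim(v)))
  })
}

# --- structured (H, W, C, N) operations ------------------------------------

tp_conv2d <- function(tp, x, w, b, pad = 0L) {
  force(x); force(w); force(b)
  y <- cpp_conv2d(tp$vals[[x]], tp$vals[[w]], tp$vals[[b]], as.integer(pad))
  tp_node(tp, y, c(x, w, b), function(g, tp) {
    bw <- cpp_conv2d_bwd(tp$vals[[x]], tp$vals[[w]], g, as.integer(pad))
    list(bw$gx, bw$gw, bw$gb)
  })
}

tp_maxpool2 <- function(tp, x) {
  force(x)
  mp <- cpp_maxpool2(tp$vals[[x]])
  dimx <- dim(tp$vals[[x]])
  tp_node(tp, mp$y, x, function(g, tp)
    list(cpp_maxpool2_bwd(g, mp$idx, as.integer(dimx))))
}

# Nearest-neighbour x2 upsampling.
tp_upsample2 <- function(tp, x) {
  force(x)
  v <- tp$vals[[x]]
  d <- dim(v)
  ih <- rep(seq_len(d[1]), each = 2L)
  iw <- rep(seq_len(d[2]), each = 2L)
  y <- v[ih, iw, , , drop = FALSE]
  tp_node(tp, y, x, function(g, tp) {
    o1 <- seq(1L, 2L * d[1], by = 2L); o2 <- o1 + 1L
    p1 <- seq(1L, 2L * d[2], by = 2L); p2 <- p1 + 1L
    list(g[o1, p1, , , drop = FALSE] + g[o2, p1, , , drop = FALSE] +
         g[o1, p2, , , drop = FALSE] + g[o2, p2, , , drop = FALSE])
  })
}

# 2x2 average pooling (dyadic downsampling between MS-SSIM scales).
tp_avgpool2 <- function(tp, x) {
  force(x)
  v <- tp$vals[[x]]
  d <- dim(v)
  h <- 2L * (d[1] %/% 2L); w <- 2L * (d[2] %/% 2L)  # drop odd remainder
  o1 <- seq(1L, h, by = 2L); o2 <- o1 + 1L
  p1 <- seq(1L, w, by = 2L); p2 <- p1 + 1L
  y <- (v[o1, p1, , , drop = FALSE] + v[o2, p1, , , drop = FALSE] +
        v[o1, p2, , , drop = FALSE] + v[o2, p2, , , drop = FALSE]) / 4
  tp_node(tp, y, x, function(g, tp) {
    gx <- array(0, dim = d)
    gq <- g / 4
    gx[o1, p1, , ] <- gq
    gx[o2, p1, , ] <- gx[o2, p1, , , drop = FALSE] + gq
    gx[o1, p2, , ] <- gx[o1, p2, , , drop = FALSE] + gq
    gx[o2, p2, , ] <- gx[o2, p2, , , drop = FALSE] + gq
    list(gx)
  })
}

tp_concat_c <- function(tp, a, b) {
  force(a); force(b)
  va <- tp$vals[[a]]; vb <- tp$vals[[b]]
  da <- dim(va); db <- dim(vb)
  stopifnot(all(da[c(1, 2, 4)] == db[c(1, 2, 4)]))
  y <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- va
  y[, , da[3] + seq_len(db[3]), ] <- vb
  tp_node(tp, y, c(a, b), function(g, tp)
    list(g[, , seq_len(da[3]), , drop = FALSE],
         g[, , da[3] + seq_len(db[3]), , drop = FALSE]))
}

# Batch normalization over (H, W, N) per channel.
#
# In training mode the batch statistics normalize the activations and are
# returned via `state_out` so the caller can fold them into running averages
# (the caller decides when running statistics update — see mechanism_step).
# In eval mode the stored running statistics are used, making the layer a
# deterministic affine map.
tp_batchnorm <- function(tp, x, gamma, beta, running_mean, running_var,
                         training, eps = 1e-5, state_out = NULL) {
  force(x); force(gamma); force(beta)
  v <- tp$vals[[x]]
  d <- dim(v)
  C <- d[3]
  m <- d[1] * d[2] * d[4]
  mu <- numeric(C); va <- numeric(C)
  if (training) {
    for (c in seq_len(C)) {
      xc <- v[, , c, , drop = FALSE]
      mu[c] <- mean(xc)
      va[c] <- mean((xc - mu[c])^2)
    }
    if (!is.null(state_out)) { state_out$mean <- mu; state_out$var <- va }
  } else {
    mu <- running_mean
    va <- running_var
  }
  gv <- tp$vals[[gamma]]; bv <- tp$vals[[beta]]
  xhat <- array(0, dim = d)
  y <- array(0, dim = d)
  inv_sd <- 1 / sqrt(va + eps)
  for (c in seq_len(C)) {
    xhat[, , c, ] <- (v[, , c, , drop = FALSE] - mu[c]) * inv_sd[c]
    y[, , c, ] <- gv[c] * xhat[, , c, , drop = FALSE] + bv[c]
  }
  tp_node(tp, y, c(x, gamma, beta), function(g, tp) {
    gx <- array(0, dim = d)
    ggamma <- numeric(C); gbeta <- numeric(C)
    for (c in seq_len(C)) {
      gc <- g[, , c, , drop = FALSE]
      xh <- xhat[, , c, , drop = FALSE]
      ggamma[c] <- sum(gc * xh)
      gbeta[c] <- sum(gc)
      if (training) {
        gx[, , c, ] <- (gv[c] * inv_sd[c]) *
          (gc - sum(gc) / m - xh * (ggamma[c] / m))
      } else {
        gx[, , c, ] <- gv[c] * inv_sd[c] * gc
      }
    }
    list(gx, ggamma, gbeta)
  })
}
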