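# The three five-level feature extractors. Each consumes a [H,W,C,N] batch
# (KFEM: a complex_tensor batch) and emits a feature pyramid: five real maps
# with channel schedule {32, 64, 128, 256, 512} and spatial size H/2^i at
# level i. The deepest level feeds the decoder bottleneck; the others are
# skip connections.

PYRAMID_CHANNELS <- c(32L, 64L, 128L, 256L, 512L)

#' Check the feature-pyramid contract
#'
#' Validates that `pyr` is a list of five `[H/2^i, W/2^i, Ci, N]` arrays with
#' the standard channel schedule.
#'
#' @param pyr list of five feature arrays.
#' @param H,W input spatial size.
#' @return invisibly `TRUE`; errors otherwise.
#' @export
check_pyramid <- function(pyr, H, W) {
  if (!is.list(pyr) || length(pyr) != 5)
    stopf("feature pyramid must have exactly 5 levels")
  for (i in 1:5) {
    d <- dim(pyr[[i]])
    want <- c(H %/% 2^i, W %/% 2^i, PYRAMID_CHANNELS[i])
    if (!all(d[1:3] == want))
      stopf("pyramid level %d has shape [%s], expected [%s, N]",
            i, paste(d, collapse = ","), paste(want, collapse = ","))
  }
  invisible(TRUE)
}

check_divisible <- function(H, W, by = 32L, what = "input") {
  if (H %% by != 0 || W %% by != 0)
    stopf("%s size %dx%d is not divisible by %d; pad or resize the slices",
          what, H, W, by)
}

# ---- CFEM: U-Net style convolutional encoder ------------------------------

# Level block: Conv3x3 -> BN -> ReLU -> 2x max-pool.
cfem_module <- function(in_ch, channels = PYRAMID_CHANNELS, bias = TRUE) {
  self <- new_module("cfem")
  prev <- in_ch
  for (i in seq_along(channels)) {
    self$layers[[paste0("conv", i)]] <- nn_conv2d(prev, channels[i], 3, 1, 1,
                                                  bias = bias)
    self$layers[[paste0("bn", i)]] <- nn_batchnorm2d(channels[i])
    self$layers[[paste0("relu", i)]] <- nn_relu()
    self$layers[[paste0("pool", i)]] <- nn_maxpool2()
    prev <- channels[i]
  }
  self$n_levels <- length(channels)
  self$forward <- function(x, training = TRUE) {
    check_divisible(dim(x)[1], dim(x)[2])
    pyr <- vector("list", self$n_levels)
    for (i in seq_len(self$n_levels)) {
      x <- self$layers[[paste0("conv", i)]]$forward(x, training)
      x <- self$layers[[paste0("bn", i)]]$forward(x, training)
      x <- self$layers[[paste0("relu", i)]]$forward(x, training)
      x <- self$layers[[paste0("pool", i)]]$forward(x, training)
      pyr[[i]] <- x
    }
    pyr
  }
  self$backward <- function(dpyr) {
    g <- dpyr[[self$n_levels]]
    for (i in self$n_levels:1) {
      g <- self$layers[[paste0("pool", i)]]$backward(g)
      g <- self$layers[[paste0("relu", i)]]$backward(g)
      g <- self$layers[[paste0("bn", i)]]$backward(g)
      g <- self$layers[[paste0("conv", i)]]$backward(g, need_dx = i > 1)
      if (i > 1) g <- dpyr[[i - 1]] + g
    }
    g
  }
  self
}

# ---- TFEM: hierarchical window-attention encoder --------------------------

# Largest window size <= `pref` dividing both spatial dims (7 suits
# 224-derived level sizes; powers of two fall back to 4, 2, 1).
pick_window <- function(h, w, pref = 7L) {
  for (s in seq(min(pref, h, w), 1L)) if (h %% s == 0 && w %% s == 0) return(s)
  1L
}

# [H,W,C,N] -> [T, C, B] token windows (T = win^2, B = nH*nW*N) and back.
win_partition <- function(x, win) {
  d <- dim(x)
  nh <- d[1] %/% win; nw <- d[2] %/% win
  y <- aperm(array(x, c(win, nh, win, nw, d[3], d[4])), c(1, 3, 5, 2, 4, 6))
  dim(y) <- c(win * win, d[3], nh * nw * d[4])
  y
}

win_merge <- function(y, win, d) {
  nh <- d[1] %/% win; nw <- d[2] %/% win
  dim(y) <- c(win, win, d[3], nh, nw, d[4])
  x <- aperm(y, c(1, 4, 2, 5, 3, 6))
  dim(x) <- d
  x
}

# Single-head self-attention within non-overlapping windows. Caches the
# attention probabilities for the backward pass (and for inspection via
# `keep_attn`).
nn_window_attention <- function(C, window = 7L) {
  self <- new_module("window_attention")
  self$C <- C; self$window <- window
  self$layers <- list(q = nn_conv2d(C, C, 1, 1, 0, scheme = "xavier"),
                      k = nn_conv2d(C, C, 1, 1, 0, scheme = "xavier"),
                      v = nn_conv2d(C, C, 1, 1, 0, scheme = "xavier"))
  self$keep_attn <- FALSE
  self$forward <- function(x, training = TRUE) {
    d <- dim(x)
    win <- pick_window(d[1], d[2], self$window)
    Q <- win_partition(self$layers$q$forward(x, training), win)
    K <- win_partition(self$layers$k$forward(x, training), win)
    V <- win_partition(self$layers$v$forward(x, training), win)
    B <- dim(Q)[3]
    O <- array(0, dim(Q))
    P <- vector("list", B)
    sc <- 1 / sqrt(C)
    for (bi in seq_len(B)) {
      S <- (Q[, , bi] %*% t(K[, , bi])) * sc
      S <- S - apply(S, 1, max)
      E <- exp(S)
      Pb <- E / rowSums(E)
      O[, , bi] <- Pb %*% V[, , bi]
      P[[bi]] <- Pb
    }
    self$cache <- list(Q = Q, K = K, V = V, P = P, d = d, win = win)
    if (self$keep_attn) self$last_attn <- P
    win_merge(O, win, d)
  }
  self$backward <- function(dy) {
    cc <- self$cache
    dO <- win_partition(dy, cc$win)
    dQ <- array(0, dim(cc$Q)); dK <- dQ; dV <- dQ
    sc <- 1 / sqrt(self$C)
    for (bi in seq_len(dim(dO)[3])) {
      Pb <- cc$P[[bi]]
      dOb <- dO[, , bi]
      dV[, , bi] <- t(Pb) %*% dOb
      dP <- dOb %*% t(cc$V[, , bi])
      dS <- Pb * (dP - rowSums(dP * Pb))
      dQ[, , bi] <- (dS %*% cc$K[, , bi]) * sc
      dK[, , bi] <- (t(dS) %*% cc$Q[, , bi]) * sc
    }
    d <- cc$d
    self$cache <- NULL
    self$layers$q$backward(win_merge(dQ, cc$win, d)) +
      self$layers$k$backward(win_merge(dK, cc$win, d)) +
      self$layers$v$backward(win_merge(dV, cc$win, d))
  }
  self
}

# Level block: 2x2 stride-2 patch-merge projection, then a pre-norm
# window-attention residual: y = pm(x); out = y + proj(attn(LN(y))).
tfem_module <- function(in_ch, channels = PYRAMID_CHANNELS, window = 7L) {
  self <- new_module("tfem")
  prev <- in_ch
  for (i in seq_along(channels)) {
    self$layers[[paste0("pm", i)]] <- nn_conv2d(prev, channels[i], 2, 2, 0,
                                                scheme = "xavier")
    self$layers[[paste0("ln", i)]] <- nn_layernorm_ch(channels[i])
    self$layers[[paste0("attn", i)]] <- nn_window_attention(channels[i], window)
    self$layers[[paste0("proj", i)]] <- nn_conv2d(channels[i], channels[i],
                                                  1, 1, 0, scheme = "xavier")
    prev <- channels[i]
  }
  self$n_levels <- length(channels)
  self$forward <- function(x, training = TRUE) {
    check_divisible(dim(x)[1], dim(x)[2])
    pyr <- vector("list", self$n_levels)
    for (i in seq_len(self$n_levels)) {
      y <- self$layers[[paste0("pm", i)]]$forward(x, training)
      a <- self$layers[[paste0("ln", i)]]$forward(y, training)
      a <- self$layers[[paste0("attn", i)]]$forward(a, training)
      a <- self$layers[[paste0("proj", i)]]$forward(a, training)
      x <- y + a
      pyr[[i]] <- x
    }
    pyr
  }
  self$backward <- function(dpyr) {
    g <- dpyr[[self$n_levels]]
    for (i in self$n_levels:1) {
      da <- self$layers[[paste0("proj", i)]]$backward(g)
      da <- self$layers[[paste0("attn", i)]]$backward(da)
      dy <- g + self$layers[[paste0("ln", i)]]$backward(da)
      g <- self$layers[[paste0("pm", i)]]$backward(dy, need_dx = i > 1)
      if (i > 1) g <- dpyr[[i - 1]] + g
    }
    g
  }
  self
}

# ---- KFEM: complex-convolution K-space encoder ----------------------------

# Level block: complex conv (3x3, stride 2) -> split complex norm -> CReLU,
# with a per-level magnitude tap producing the real pyramid. Down-sampling
# is by strided complex convolution (no complex pooling is defined).
kfem_module <- function(in_ch, channels = PYRAMID_CHANNELS,
                        norm = c("batch", "layer", "none"),
                        activation = TRUE, bias = TRUE) {
  norm <- match.arg(norm)
  self <- new_module("kfem")
  prev <- in_ch
  for (i in seq_along(channels)) {
    self$layers[[paste0("cconv", i)]] <- nn_cconv2d(prev, channels[i], 3, 2, 1,
                                                    bias = bias)
    if (norm != "none")
      self$layers[[paste0("cnorm", i)]] <- nn_cnorm(channels[i], norm)
    if (activation)
      self$layers[[paste0("crelu", i)]] <- nn_crelu()
    prev <- channels[i]
  }
  self$n_levels <- length(channels)
  self$mag_eps <- 1e-12
  self$forward <- function(x, training = TRUE) {
    # accepts a complex_tensor batch, or a kspace_grid (single slice)
    if (inherits(x, "kspace_grid")) {
      if (!all(x$mask))
        stopf("kfem: grid is partially sampled; run conjugate_complete() first")
      x <- complex_tensor(as_hwcn(Re(x$data)), as_hwcn(Im(x$data)))
    }
    stopifnot(inherits(x, "complex_tensor"))
    check_divisible(dim(x$real)[1], dim(x$real)[2])
    pyr <- vector("list", self$n_levels)
    self$taps <- vector("list", self$n_levels)
    for (i in seq_len(self$n_levels)) {
      x <- self$layers[[paste0("cconv", i)]]$forward(x, training)
      nl <- self$layers[[paste0("cnorm", i)]]
      if (!is.null(nl)) x <- nl$forward(x, training)
      al <- self$layers[[paste0("crelu", i)]]
      if (!is.null(al)) x <- al$forward(x, training)
      mag <- sqrt(x$real^2 + x$imag^2)
      self$taps[[i]] <- list(a = x$real, b = x$imag,
                             inv = 1 / pmax(mag, self$mag_eps))
      pyr[[i]] <- mag
    }
    pyr
  }
  self$backward <- function(dpyr) {
    mag_bwd <- function(i, dm) {
      tp <- self$taps[[i]]
      complex_tensor(dm * tp$a * tp$inv, dm * tp$b * tp$inv)
    }
    g <- mag_bwd(self$n_levels, dpyr[[self$n_levels]])
    for (i in self$n_levels:1) {
      al <- self$layers[[paste0("crelu", i)]]
      if (!is.null(al)) g <- al$backward(g)
      nl <- self$layers[[paste0("cnorm", i)]]
      if (!is.null(nl)) g <- nl$backward(g)
      g <- self$layers[[paste0("cconv", i)]]$backward(g, need_dx = i > 1)
      if (i > 1) g <- ct_add(g, mag_bwd(i - 1, dpyr[[i - 1]]))
    }
    self$taps <- NULL
    g
  }
  self
}

#' Encoder forward passes
#'
#' Convenience functional wrappers running one encoder on a single slice
#' (or batch) and returning the five-level feature pyramid. `cfem_forward`
#' is the convolutional image encoder, `tfem_forward` the hierarchical
#' window-attention encoder, `kfem_forward` the complex-valued K-space
#' encoder (which requires a fully sampled grid; see
#' [conjugate_complete()]).
#'
#' @param encoder a module built by [build_model()] internals or the
#'   `*_module` constructors.
#' @param x input: real `[H, W, C]` / `[H, W, C, N]` array, or for
#'   `kfem_forward` a [kspace_grid()] or [complex_tensor()].
#' @param training use batch statistics (`TRUE`) or running statistics.
#' @return list of five feature arrays `[H/2^i, W/2^i, Ci, N]`.
#' @name encoder-forward
NULL

#' @rdname encoder-forward
#' @export
cfem_forward <- function(encoder, x, training = FALSE) {
  encoder$forward(as_hwcn(x), training)
}

#' @rdname encoder-forward
#' @export
tfem_forward <- function(encoder, x, training = FALSE) {
  encoder$forward(as_hwcn(x), training)
}

#' @rdname encoder-forward
#' @export
kfem_forward <- function(encoder, x, training = FALSE) {
  encoder$forward(x, training)
}
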