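# Minimal trainable-layer framework.
#
# A layer is an environment with:
#   $params  - character vector of trainable field names (e.g. "W", "b");
#              gradients accumulate in fields prefixed "g_"
#   $buffers - character vector of non-trainable state (running stats)
#   $forward(x, training) / $backward(dy)
# A module is an environment with $layers (a named list of layers and/or
# sub-modules) plus its own forward/backward closures. `collect_layers()`
# flattens a module tree for the optimizer and for checkpointing.
# Parameter initialization draws from the caller's RNG stream, so a model
# built under set.seed() is reproducible.

new_layer <- function(kind) {
  self <- new.env(parent = emptyenv())
  self$kind <- kind
  self$params <- character()
  self$buffers <- character()
  class(self) <- c(paste0("nn_", kind), "nn_layer")
  self
}

new_module <- function(kind) {
  self <- new.env(parent = emptyenv())
  self$kind <- kind
  self$layers <- list()
  class(self) <- c(paste0("nn_", kind), "nn_module")
  self
}

# ---- weight banks ---------------------------------------------------------

# Weight matrix [kh*kw*Cin, Cout] with He (fan-in) or Xavier init.
init_weight_mat <- function(in_ch, out_ch, kh, kw, scheme = c("he", "xavier")) {
  scheme <- match.arg(scheme)
  fan_in <- kh * kw * in_ch
  sd <- if (scheme == "he") sqrt(2 / fan_in) else sqrt(1 / fan_in)
  matrix(stats::rnorm(fan_in * out_ch, sd = sd), nrow = fan_in, ncol = out_ch)
}

# Convert between a [kh,kw,Cin,Cout] kernel array and the im2col weight
# matrix layout (row q = ki + kh*(kj + kw*c)).
kernel_to_mat <- function(k4) {
  d <- dim(k4)
  matrix(k4, nrow = d[1] * d[2] * d[3], ncol = d[4])
}

mat_to_kernel <- function(m, kh, kw, in_ch) {
  array(m, c(kh, kw, in_ch, ncol(m)))
}

# ---- real 2D convolution --------------------------------------------------

#' 2D convolution layer
#'
#' Cross-correlation with an im2col + GEMM forward pass and analytic
#' backward pass; weights in the `[kh*kw*Cin, Cout]` matrix layout.
#'
#' @param in_ch,out_ch channel counts.
#' @param kernel kernel size (square).
#' @param stride,pad stride and zero padding.
#' @param bias include an additive bias per output channel.
#' @param scheme weight init scheme (`"he"` for ReLU stacks, `"xavier"`
#'   for linear projections).
#' @return an `nn_layer` environment.
#' @keywords internal
nn_conv2d <- function(in_ch, out_ch, kernel = 3, stride = 1, pad = 1,
                      bias = TRUE, scheme = "he") {
  self <- new_layer("conv2d")
  self$in_ch <- in_ch; self$out_ch <- out_ch
  self$kh <- kernel; self$kw <- kernel
  self$stride <- stride; self$pad <- pad
  self$W <- init_weight_mat(in_ch, out_ch, kernel, kernel, scheme)
  self$g_W <- self$W * 0
  self$params <- "W"
  if (bias) {
    self$b <- numeric(out_ch)
    self$g_b <- numeric(out_ch)
    self$params <- c("W", "b")
  }
  self$forward <- function(x, training = TRUE) {
    if (dim(x)[3] != self$in_ch)
      stopf("conv2d: expected %d input channels, got %d", self$in_ch, dim(x)[3])
    self$x <- x
    conv2d_fwd_cpp(x, self$W, if (is.null(self$b)) numeric(0) else self$b,
                   self$kh, self$kw, self$stride, self$pad)
  }
  self$backward <- function(dy, need_dx = TRUE) {
    r <- conv2d_bwd_cpp(self$x, self$W, dy, self$kh, self$kw,
                        self$stride, self$pad, need_dx, !is.null(self$b))
    self$g_W <- self$g_W + r$dW
    if (!is.null(self$b)) self$g_b <- self$g_b + r$db
    self$x <- NULL
    r$dx
  }
  self
}

# ---- normalization --------------------------------------------------------

# Column-wise standardization of a matrix: each column is one reduction
# group. Returns xhat and the pieces needed for the backward pass.
colnorm_fwd <- function(xm, eps) {
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu, "-")
  v <- colMeans(xc * xc)
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, istd, "*")
  list(xhat = xhat, istd = istd, mu = mu, var = v)
}

colnorm_bwd <- function(dxhat, xhat, istd) {
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  sweep(dxhat - sweep(xhat, 2, m2, "*"), 2, m1, "-") |>
    sweep(2, istd, "*")
}

#' Batch normalization over (H, W, N) per channel
#' @keywords internal
nn_batchnorm2d <- function(C, eps = 1e-5, momentum = 0.1, affine = TRUE) {
  self <- new_layer("batchnorm2d")
  self$C <- C; self$eps <- eps; self$momentum <- momentum
  self$running_mean <- numeric(C)
  self$running_var <- rep(1, C)
  self$buffers <- c("running_mean", "running_var")
  if (affine) {
    self$gamma <- rep(1, C); self$beta <- numeric(C)
    self$g_gamma <- numeric(C); self$g_beta <- numeric(C)
    self$params <- c("gamma", "beta")
  }
  self$forward <- function(x, training = TRUE) {
    d <- dim(x)
    xm <- matrix(aperm(array(x, c(d[1] * d[2], d[3], d[4])), c(1, 3, 2)),
                 ncol = d[3])
    if (training) {
      f <- colnorm_fwd(xm, self$eps)
      mom <- self$momentum
      self$running_mean <- (1 - mom) * self$running_mean + mom * f$mu
      self$running_var <- (1 - mom) * self$running_var + mom * f$var
      self$xhat <- f$xhat; self$istd <- f$istd
      xh <- f$xhat
    } else {
      xh <- sweep(sweep(xm, 2, self$running_mean, "-"), 2,
                  1 / sqrt(self$running_var + self$eps), "*")
    }
    y <- if (is.null(self$gamma)) xh
         else sweep(sweep(xh, 2, self$gamma, "*"), 2, self$beta, "+")
    self$d <- d
    aperm(array(y, c(d[1] * d[2], d[4], d[3])), c(1, 3, 2)) |>
      array(dim = d)
  }
  self$backward <- function(dy) {
    d <- self$d
    dym <- matrix(aperm(array(dy, c(d[1] * d[2], d[3], d[4])), c(1, 3, 2)),
                  ncol = d[3])
    if (!is.null(self$gamma)) {
      self$g_gamma <- self$g_gamma + colSums(dym * self$xhat)
      self$g_beta <- self$g_beta + colSums(dym)
      dxhat <- sweep(dym, 2, self$gamma, "*")
    } else dxhat <- dym
    dxm <- colnorm_bwd(dxhat, self$xhat, self$istd)
    self$xhat <- NULL
    aperm(array(dxm, c(d[1] * d[2], d[4], d[3])), c(1, 3, 2)) |>
      array(dim = d)
  }
  self
}

#' Instance normalization over (H, W) per channel and sample
#' @keywords internal
nn_instancenorm2d <- function(C, eps = 1e-5, affine = TRUE) {
  self <- new_layer("instancenorm2d")
  self$C <- C; self$eps <- eps
  if (affine) {
    self$gamma <- rep(1, C); self$beta <- numeric(C)
    self$g_gamma <- numeric(C); self$g_beta <- numeric(C)
    self$params <- c("gamma", "beta")
  }
  self$forward <- function(x, training = TRUE) {
    d <- dim(x)
    xm <- matrix(x, nrow = d[1] * d[2])        # columns: (c, n) pairs
    f <- colnorm_fwd(xm, self$eps)
    self$xhat <- f$xhat; self$istd <- f$istd; self$d <- d
    g <- rep(self$gamma %||% rep(1, d[3]), times = d[4])
    b <- rep(self$beta %||% numeric(d[3]), times = d[4])
    array(sweep(sweep(f$xhat, 2, g, "*"), 2, b, "+"), d)
  }
  self$backward <- function(dy) {
    d <- self$d
    dym <- matrix(dy, nrow = d[1] * d[2])
    if (!is.null(self$gamma)) {
      gs <- colSums(dym * self$xhat)
      bs <- colSums(dym)
      self$g_gamma <- self$g_gamma + rowSums(matrix(gs, d[3], d[4]))
      self$g_beta <- self$g_beta + rowSums(matrix(bs, d[3], d[4]))
      dxhat <- sweep(dym, 2, rep(self$gamma, times = d[4]), "*")
    } else dxhat <- dym
    dxm <- colnorm_bwd(dxhat, self$xhat, self$istd)
    self$xhat <- NULL
    array(dxm, d)
  }
  self
}

#' Layer normalization over channels per spatial position
#'
#' The token normalization used by the window-attention encoder: each
#' position (h, w, n) is standardized over its C channels.
#' @keywords internal
nn_layernorm_ch <- function(C, eps = 1e-5, affine = TRUE) {
  self <- new_layer("layernorm_ch")
  self$C <- C; self$eps <- eps
  if (affine) {
    self$gamma <- rep(1, C); self$beta <- numeric(C)
    self$g_gamma <- numeric(C); self$g_beta <- numeric(C)
    self$params <- c("gamma", "beta")
  }
  self$forward <- function(x, training = TRUE) {
    d <- dim(x)
    # [C, H*W*N] with channels as rows -> columns are reduction groups
    xm <- matrix(aperm(array(x, c(d[1] * d[2], d[3], d[4])), c(2, 1, 3)),
                 nrow = d[3])
    f <- colnorm_fwd(xm, self$eps)
    self$xhat <- f$xhat; self$istd <- f$istd; self$d <- d
    y <- if (is.null(self$gamma)) f$xhat else self$gamma * f$xhat + self$beta
    aperm(array(y, c(d[3], d[1] * d[2], d[4])), c(2, 1, 3)) |>
      array(dim = d)
  }
  self$backward <- function(dy) {
    d <- self$d
    dym <- matrix(aperm(array(dy, c(d[1] * d[2], d[3], d[4])), c(2, 1, 3)),
                  nrow = d[3])
    if (!is.null(self$gamma)) {
      self$g_gamma <- self$g_gamma + rowSums(dym * self$xhat)
      self$g_beta <- self$g_beta + rowSums(dym)
      dxhat <- self$gamma * dym
    } else dxhat <- dym
    dxm <- colnorm_bwd(dxhat, self$xhat, self$istd)
    self$xhat <- NULL
    aperm(array(dxm, c(d[3], d[1] * d[2], d[4])), c(2, 1, 3)) |>
      array(dim = d)
  }
  self
}

# ---- stateless activations / resampling -----------------------------------

nn_relu <- function() {
  self <- new_layer("relu")
  self$forward <- function(x, training = TRUE) {
    self$mask <- x > 0
    x * self$mask
  }
  self$backward <- function(dy) {
    dx <- dy * self$mask
    self$mask <- NULL
    dx
  }
  self
}

nn_sigmoid <- function() {
  self <- new_layer("sigmoid")
  self$forward <- function(x, training = TRUE) {
    y <- 1 / (1 + exp(-x))
    self$y <- y
    y
  }
  self$backward <- function(dy) {
    dx <- dy * self$y * (1 - self$y)
    self$y <- NULL
    dx
  }
  self
}

nn_maxpool2 <- function() {
  self <- new_layer("maxpool2")
  self$forward <- function(x, training = TRUE) {
    r <- maxpool2_fwd_cpp(x)
    self$idx <- r$idx
    r$y
  }
  self$backward <- function(dy) {
    dx <- maxpool2_bwd_cpp(dy, self$idx)
    self$idx <- NULL
    dx
  }
  self
}

nn_upsample2 <- function() {
  self <- new_layer("upsample2")
  self$forward <- function(x, training = TRUE) upsample2_fwd_cpp(x)
  self$backward <- function(dy) upsample2_bwd_cpp(dy)
  self
}

# ---- module plumbing ------------------------------------------------------

# Flatten a module tree into a named list of primitive layers.
collect_layers <- function(x, prefix = "") {
  if (inherits(x, "nn_layer")) {
    out <- list(x); names(out) <- prefix
    return(out)
  }
  kids <- if (inherits(x, "nn_module")) x$layers else x
  out <- list()
  for (nm in names(kids)) {
    sub <- collect_layers(kids[[nm]],
                          if (nzchar(prefix)) paste(prefix, nm, sep = ".") else nm)
    out <- c(out, sub)
  }
  out
}

zero_grads <- function(layers) {
  for (l in layers)
    for (p in l$params) l[[paste0("g_", p)]] <- l[[p]] * 0
  invisible(NULL)
}

#' Number of trainable parameters in a module tree
#' @param module a network module.
#' @return integer count.
#' @export
count_params <- function(module) {
  ls <- collect_layers(module)
  sum(vapply(ls, function(l) sum(vapply(l$params, function(p)
    length(l[[p]]), 1L)), 1L))
}

# Serializable snapshot of all parameters and buffers.
state_dict <- function(module) {
  ls <- collect_layers(module)
  lapply(ls, function(l) {
    s <- lapply(c(l$params, l$buffers), function(p) l[[p]])
    names(s) <- c(l$params, l$buffers)
    s
  })
}

load_state_dict <- function(module, state) {
  ls <- collect_layers(module)
  if (!setequal(names(ls), names(state)))
    stopf("checkpoint does not match the model architecture")
  for (nm in names(ls)) {
    l <- ls[[nm]]
    for (p in names(state[[nm]])) {
      v <- state[[nm]][[p]]
      if (length(v) != length(l[[p]]))
        stopf("checkpoint field %s.%s has wrong size", nm, p)
      # copy, so later in-place optimizer updates never alias the snapshot
      l[[p]] <- if (is.numeric(v)) v + 0 else v
    }
  }
  invisible(module)
}

# ---- Adam -----------------------------------------------------------------

adam_step <- function(layers, lr = 3e-4, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (l in layers) {
    if (is.null(l$adam_t)) l$adam_t <- 0L
    l$adam_t <- l$adam_t + 1L
    for (p in l$params) {
      mkey <- paste0("adam_m_", p); vkey <- paste0("adam_v_", p)
      if (is.null(l[[mkey]])) {
        l[[mkey]] <- l[[p]] * 0
        l[[vkey]] <- l[[p]] * 0
      }
      # in-place update of the parameter and moment buffers
      adam_update_cpp(l[[p]], l[[paste0("g_", p)]], l[[mkey]], l[[vkey]],
                      lr, beta1, beta2, eps, l$adam_t)
    }
  }
  invisible(NULL)
}
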