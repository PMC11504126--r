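# Dual-path attention feature fusion (DAFFM).
#
# Given an image-domain feature xi and a K-space-domain feature xk of equal
# shape, a shared sum X = xi + xk drives two sigmoid gates:
#   local:  Wl = sigmoid(BN(Conv1x1(ReLU(BN(Conv1x1(X))))))       (per position)
#           xl = xi * Wl + xk * (1 - Wl)
#   global: same bottleneck on the globally average-pooled descriptor,
#           Wg broadcast over space, with the printed role reversal:
#           xg = xi * (1 - Wg) + xk * Wg
# Output = xl + xg. Both bottlenecks reduce C -> C/r -> C (r = 4 default).
# Note the deliberate asymmetry: Wl weights xi while Wg weights xk, exactly
# as the defining equations are printed.

daffm_module <- function(C, r = 4L) {
  self <- new_module("daffm")
  cr <- max(1L, C %/% r)
  self$C <- C
  self$layers <- list(
    l_conv1 = nn_conv2d(C, cr, 1, 1, 0), l_bn1 = nn_batchnorm2d(cr),
    l_relu = nn_relu(),
    l_conv2 = nn_conv2d(cr, C, 1, 1, 0), l_bn2 = nn_batchnorm2d(C),
    l_sig = nn_sigmoid(),
    g_conv1 = nn_conv2d(C, cr, 1, 1, 0), g_bn1 = nn_batchnorm2d(cr),
    g_relu = nn_relu(),
    g_conv2 = nn_conv2d(cr, C, 1, 1, 0), g_bn2 = nn_batchnorm2d(C),
    g_sig = nn_sigmoid())

  gate <- function(prefix, x, training) {
    L <- self$layers
    z <- L[[paste0(prefix, "_conv1")]]$forward(x, training)
    z <- L[[paste0(prefix, "_bn1")]]$forward(z, training)
    z <- L[[paste0(prefix, "_relu")]]$forward(z, training)
    z <- L[[paste0(prefix, "_conv2")]]$forward(z, training)
    z <- L[[paste0(prefix, "_bn2")]]$forward(z, training)
    L[[paste0(prefix, "_sig")]]$forward(z, training)
  }
  gate_bwd <- function(prefix, dw) {
    L <- self$layers
    dz <- L[[paste0(prefix, "_sig")]]$backward(dw)
    dz <- L[[paste0(prefix, "_bn2")]]$backward(dz)
    dz <- L[[paste0(prefix, "_conv2")]]$backward(dz)
    dz <- L[[paste0(prefix, "_relu")]]$backward(dz)
    dz <- L[[paste0(prefix, "_bn1")]]$backward(dz)
    L[[paste0(prefix, "_conv1")]]$backward(dz)
  }

  self$local_forward <- function(xi, xk, training = TRUE) {
    Wl <- gate("l", xi + xk, training)
    self$c_l <- list(xi = xi, xk = xk, Wl = Wl)
    xi * Wl + xk * (1 - Wl)
  }
  self$global_forward <- function(xi, xk, training = TRUE) {
    X <- xi + xk
    d <- dim(X)
    g <- array(colMeans(matrix(X, nrow = d[1] * d[2])), c(1, 1, d[3], d[4]))
    Wg <- gate("g", g, training)
    self$c_g <- list(xi = xi, xk = xk, Wg = Wg, d = d)
    wg_full <- aperm(array(Wg[1, 1, , ], c(d[3], d[4], d[1] * d[2])),
                     c(3, 1, 2))
    dim(wg_full) <- d
    self$c_g$wg_full <- wg_full
    xi * (1 - wg_full) + xk * wg_full
  }

  self$forward <- function(xi, xk, training = TRUE) {
    if (!identical(dim(xi), dim(xk)))
      stopf("daffm: feature shapes differ")
    self$local_forward(xi, xk, training) +
      self$global_forward(xi, xk, training)
  }

  self$local_backward <- function(dy) {
    cc <- self$c_l
    dWl <- dy * (cc$xi - cc$xk)
    dX <- gate_bwd("l", dWl)
    list(dxi = dy * cc$Wl + dX, dxk = dy * (1 - cc$Wl) + dX)
  }
  self$global_backward <- function(dy) {
    cc <- self$c_g
    d <- cc$d
    dWg_full <- dy * (cc$xk - cc$xi)
    dWg <- array(colSums(matrix(dWg_full, nrow = d[1] * d[2])),
                 c(1, 1, d[3], d[4]))
    dg <- gate_bwd("g", dWg)
    dX_each <- aperm(array(dg[1, 1, , ] / (d[1] * d[2]),
                           c(d[3], d[4], d[1] * d[2])), c(3, 1, 2))
    dim(dX_each) <- d
    list(dxi = dy * (1 - cc$wg_full) + dX_each,
         dxk = dy * cc$wg_full + dX_each)
  }
  self$backward <- function(dy) {
    a <- self$local_backward(dy)
    b <- self$global_backward(dy)
    self$c_l <- NULL; self$c_g <- NULL
    list(dxi = a$dxi + b$dxi, dxk = a$dxk + b$dxk)
  }
  self
}

# Parameter-free elementwise-addition fusion (ablation No.3).
add_fusion_module <- function() {
  self <- new_module("add_fusion")
  self$forward <- function(xi, xk, training = TRUE) xi + xk
  self$backward <- function(dy) list(dxi = dy, dxk = dy)
  self
}

# Promote [H,W,C] pairs to batch-1 and run a fusion path.
fusion_call <- function(m, xi, xk, fn, training) {
  single <- length(dim(xi)) == 3
  xi <- as_hwcn(xi); xk <- as_hwcn(xk)
  if (!identical(dim(xi), dim(xk))) stopf("fusion: feature shapes differ")
  y <- fn(xi, xk, training)
  if (single) dim(y) <- dim(y)[1:3]
  y
}

#' Dual-path attention feature fusion
#'
#' `daffm_create()` builds a fusion module for `C`-channel features with
#' bottleneck ratio `r`. `local_fusion()` computes the per-position
#' sigmoid-gated convex combination `xi * Wl + xk * (1 - Wl)`;
#' `global_fusion()` pools the shared sum to a per-channel descriptor and
#' applies the reversed gate `xi * (1 - Wg) + xk * Wg`; `daffm_forward()`
#' returns their sum.
#'
#' @param C channel count of the fused features.
#' @param r bottleneck reduction ratio of the two pointwise convolutions.
#' @param m a module from `daffm_create()`.
#' @param xi,xk image-domain and K-space-domain features, `[H, W, C]` or
#'   `[H, W, C, N]`, identical shapes.
#' @param training use batch statistics in the gate normalizations.
#' @return `daffm_create`: a fusion module; the others: a real array shaped
#'   like `xi`.
#' @export
daffm_create <- function(C, r = 4L) daffm_module(C, r)

#' @rdname daffm_create
#' @export
local_fusion <- function(m, xi, xk, training = TRUE)
  fusion_call(m, xi, xk, m$local_forward, training)

#' @rdname daffm_create
#' @export
global_fusion <- function(m, xi, xk, training = TRUE)
  fusion_call(m, xi, xk, m$global_forward, training)

#' @rdname daffm_create
#' @export
daffm_forward <- function(m, xi, xk, training = TRUE)
  fusion_call(m, xi, xk, m$forward, training)
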