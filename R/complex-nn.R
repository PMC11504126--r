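# Complex-valued network primitives.
#
# A complex convolution W * x with W = A + iB and x = a + ib is realized by
# four real convolutions:
#   Re(W * x) = A*a - B*b      Im(W * x) = B*a + A*b
# CReLU and the split normalizations apply the real operation independently
# to the real and imaginary parts.

#' Complex convolution kernel
#'
#' @param real_weights,imag_weights real arrays `[kh, kw, Cin, Cout]`
#'   (the A and B banks of `W = A + iB`).
#' @param bias optional complex vector of length `Cout`.
#' @return object of class `complex_kernel`.
#' @export
complex_kernel <- function(real_weights, imag_weights, bias = NULL) {
  if (!identical(dim(real_weights), dim(imag_weights)))
    stopf("complex_kernel: weight bank shapes differ")
  if (length(dim(real_weights)) != 4)
    stopf("complex_kernel: weights must be [kh, kw, Cin, Cout]")
  if (!is.null(bias) && length(bias) != dim(real_weights)[4])
    stopf("complex_kernel: bias length != Cout")
  structure(list(real_weights = real_weights, imag_weights = imag_weights,
                 bias = if (!is.null(bias)) as.complex(bias)),
            class = "complex_kernel")
}

#' 2D complex convolution
#'
#' Computes `W * x = (A*a - B*b) + i(B*a + A*b)` for a complex input
#' `x = a + ib` and complex kernel `W = A + iB`, via four real convolutions.
#'
#' @param x a [complex_tensor()] of shape `[H, W, Cin]` or `[H, W, Cin, N]`.
#' @param W a [complex_kernel()].
#' @param stride,padding convolution stride and zero padding.
#' @return a [complex_tensor()] of the convolved shape.
#' @export
complex_conv2d <- function(x, W, stride = 1, padding = 0) {
  stopifnot(inherits(x, "complex_tensor"), inherits(W, "complex_kernel"))
  dk <- dim(W$real_weights)
  single <- length(dim(x$real)) == 3
  a <- as_hwcn(x$real); b <- as_hwcn(x$imag)
  if (dim(a)[3] != dk[3])
    stopf("complex_conv2d: input has %d channels, kernel expects %d",
          dim(a)[3], dk[3])
  if (stride < 1) stopf("complex_conv2d: stride must be >= 1")
  A <- kernel_to_mat(W$real_weights)
  B <- kernel_to_mat(W$imag_weights)
  nb <- numeric(0)
  cv <- function(xx, mm) conv2d_fwd_cpp(xx, mm, nb, dk[1], dk[2],
                                        stride, padding)
  yr <- cv(a, A) - cv(b, B)
  yi <- cv(a, B) + cv(b, A)
  if (!is.null(W$bias)) {
    d <- dim(yr)
    br <- rep(rep(Re(W$bias), each = d[1] * d[2]), times = d[4])
    bi <- rep(rep(Im(W$bias), each = d[1] * d[2]), times = d[4])
    yr <- yr + array(br, d); yi <- yi + array(bi, d)
  }
  if (single) {
    dim(yr) <- dim(yr)[1:3]; dim(yi) <- dim(yi)[1:3]
  }
  complex_tensor(yr, yi)
}

#' Complex ReLU
#'
#' `CReLU(K) = ReLU(Kr) + i ReLU(Ki)`: the rectifier applied independently
#' to the real and imaginary parts.
#'
#' @param x a [complex_tensor()].
#' @return a [complex_tensor()].
#' @export
crelu <- function(x) {
  stopifnot(inherits(x, "complex_tensor"))
  complex_tensor(pmax(x$real, 0), pmax(x$imag, 0))
}

#' Split complex normalization
#'
#' The chosen real normalization applied separately to the real and
#' imaginary parts: `CLN(K) = LN(Kr) + i LN(Ki)` for layer mode, and the
#' batch-statistics analogue for batch mode.
#'
#' Layer mode standardizes each sample over all of its elements; batch mode
#' standardizes each channel over (H, W, N). This is the "split" variant (no
#' covariance whitening between the two parts).
#'
#' @param x a [complex_tensor()] of shape `[H, W, C]` or `[H, W, C, N]`.
#' @param mode `"batch"` or `"layer"`.
#' @param eps variance guard.
#' @return a [complex_tensor()] with standardized parts.
#' @export
complex_norm <- function(x, mode = c("batch", "layer"), eps = 1e-5) {
  stopifnot(inherits(x, "complex_tensor"))
  mode <- match.arg(mode)
  single <- length(dim(x$real)) == 3
  re <- as_hwcn(x$real); im <- as_hwcn(x$imag)
  d <- dim(re)
  norm_part <- function(p) {
    xm <- if (mode == "layer") matrix(p, ncol = d[4])
          else matrix(aperm(array(p, c(d[1] * d[2], d[3], d[4])), c(1, 3, 2)),
                      ncol = d[3])
    y <- colnorm_fwd(xm, eps)$xhat
    if (mode == "layer") array(y, d)
    else array(aperm(array(y, c(d[1] * d[2], d[4], d[3])), c(1, 3, 2)), d)
  }
  yr <- norm_part(re); yi <- norm_part(im)
  if (single) { dim(yr) <- d[1:3]; dim(yi) <- d[1:3] }
  complex_tensor(yr, yi)
}

# ---- trainable complex layers --------------------------------------------

# Complex conv layer: two real weight banks, complex bias, backward pass by
# the chain rule through the four real convolutions.
nn_cconv2d <- function(in_ch, out_ch, kernel = 3, stride = 1, pad = 1,
                       bias = TRUE) {
  self <- new_layer("cconv2d")
  self$in_ch <- in_ch; self$out_ch <- out_ch
  self$kh <- kernel; self$kw <- kernel
  self$stride <- stride; self$pad <- pad
  # He fan-in applied independently to each bank
  self$Wr <- init_weight_mat(in_ch, out_ch, kernel, kernel, "he")
  self$Wi <- init_weight_mat(in_ch, out_ch, kernel, kernel, "he")
  self$g_Wr <- self$Wr * 0; self$g_Wi <- self$Wi * 0
  self$params <- c("Wr", "Wi")
  if (bias) {
    self$br <- numeric(out_ch); self$bi <- numeric(out_ch)
    self$g_br <- numeric(out_ch); self$g_bi <- numeric(out_ch)
    self$params <- c(self$params, "br", "bi")
  }
  nb <- numeric(0)
  self$forward <- function(x, training = TRUE) {
    self$a <- x$real; self$b <- x$imag
    cv <- function(xx, mm, bb) conv2d_fwd_cpp(xx, mm, bb, self$kh, self$kw,
                                              self$stride, self$pad)
    yr <- cv(x$real, self$Wr, self$br %||% nb) -
      conv2d_fwd_cpp(x$imag, self$Wi, nb, self$kh, self$kw, self$stride, self$pad)
    yi <- cv(x$real, self$Wi, self$bi %||% nb) +
      conv2d_fwd_cpp(x$imag, self$Wr, nb, self$kh, self$kw, self$stride, self$pad)
    complex_tensor(yr, yi)
  }
  self$backward <- function(dy, need_dx = TRUE) {
    # dy: complex_tensor of gradients (dyr, dyi)
    bw <- function(x, W, g, db) conv2d_bwd_cpp(x, W, g, self$kh, self$kw,
                                               self$stride, self$pad,
                                               need_dx, db)
    has_b <- !is.null(self$br)
    r_ar <- bw(self$a, self$Wr, dy$real, has_b)   # via A*a in Re
    r_bi <- bw(self$b, self$Wi, dy$real, FALSE)   # via -B*b in Re
    r_ai <- bw(self$a, self$Wi, dy$imag, has_b)   # via B*a in Im
    r_br <- bw(self$b, self$Wr, dy$imag, FALSE)   # via A*b in Im
    self$g_Wr <- self$g_Wr + r_ar$dW + r_br$dW
    self$g_Wi <- self$g_Wi + r_ai$dW - r_bi$dW
    if (has_b) {
      self$g_br <- self$g_br + r_ar$db
      self$g_bi <- self$g_bi + r_ai$db
    }
    out <- NULL
    if (need_dx)
      out <- complex_tensor(r_ar$dx + r_ai$dx, r_br$dx - r_bi$dx)
    self$a <- NULL; self$b <- NULL
    out
  }
  self
}

# Split complex normalization layer: one real normalization per part.
nn_cnorm <- function(C, mode = c("batch", "layer"), eps = 1e-5,
                     affine = TRUE) {
  mode <- match.arg(mode)
  self <- new_module("cnorm")
  mk <- function() if (mode == "batch") nn_batchnorm2d(C, eps, affine = affine)
                   else nn_layernorm_ch(C, eps, affine = affine)
  self$layers <- list(re = mk(), im = mk())
  self$forward <- function(x, training = TRUE)
    complex_tensor(self$layers$re$forward(x$real, training),
                   self$layers$im$forward(x$imag, training))
  self$backward <- function(dy)
    complex_tensor(self$layers$re$backward(dy$real),
                   self$layers$im$backward(dy$imag))
  self
}

# CReLU layer with cached masks.
nn_crelu <- function() {
  self <- new_layer("crelu")
  self$forward <- function(x, training = TRUE) {
    self$mr <- x$real > 0; self$mi <- x$imag > 0
    complex_tensor(x$real * self$mr, x$imag * self$mi)
  }
  self$backward <- function(dy) {
    out <- complex_tensor(dy$real * self$mr, dy$imag * self$mi)
    self$mr <- NULL; self$mi <- NULL
    out
  }
  self
}
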