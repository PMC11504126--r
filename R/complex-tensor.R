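# Complex-valued feature maps as paired real arrays.

#' Complex-valued tensor
#'
#' A pair of identically shaped real arrays holding the real and imaginary
#' parts of a complex feature map (`[H, W, C]` or `[H, W, C, N]`).
#'
#' @param real,imag real arrays of identical shape.
#' @return object of class `complex_tensor` with fields `real`, `imag`.
#' @export
complex_tensor <- function(real, imag = NULL) {
  if (is.complex(real)) {
    imag <- Im(real); real <- Re(real)
  }
  imag <- imag %||% array(0, dim(real))
  if (is.null(dim(real))) stopf("complex_tensor: parts must be arrays")
  if (!identical(dim(real), dim(imag)))
    stopf("complex_tensor: real and imag shapes differ")
  structure(list(real = real, imag = imag), class = "complex_tensor")
}

#' @export
print.complex_tensor <- function(x, ...) {
  cat("<complex_tensor> [", paste(dim(x$real), collapse = " x "), "]\n")
  invisible(x)
}

#' Elementwise magnitude of a complex tensor
#'
#' @param x a [complex_tensor()].
#' @return real array `sqrt(real^2 + imag^2)`.
#' @export
ct_magnitude <- function(x) {
  stopifnot(inherits(x, "complex_tensor"))
  sqrt(x$real^2 + x$imag^2)
}

#' Scale a complex tensor by a complex scalar
#'
#' @param x a [complex_tensor()].
#' @param z a single complex (or real) number.
#' @return a [complex_tensor()] holding `z * x`.
#' @export
ct_scale <- function(x, z) {
  stopifnot(inherits(x, "complex_tensor"), length(z) == 1)
  z <- as.complex(z)
  complex_tensor(Re(z) * x$real - Im(z) * x$imag,
                 Im(z) * x$real + Re(z) * x$imag)
}

#' Add two complex tensors
#'
#' @param a,b [complex_tensor()]s of identical shape.
#' @return their elementwise sum.
#' @export
ct_add <- function(a, b) {
  complex_tensor(a$real + b$real, a$imag + b$imag)
}
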