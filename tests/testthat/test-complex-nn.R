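# Complex convolution, CReLU and split normalization.

test_that("complex conv degenerates to a real convolution for real data", {
  set.seed(21)
  a <- array(rnorm(7 * 7 * 2), c(7, 7, 2))
  x <- complex_tensor(a)                      # b = 0
  A <- array(rnorm(3 * 3 * 2 * 3, sd = 0.3), c(3, 3, 2, 3))
  W <- complex_kernel(A, A * 0)               # B = 0
  y <- complex_conv2d(x, W, stride = 1, padding = 1)
  expect_equal(max(abs(y$imag)), 0)
  ref <- naive_complex_conv(a + 0i, A + 0i, 1, 1)
  expect_lt(max(abs(y$real - Re(ref))), 1e-10)
})

test_that("kernel i*delta rotates the input phase by 90 degrees", {
  set.seed(22)
  a <- array(rnorm(5 * 5 * 1), c(5, 5, 1))
  b <- array(rnorm(5 * 5 * 1), c(5, 5, 1))
  x <- complex_tensor(a, b)
  B <- array(0, c(1, 1, 1, 1)); B[1, 1, 1, 1] <- 1
  W <- complex_kernel(B * 0, B)               # W = i * delta
  y <- complex_conv2d(x, W)
  expect_equal(y$real, -b, tolerance = 1e-12)
  expect_equal(y$imag, a, tolerance = 1e-12)
})

test_that("complex conv matches the naive complex-arithmetic loop", {
  set.seed(23)
  for (case in 1:12) {
    Cin <- sample(1:3, 1); Cout <- sample(1:3, 1)
    kk <- sample(c(1, 3), 1)
    stride <- sample(1:2, 1); pad <- sample(0:1, 1)
    H <- sample(5:8, 1); W <- sample(5:8, 1)
    a <- array(rnorm(H * W * Cin), c(H, W, Cin))
    b <- array(rnorm(H * W * Cin), c(H, W, Cin))
    A <- array(rnorm(kk * kk * Cin * Cout), c(kk, kk, Cin, Cout))
    B <- array(rnorm(kk * kk * Cin * Cout), c(kk, kk, Cin, Cout))
    bias <- complex(real = rnorm(Cout), imaginary = rnorm(Cout))
    y <- complex_conv2d(complex_tensor(a, b), complex_kernel(A, B, bias),
                        stride, pad)
    ref <- naive_complex_conv(a + 1i * b, A + 1i * B, stride, pad, bias)
    expect_lt(max(abs(y$real - Re(ref))), 1e-5)
    expect_lt(max(abs(y$imag - Im(ref))), 1e-5)
  }
})

test_that("complex conv is linear under complex scalar multiplication", {
  set.seed(24)
  a <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  b <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  x <- complex_tensor(a, b)
  W <- complex_kernel(array(rnorm(36), c(3, 3, 2, 2)),
                      array(rnorm(36), c(3, 3, 2, 2)))   # no bias
  for (alpha in c(2 + 0i, 0 + 1i, 0.7 - 1.3i)) {
    y1 <- complex_conv2d(ct_scale(x, alpha), W, padding = 1)
    y2 <- ct_scale(complex_conv2d(x, W, padding = 1), alpha)
    expect_lt(max(abs(y1$real - y2$real), abs(y1$imag - y2$imag)), 1e-5)
  }
})

test_that("complex conv rejects mismatched channel counts", {
  x <- complex_tensor(array(0, c(4, 4, 2)))
  W <- complex_kernel(array(0, c(3, 3, 3, 1)), array(0, c(3, 3, 3, 1)))
  expect_error(complex_conv2d(x, W), "channels")
})

test_that("crelu rectifies each part independently and is idempotent", {
  x <- complex_tensor(array(c(1, -1, -1), c(1, 1, 3)),
                      array(c(2, -2, 2), c(1, 1, 3)))
  y <- crelu(x)
  expect_equal(as.vector(y$real), c(1, 0, 0))
  expect_equal(as.vector(y$imag), c(2, 0, 2))
  set.seed(25)
  z <- complex_tensor(array(rnorm(100), c(5, 5, 4)),
                      array(rnorm(100), c(5, 5, 4)))
  once <- crelu(z); twice <- crelu(once)
  expect_identical(once, twice)
})

test_that("split normalization standardizes both parts", {
  set.seed(26)
  x <- complex_tensor(array(rnorm(8 * 8 * 3, mean = 2, sd = 3), c(8, 8, 3)),
                      array(rnorm(8 * 8 * 3, mean = -1, sd = 0.5), c(8, 8, 3)))
  y <- complex_norm(x, "layer")
  expect_lt(abs(mean(y$real)), 1e-4)
  expect_lt(abs(mean(y$imag)), 1e-4)
  expect_lt(abs(mean(y$real^2) - 1), 1e-3)
  expect_lt(abs(mean(y$imag^2) - 1), 1e-3)

  # batch mode: per-channel moments
  yb <- complex_norm(x, "batch")
  for (c in 1:3) {
    expect_lt(abs(mean(yb$real[, , c])), 1e-4)
    expect_lt(abs(mean(yb$real[, , c]^2) - 1), 1e-3)
  }

  # constant input maps to zeros (epsilon-guarded, no division by zero)
  cz <- complex_norm(complex_tensor(array(5, c(4, 4, 2))), "layer")
  expect_equal(max(abs(cz$real)), 0)

  # zero imaginary part stays zero
  zi <- complex_norm(complex_tensor(array(rnorm(32), c(4, 4, 2))), "layer")
  expect_equal(max(abs(zi$imag)), 0)
})
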