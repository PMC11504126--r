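# Fourier transform conventions, half-plus-one sampling, conjugate symmetry.

test_that("orthonormal FFT: impulse, constant and Parseval identities", {
  # unit impulse -> flat spectrum of magnitude 1/sqrt(H*W)
  x <- array(0, c(8, 8, 1)); x[1, 1, 1] <- 1
  k <- image_to_kspace(x)
  expect_equal(as.vector(Mod(k$data)), rep(1 / 8, 64), tolerance = 1e-12)

  # constant image -> all energy in the DC bin
  xc <- array(3.7, c(8, 8, 1))
  kc <- image_to_kspace(xc)
  expect_equal(Mod(kc$data[1, 1, 1]), 3.7 * 8, tolerance = 1e-10)
  expect_lt(max(Mod(kc$data[-1])), 1e-10)

  # Parseval by direct summation on a random image
  set.seed(4)
  xr <- array(rnorm(16 * 16), c(16, 16, 1))
  kr <- image_to_kspace(xr)
  expect_lt(abs(sum(xr^2) - sum(Mod(kr$data)^2)), 1e-5)
})

test_that("kspace_to_image inverts image_to_kspace and validates its input", {
  set.seed(5)
  x <- array(rnorm(12 * 20 * 3), c(12, 20, 3))
  k <- image_to_kspace(x)
  expect_lt(max(abs(kspace_to_image(k) - x)), 1e-6)

  # zero grid -> zero image
  kz <- kspace_grid(array(complex(real = 0), c(8, 8, 1)))
  expect_equal(max(abs(kspace_to_image(kz))), 0)

  # partial grids and non-finite images are rejected
  kp <- apply_sampling_mask(k, half_plus_one_mask(12))
  expect_error(kspace_to_image(kp), "partially sampled")
  xb <- x; xb[1] <- NA
  expect_error(image_to_kspace(xb), "non-finite")

  # a genuinely complex grid is rejected on inversion
  kc <- kspace_grid(array(complex(real = rnorm(64), imaginary = rnorm(64)),
                          c(8, 8, 1)))
  expect_error(kspace_to_image(kc), "imaginary residue")
})

test_that("half_plus_one_mask selects DC plus non-negative frequency rows", {
  expect_equal(sum(half_plus_one_mask(224)), 113)
  expect_equal(which(half_plus_one_mask(8)), 1:5)     # rows u = 0..4
  m7 <- half_plus_one_mask(7)
  expect_equal(which(m7), 1:4)                        # rows u = 0..3
  expect_equal(sum(m7), 4)
  expect_error(half_plus_one_mask(1), "H must be")
  for (H in 2:40) expect_equal(sum(half_plus_one_mask(H)), H %/% 2 + 1)
})

test_that("conjugate symmetry holds for grids of real images", {
  set.seed(6)
  for (H in c(8, 9)) {
    W <- H + 3
    x <- array(rnorm(H * W), c(H, W, 1))
    k <- image_to_kspace(x)$data[, , 1]
    for (u in 0:(H - 1)) for (v in 0:(W - 1)) {
      expect_lt(Mod(k[u + 1, v + 1] -
                    Conj(k[(H - u) %% H + 1, (W - v) %% W + 1])), 1e-5)
    }
  }
})

test_that("conjugate_complete reconstructs the full grid of a real image", {
  set.seed(7)
  for (H in c(16, 15, 32)) {
    x <- array(rnorm(H * H * 2), c(H, H, 2))
    full <- image_to_kspace(x)
    half <- apply_sampling_mask(full, half_plus_one_mask(H))
    done <- conjugate_complete(half)
    expect_true(all(done$mask))
    expect_lt(max(Mod(done$data - full$data)), 1e-5)
    expect_lt(max(abs(kspace_to_image(done) - x)), 1e-5)
  }
})

test_that("conjugate completion is exact only for real-valued sources", {
  set.seed(8)
  x <- matrix(rnorm(256), 16, 16)
  z <- x + 1i * matrix(rnorm(256, sd = 0.5), 16, 16)
  full <- stats::fft(z) / 16
  k <- kspace_grid(array(full, c(16, 16, 1)))
  half <- apply_sampling_mask(k, half_plus_one_mask(16))
  done <- conjugate_complete(half)
  expect_gt(max(Mod(done$data[, , 1] - full)), 1e-3)  # documented limitation
})

test_that("conjugate_complete is a no-op on full grids and detects gaps", {
  set.seed(9)
  k <- image_to_kspace(array(rnorm(64), c(8, 8, 1)))
  expect_identical(conjugate_complete(k)$data, k$data)

  # drop a row whose conjugate partner is also missing
  bad <- k
  bad$mask[c(2, 8)] <- FALSE   # rows u = 1 and u = 7 are partners
  bad$data[c(2, 8), , ] <- 0
  expect_error(conjugate_complete(bad), "no acquired conjugate partner")
})

test_that("row replaced by its conjugate partner leaves the image unchanged", {
  set.seed(10)
  x <- array(rnorm(16 * 16), c(16, 16, 1))
  k <- image_to_kspace(x)
  r <- 4                                     # u = 3; partner u = 13
  partner <- (16 - (r - 1)) %% 16 + 1
  k$data[r, , 1] <- Conj(k$data[partner, c(1, 16:2), 1])
  expect_lt(max(abs(kspace_to_image(k) - x)), 1e-5)
})

test_that("centered view round-trips and moves DC to the middle", {
  x <- array(0, c(8, 8, 1)); x[1, 1, 1] <- 1
  x <- x + 0.3
  k <- image_to_kspace(x)
  kc <- kspace_center(k)
  expect_equal(kc$convention, "centered")
  # DC (largest bin of a near-constant image) now sits at H/2+1
  idx <- which.max(Mod(kc$data[, , 1]))
  expect_equal(arrayInd(idx, c(8, 8)), matrix(c(5L, 5L), 1))
  back <- kspaceseg:::kspace_uncenter(kc)
  expect_equal(back$data, k$data)
})
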