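# Phantom generator, normalization and augmentation.

test_that("generation is bitwise deterministic in the seed", {
  a <- generate_phantom(123)
  b <- generate_phantom(123)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  c <- generate_phantom(124)
  expect_false(identical(a$mask, c$mask))
})

test_that("label vocabulary and nesting hold across many seeds", {
  for (s in seq_len(1000)) {
    m <- generate_phantom(s, noise_sigma = 0)$mask
    labs <- sort(unique(as.vector(m)))
    expect_true(all(labs %in% c(0L, 1L, 2L, 4L)))
    et <- m == 4; tc <- m %in% c(1, 4); wt <- m %in% c(1, 2, 4)
    expect_true(any(et) && any(tc) && any(wt))   # all regions populated
    expect_true(all(!(et & !tc)) && all(!(tc & !wt)))  # ET in TC in WT
  }
})

test_that("region mean differences equal the configured contrast scaling", {
  s1 <- generate_phantom(9, noise_sigma = 0, contrast = 1)
  s2 <- generate_phantom(9, noise_sigma = 0, contrast = 2)
  for (ci in 1:4) {
    d1 <- mean(s1$image[, , ci][s1$mask == 2]) -
          mean(s1$image[, , ci][s1$mask == 1])
    d2 <- mean(s2$image[, , ci][s2$mask == 2]) -
          mean(s2$image[, , ci][s2$mask == 1])
    expect_equal(d2, 2 * d1, tolerance = 1e-12)
  }
  expect_error(generate_phantom(1, contrast = 0), "contrast")
  expect_error(generate_phantom(1, H = 48, W = 48), "divisible")
})

test_that("acdc profile produces the three cardiac structures", {
  m <- generate_phantom(31, profile = "acdc")$mask
  expect_true(all(sort(unique(as.vector(m))) %in% 0:3))
  for (lb in 1:3) expect_gt(sum(m == lb), 0)
})

test_that("z-score normalization standardizes each modality", {
  set.seed(72)
  x <- array(rnorm(64 * 64 * 3, mean = 40, sd = 9), c(64, 64, 3))
  z <- zscore_normalize(x)
  for (ci in 1:3) {
    expect_lt(abs(mean(z[, , ci])), 1e-6)
    expect_lt(abs(mean(z[, , ci]^2) - 1), 1e-5)
  }
  # idempotence
  expect_lt(max(abs(zscore_normalize(z) - z)), 1e-6)
  # constant channel -> zeros through the epsilon path
  xc <- array(5, c(8, 8, 1))
  dim(xc) <- c(8, 8, 1)
  expect_equal(max(abs(zscore_normalize(xc))), 0)
})

test_that("augmentation identity and mirroring involution", {
  s <- generate_phantom(41)
  expect_identical(augment(s, 1, transforms = character(0)), s)
  m1 <- augment(s, 2, transforms = "mirror", prob = 1)
  expect_false(identical(m1$image, s$image))
  m2 <- augment(m1, 3, transforms = "mirror", prob = 1)
  expect_identical(m2$image, s$image)
  expect_identical(m2$mask, s$mask)
})

test_that("exact 90-degree rotation moves image and mask consistently", {
  s <- generate_phantom(42, noise_sigma = 0)
  r <- augment(s, 5, transforms = "rotate", prob = 1, rot_range = c(90, 90))
  # direct construction with the same backward map:
  # out[i, j] = in[cy + (j - cx) rotated], i.e. index arithmetic only
  H <- 64; ctr <- (H + 1) / 2
  oracle <- matrix(0L, H, H)
  for (i in 1:H) for (j in 1:H) {
    si <- round(ctr - (j - ctr)); sj <- round(ctr + (i - ctr))
    if (si >= 1 && si <= H && sj >= 1 && sj <= H)
      oracle[i, j] <- s$mask[si, sj]
  }
  expect_equal(dice_score(r$mask, oracle, region_spec("WT")), 1)
  expect_equal(dice_score(r$mask, oracle, region_spec("ET")), 1)
  # label vocabulary preserved under nearest-neighbor resampling
  expect_true(all(unique(as.vector(r$mask)) %in% c(0L, 1L, 2L, 4L)))
})

test_that("every augmentation preserves vocabulary and region nesting", {
  s <- generate_phantom(43)
  for (tr in c("rotate", "translate", "scale", "elastic", "histmatch")) {
    a <- augment(s, 7, transforms = tr, prob = 1)
    m <- a$mask
    expect_true(all(unique(as.vector(m)) %in% c(0L, 1L, 2L, 4L)),
                label = tr)
    et <- m == 4; tc <- m %in% c(1, 4); wt <- m %in% c(1, 2, 4)
    expect_true(all(!(et & !tc)) && all(!(tc & !wt)), label = tr)
    expect_true(all(is.finite(a$image)), label = tr)
  }
  # histogram matching changes intensities but never the mask
  h <- augment(s, 8, transforms = "histmatch", prob = 1)
  expect_identical(h$mask, s$mask)
  expect_false(identical(h$image, s$image))
})

test_that("augmentation is deterministic in its seed", {
  s <- generate_phantom(44)
  a1 <- augment(s, 99)
  a2 <- augment(s, 99)
  expect_identical(a1$image, a2$image)
  expect_identical(a1$mask, a2$mask)
})
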