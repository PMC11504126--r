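# Loss closed forms and metric oracles.

test_that("cross-entropy closed forms and hand-summed case", {
  # perfect prediction -> 0
  p <- array(0, c(2, 2, 4)); p[, , 2] <- 1
  tgt <- matrix(1L, 2, 2)
  expect_equal(cross_entropy_loss(p, tgt), 0)

  # uniform probabilities over 4 classes -> log(4) per pixel
  pu <- array(0.25, c(3, 3, 4))
  expect_equal(cross_entropy_loss(pu, matrix(0L, 3, 3)), log(4),
               tolerance = 1e-12)

  # 3-pixel case against a direct hand sum
  pr <- matrix(c(0.7, 0.2, 0.1,
                 0.1, 0.8, 0.1,
                 0.3, 0.3, 0.4), 3, 3, byrow = TRUE)
  probs <- array(0, c(3, 1, 3))
  for (i in 1:3) probs[i, 1, ] <- pr[i, ]
  tgt <- array(c(0L, 1L, 2L), c(3, 1))
  expect_equal(cross_entropy_loss(probs, tgt),
               -(log(0.7) + log(0.8) + log(0.4)) / 3, tolerance = 1e-6)

  expect_error(cross_entropy_loss(probs - 1, tgt), "outside")
})

test_that("dice loss closed forms", {
  # perfect binary prediction -> exactly 0
  p <- array(0, c(4, 4, 2)); p[, , 1] <- 1
  p[1:2, 1:2, 1] <- 0; p[1:2, 1:2, 2] <- 1
  tgt <- matrix(0L, 4, 4); tgt[1:2, 1:2] <- 1L
  expect_equal(dice_loss(p, tgt), 0, tolerance = 1e-9)

  # completely disjoint -> 1 (up to the smoothing epsilon)
  pd <- array(0, c(4, 4, 2)); pd[, , 1] <- 1
  pd[1:2, 1:2, 1] <- 0; pd[1:2, 1:2, 2] <- 1   # pred foreground: the block
  td <- matrix(1L, 4, 4); td[1:2, 1:2] <- 0L   # true foreground: complement
  expect_equal(dice_loss(pd, td), 1, tolerance = 1e-4)

  # p = 0.5 everywhere, g = 1 everywhere:
  # 1 - 2*(0.5 N)/(0.25 N + N) = 1 - 1/1.25 = 0.2
  ph <- array(0.5, c(8, 8, 2))
  th <- matrix(1L, 8, 8)
  expect_equal(dice_loss(ph, th), 0.2, tolerance = 1e-6)
})

test_that("combined loss is the weighted sum of its parts", {
  set.seed(71)
  logits <- array(rnorm(4 * 4 * 4), c(4, 4, 4))
  p <- softmax_classes(logits)
  tgt <- matrix(sample(0:3, 16, TRUE), 4, 4)
  expect_equal(combined_loss(p, tgt, alpha = 1, beta = 0),
               cross_entropy_loss(p, tgt))
  expect_equal(combined_loss(p, tgt, alpha = 0, beta = 1),
               dice_loss(p, tgt))
  expect_equal(combined_loss(p, tgt, 1, 1),
               cross_entropy_loss(p, tgt) + dice_loss(p, tgt),
               tolerance = 1e-12)
  expect_error(combined_loss(p, tgt, -1, 1), "nonnegative")
  # one-hot of the target scores 0 Dice loss and >= 0 combined loss
  oh <- kspaceseg:::as_onehot(tgt, dim(kspaceseg:::as_hwcn(p)))
  expect_equal(dice_loss(oh[, , , 1], tgt), 0, tolerance = 1e-9)
  expect_gte(combined_loss(p, tgt), 0)
})

test_that("region specs encode the nested tumor label sets", {
  expect_equal(region_spec("WT")$labels, c(1, 2, 4))
  expect_equal(region_spec("TC")$labels, c(1, 4))
  expect_equal(region_spec("ET")$labels, 4)
  expect_true(all(region_spec("ET")$labels %in% region_spec("TC")$labels))
  expect_true(all(region_spec("TC")$labels %in% region_spec("WT")$labels))
  expect_error(region_spec("XX"), "unknown region")
})

test_that("dice_score hand counts and conventions", {
  # identical masks
  m <- make_random_masks(1)
  expect_equal(dice_score(m, m, region_spec("WT")), 1)

  # pred all-positive on 2x2, truth half-positive: TP=2 FP=2 FN=0
  pred <- matrix(1L, 2, 2)
  truth <- matrix(c(1L, 1L, 0L, 0L), 2, 2)
  expect_equal(dice_score(pred, truth), 2 * 2 / (2 * 2 + 2 + 0))

  # both empty -> 1 by convention
  z <- matrix(0L, 4, 4)
  expect_equal(dice_score(z, z, region_spec("ET")), 1)

  # symmetry
  a <- make_random_masks(2); b <- make_random_masks(3)
  for (rn in c("WT", "TC", "ET"))
    expect_equal(dice_score(a, b, region_spec(rn)),
                 dice_score(b, a, region_spec(rn)))
  expect_error(dice_score(matrix(0, 2, 2), matrix(0, 3, 3)), "shapes differ")
})

test_that("dice_score decreases as disagreement grows at fixed TP", {
  truth <- matrix(0L, 8, 8); truth[3:6, 3:6] <- 1L
  prev <- 1
  for (extra in 0:10) {
    pred <- truth
    if (extra > 0) pred[seq_len(extra)] <- 1L   # add FP pixels column-wise
    d <- dice_score(pred, truth)
    expect_lte(d, prev + 1e-12)
    prev <- d
  }
})

test_that("hd95 degenerate and closed-form cases", {
  m <- make_random_masks(4)
  expect_equal(hd95(m, m), 0)

  # two single-pixel sets 5 px apart
  a <- matrix(FALSE, 16, 16); b <- a
  a[8, 3] <- TRUE; b[8, 8] <- TRUE
  expect_equal(hd95(a, b), 5)
  expect_equal(hd95(a, b, spacing = 2), 10)

  # empty-mask conventions
  z <- matrix(0L, 16, 16)
  expect_equal(hd95(z, z), 0)
  expect_warning(pen <- hd95(a, z), "empty")
  expect_equal(pen, sqrt(2 * 16^2))
})

test_that("hd95 matches the brute-force all-pairs oracle", {
  for (s in 1:25) {
    a <- make_random_masks(100 + s) != 0
    b <- make_random_masks(200 + s) != 0
    if (!any(a) || !any(b)) next
    expect_equal(hd95(a, b), bruteforce_hd95(a, b), tolerance = 1e-6)
  }
})

test_that("hd95 is symmetric and translation invariant", {
  a <- make_random_masks(7) != 0
  b <- make_random_masks(8) != 0
  expect_equal(hd95(a, b), hd95(b, a))
  shift <- function(m, dy, dx) {
    out <- matrix(FALSE, nrow(m) + dy, ncol(m) + dx)
    out[dy + seq_len(nrow(m)), dx + seq_len(ncol(m))] <- m
    out
  }
  expect_equal(hd95(shift(a, 5, 3), shift(b, 5, 3)), hd95(a, b))
})
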