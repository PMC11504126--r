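# Training losses: pixelwise cross-entropy plus soft Dice, combined as
#   L_total = alpha * L_CE + beta * L_Dice
# L_CE  = mean over pixels of -sum_c y_c log p_c
# L_Dice = 1 - 2 * sum(p*g) / (sum(p^2) + sum(g^2))   (squared denominator),
# averaged over foreground classes, with eps = 1e-5 smoothing in both
# numerator and denominator so a perfect binary prediction scores exactly 0.
# Evaluation-time Dice on hard masks lives in metrics.R.

CLAMP_P <- 1e-8

# Accept either a one-hot array shaped like probs or an integer class map
# [H,W(,N)] with values 0..K-1.
as_onehot <- function(target, d) {
  dt <- dim(target)
  looks_onehot <- !is.null(dt) && length(dt) >= 3 &&
    all(dt[1:3] == d[1:3]) && all(target %in% c(0, 1)) &&
    (length(dt) == 4 || d[4] == 1)
  if (looks_onehot)
    return(as_hwcn(target))
  tgt <- target
  if (is.null(dim(tgt))) stopf("target must be an array")
  if (length(dim(tgt)) == 2) dim(tgt) <- c(dim(tgt), 1L)
  if (!all(dim(tgt) == d[c(1, 2, 4)]))
    stopf("target shape does not match probabilities")
  oh <- array(0, d)
  for (k in seq_len(d[3]))
    oh[, , k, ] <- (tgt == k - 1) * 1
  oh
}

#' Pixelwise cross-entropy loss
#'
#' Mean over pixels of `-sum_c y_c log(p_c)`. Probabilities are clamped at
#' `1e-8` before the log so a zero probability at the true class yields a
#' large finite penalty rather than `Inf`.
#'
#' @param probs class probabilities `[H, W, K]` or `[H, W, K, N]`, rows
#'   (class vectors per pixel) summing to 1.
#' @param target one-hot array shaped like `probs`, or an integer class map
#'   `[H, W(, N)]` with classes `0..K-1`.
#' @return scalar loss (>= 0).
#' @export
cross_entropy_loss <- function(probs, target) {
  p <- as_hwcn(probs)
  d <- dim(p)
  if (any(p < 0) || any(p > 1 + 1e-6))
    stopf("cross_entropy_loss: probabilities outside [0, 1]")
  y <- as_onehot(target, d)
  npix <- d[1] * d[2] * d[4]
  -sum(y * log(pmax(p, CLAMP_P))) / npix
}

#' Soft Dice loss (squared-denominator form)
#'
#' Per foreground class: `1 - 2*sum(p*g) / (sum(p^2) + sum(g^2))` with
#' `eps = 1e-5` smoothing, then averaged over the included classes. The
#' background class (index 0) is excluded by default; sums run over all
#' pixels of the batch.
#'
#' @inheritParams cross_entropy_loss
#' @param eps smoothing constant.
#' @param include_background also average over class 0.
#' @return scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(probs, target, eps = 1e-5, include_background = FALSE) {
  p <- as_hwcn(probs)
  d <- dim(p)
  y <- as_onehot(target, d)
  ks <- if (include_background || d[3] == 1) seq_len(d[3]) else 2:d[3]
  tot <- 0
  for (k in ks) {
    pk <- p[, , k, ]; gk <- y[, , k, ]
    tot <- tot + 1 - (2 * sum(pk * gk) + eps) / (sum(pk * pk) + sum(gk * gk) + eps)
  }
  tot / length(ks)
}

#' Combined cross-entropy + Dice loss
#'
#' `alpha * L_CE + beta * L_Dice` (defaults `alpha = beta = 1`).
#'
#' @inheritParams dice_loss
#' @param alpha,beta nonnegative weights for the two terms.
#' @return scalar loss.
#' @export
combined_loss <- function(probs, target, alpha = 1, beta = 1, eps = 1e-5) {
  if (alpha < 0 || beta < 0)
    stopf("combined_loss: weights must be nonnegative")
  alpha * cross_entropy_loss(probs, target) +
    beta * dice_loss(probs, target, eps = eps)
}

#' Softmax over the class axis
#'
#' @param logits array `[H, W, K]` or `[H, W, K, N]`.
#' @return probabilities of the same shape, summing to 1 over classes.
#' @export
softmax_classes <- function(logits) {
  single <- length(dim(logits)) == 3
  x <- as_hwcn(logits)
  d <- dim(x)
  xm <- matrix(aperm(array(x, c(d[1] * d[2], d[3], d[4])), c(2, 1, 3)),
               nrow = d[3])
  cmax <- xm[1, ]
  for (k in seq_len(d[3])[-1]) cmax <- pmax(cmax, xm[k, ])
  xm <- sweep(xm, 2, cmax, "-")
  e <- exp(xm)
  e <- sweep(e, 2, colSums(e), "/")
  p <- array(aperm(array(e, c(d[3], d[1] * d[2], d[4])), c(2, 1, 3)), d)
  if (single) dim(p) <- d[1:3]
  p
}

# Combined loss with analytic gradient w.r.t. logits; used by the training
# loop. CE gradient through softmax is (p - y)/npix; the Dice term's
# gradient w.r.t. p is chained through the softmax Jacobian.
combined_loss_grad <- function(logits, target, alpha = 1, beta = 1,
                               eps = 1e-5, include_background = FALSE) {
  p <- softmax_classes(logits)
  d <- dim(p)
  y <- as_onehot(target, d)
  npix <- d[1] * d[2] * d[4]

  ce <- -sum(y * log(pmax(p, CLAMP_P))) / npix
  dlogits <- alpha * (p - y) / npix

  ks <- if (include_background) seq_len(d[3]) else 2:d[3]
  dice <- 0
  dLdp <- array(0, d)
  for (k in ks) {
    pk <- p[, , k, , drop = FALSE]; gk <- y[, , k, , drop = FALSE]
    num <- 2 * sum(pk * gk) + eps
    den <- sum(pk * pk) + sum(gk * gk) + eps
    dice <- dice + 1 - num / den
    dLdp[, , k, ] <- (-2 * gk * den + 2 * pk * num) / den^2
  }
  dice <- dice / length(ks)
  dLdp <- dLdp / length(ks)

  # chain dL/dp through softmax: dz = p * (dLdp - sum_c dLdp_c p_c)
  inner <- array(rep(colSums(matrix(aperm(array(dLdp * p,
             c(d[1] * d[2], d[3], d[4])), c(2, 1, 3)), nrow = d[3])),
             each = 1), c(d[1] * d[2], d[4]))
  innerf <- aperm(array(inner, c(d[1] * d[2], d[4], d[3])), c(1, 3, 2))
  dim(innerf) <- d
  dlogits <- dlogits + beta * p * (dLdp - innerf)

  list(loss = alpha * ce + beta * dice, ce = ce, dice = dice,
       dlogits = dlogits, probs = p)
}
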