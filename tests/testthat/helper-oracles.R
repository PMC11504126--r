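# Independent oracles used to pin down expected values. These deliberately
# use naive scalar arithmetic / explicit loops, not the package's own
# vectorized or compiled code paths.

# Naive complex 2D convolution (cross-correlation) with native complex
# scalars: x [H,W,Cin] complex, w [kh,kw,Cin,Cout] complex.
naive_complex_conv <- function(x, w, stride = 1, pad = 0, bias = NULL) {
  d <- dim(x); dk <- dim(w)
  H <- d[1]; W <- d[2]; Cin <- d[3]
  Ho <- (H + 2 * pad - dk[1]) %/% stride + 1
  Wo <- (W + 2 * pad - dk[2]) %/% stride + 1
  xp <- array(complex(real = 0), c(H + 2 * pad, W + 2 * pad, Cin))
  xp[pad + seq_len(H), pad + seq_len(W), ] <- x
  y <- array(complex(real = 0), c(Ho, Wo, dk[4]))
  for (co in seq_len(dk[4])) {
    for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
      acc <- if (is.null(bias)) 0 + 0i else bias[co]
      for (ci in seq_len(Cin))
        for (ki in seq_len(dk[1])) for (kj in seq_len(dk[2]))
          acc <- acc + xp[(ho - 1) * stride + ki, (wo - 1) * stride + kj, ci] *
                       w[ki, kj, ci, co]
      y[ho, wo, co] <- acc
    }
  }
  y
}

# Explicit linear-interpolation percentile (same definition as numpy's
# default), written out by hand.
manual_percentile <- function(v, q) {
  s <- sort(v)
  n <- length(s)
  if (n == 1) return(s)
  h <- (n - 1) * q
  lo <- floor(h)
  s[lo + 1] + (h - lo) * (s[min(lo + 2, n)] - s[lo + 1])
}

# Brute-force HD95: explicit boundary scan and all-pairs distances.
bruteforce_hd95 <- function(a, b, spacing = 1) {
  boundary <- function(m) {
    d <- dim(m)
    pts <- NULL
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      if (!m[i, j]) next
      nb <- c(if (i > 1) m[i - 1, j] else FALSE,
              if (i < d[1]) m[i + 1, j] else FALSE,
              if (j > 1) m[i, j - 1] else FALSE,
              if (j < d[2]) m[i, j + 1] else FALSE)
      if (!all(nb)) pts <- rbind(pts, c(i, j))
    }
    pts
  }
  pa <- boundary(a); pb <- boundary(b)
  directed <- function(p, q) {
    vapply(seq_len(nrow(p)), function(i)
      min(sqrt((p[i, 1] - q[, 1])^2 + (p[i, 2] - q[, 2])^2)), 0)
  }
  max(manual_percentile(directed(pa, pb), 0.95),
      manual_percentile(directed(pb, pa), 0.95)) * spacing
}

# Step-by-step fusion-gate oracle (the printed equation chain), reading the
# weight banks out of a built fusion module. conv1x1 is a per-position
# matrix product; BN uses training-time batch statistics.
oracle_conv1x1 <- function(x, Wmat, b) {
  d <- dim(x)
  y <- array(0, c(d[1], d[2], ncol(Wmat), d[4]))
  for (n in seq_len(d[4])) for (h in seq_len(d[1])) for (w in seq_len(d[2]))
    y[h, w, , n] <- as.vector(x[h, w, , n] %*% Wmat) + b
  y
}

oracle_bn <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  y <- x
  for (c in seq_len(d[3])) {
    v <- x[, , c, , drop = FALSE]
    mu <- mean(v)
    s2 <- mean((v - mu)^2)
    y[, , c, ] <- gamma[c] * (v - mu) / sqrt(s2 + eps) + beta[c]
  }
  y
}

oracle_gate <- function(m, prefix, X) {
  L <- m$layers
  g1 <- L[[paste0(prefix, "_conv1")]]; b1 <- L[[paste0(prefix, "_bn1")]]
  g2 <- L[[paste0(prefix, "_conv2")]]; b2 <- L[[paste0(prefix, "_bn2")]]
  Y <- oracle_bn(oracle_conv1x1(X, g1$W, g1$b), b1$gamma, b1$beta)
  Y <- pmax(Y, 0)
  Z <- oracle_bn(oracle_conv1x1(Y, g2$W, g2$b), b2$gamma, b2$beta)
  1 / (1 + exp(-Z))
}

oracle_daffm <- function(m, xi, xk) {
  X <- xi + xk
  Wl <- oracle_gate(m, "l", X)
  xl <- xi * Wl + xk * (1 - Wl)
  d <- dim(X)
  g <- array(0, c(1, 1, d[3], d[4]))
  for (n in seq_len(d[4])) for (c in seq_len(d[3]))
    g[1, 1, c, n] <- mean(X[, , c, n])
  Wg <- oracle_gate(m, "g", g)
  wg <- array(0, d)
  for (n in seq_len(d[4])) for (c in seq_len(d[3]))
    wg[, , c, n] <- Wg[1, 1, c, n]
  xg <- xi * (1 - wg) + xk * wg
  list(Wl = Wl, Wg = Wg, xl = xl, xg = xg, out = xl + xg)
}

# Central-difference gradient check of layer input gradients.
fd_input_check <- function(layer, xdim, n_probe = 12, eps = 1e-5,
                           seed = 99) {
  set.seed(seed)
  x <- array(rnorm(prod(xdim)), xdim)
  y <- layer$forward(x, training = TRUE)
  dy <- array(rnorm(length(y)), dim(y))
  kspaceseg:::zero_grads(list(layer))
  dx <- layer$backward(dy)
  err <- 0
  for (t in seq_len(n_probe)) {
    i <- sample(length(x), 1)
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g <- (sum(layer$forward(xp, TRUE) * dy) -
          sum(layer$forward(xm, TRUE) * dy)) / (2 * eps)
    err <- max(err, abs(g - dx[i]))
  }
  err
}

make_random_masks <- function(seed, H = 32, W = 32, labels = c(0, 1, 2, 4)) {
  set.seed(seed)
  blob <- function() {
    cy <- runif(1, 8, H - 8); cx <- runif(1, 8, W - 8)
    r1 <- runif(1, 3, 9); r2 <- runif(1, 3, 9)
    ys <- matrix(seq_len(H), H, W); xs <- matrix(seq_len(W), H, W, byrow = TRUE)
    ((ys - cy) / r1)^2 + ((xs - cx) / r2)^2 <= 1
  }
  m <- matrix(0L, H, W)
  for (lb in labels[labels != 0]) m[blob()] <- as.integer(lb)
  m
}
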