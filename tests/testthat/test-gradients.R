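# Analytic backward passes versus central finite differences. These checks
# are what make the from-scratch training loop trustworthy.

test_that("primitive layer input gradients match finite differences", {
  checks <- list(
    conv    = list(function() kspaceseg:::nn_conv2d(2, 3, 3, 1, 1), c(6, 6, 2, 2)),
    strided = list(function() kspaceseg:::nn_conv2d(2, 3, 3, 2, 1), c(6, 6, 2, 2)),
    bn      = list(function() kspaceseg:::nn_batchnorm2d(2), c(5, 5, 2, 3)),
    instn   = list(function() kspaceseg:::nn_instancenorm2d(2), c(5, 5, 2, 3)),
    ln      = list(function() kspaceseg:::nn_layernorm_ch(4), c(5, 5, 4, 2)),
    pool    = list(function() kspaceseg:::nn_maxpool2(), c(6, 6, 2, 2)),
    up      = list(function() kspaceseg:::nn_upsample2(), c(4, 4, 2, 2)),
    attn    = list(function() kspaceseg:::nn_window_attention(4, 3), c(6, 6, 4, 2)))
  for (nm in names(checks)) {
    set.seed(31)
    l <- checks[[nm]][[1]]()
    err <- fd_input_check(l, checks[[nm]][[2]])
    expect_lt(err, 1e-6, label = paste(nm, "input gradient error"))
  }
})

test_that("conv weight and bias gradients match finite differences", {
  set.seed(32)
  l <- kspaceseg:::nn_conv2d(2, 3, 3, 1, 1)
  x <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  y <- l$forward(x, TRUE)
  dy <- array(rnorm(length(y)), dim(y))
  kspaceseg:::zero_grads(list(l))
  l$backward(dy)
  eps <- 1e-6
  for (i in sample(length(l$W), 8)) {
    o <- l$W[i]
    l$W[i] <- o + eps; fp <- sum(l$forward(x, TRUE) * dy)
    l$W[i] <- o - eps; fm <- sum(l$forward(x, TRUE) * dy)
    l$W[i] <- o
    expect_lt(abs((fp - fm) / (2 * eps) - l$g_W[i]), 1e-5)
  }
  o <- l$b[2]
  l$b[2] <- o + eps; fp <- sum(l$forward(x, TRUE) * dy)
  l$b[2] <- o - eps; fm <- sum(l$forward(x, TRUE) * dy)
  l$b[2] <- o
  expect_lt(abs((fp - fm) / (2 * eps) - l$g_b[2]), 1e-5)
})

test_that("complex conv layer gradients match finite differences", {
  set.seed(33)
  l <- kspaceseg:::nn_cconv2d(2, 3, 3, 2, 1)
  a <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  b <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  fwd <- function() {
    y <- l$forward(complex_tensor(a, b), TRUE)
    sum(y$real * dyr) + sum(y$imag * dyi)
  }
  y0 <- l$forward(complex_tensor(a, b), TRUE)
  dyr <- array(rnorm(length(y0$real)), dim(y0$real))
  dyi <- array(rnorm(length(y0$imag)), dim(y0$imag))
  kspaceseg:::zero_grads(list(l))
  dx <- l$backward(complex_tensor(dyr, dyi))
  eps <- 1e-6
  # input gradients (both parts)
  for (t in 1:6) {
    i <- sample(length(a), 1)
    o <- a[i]; a[i] <- o + eps; fp <- fwd(); a[i] <- o - eps; fm <- fwd(); a[i] <- o
    expect_lt(abs((fp - fm) / (2 * eps) - dx$real[i]), 1e-5)
    o <- b[i]; b[i] <- o + eps; fp <- fwd(); b[i] <- o - eps; fm <- fwd(); b[i] <- o
    expect_lt(abs((fp - fm) / (2 * eps) - dx$imag[i]), 1e-5)
  }
  # weight-bank gradients
  for (bank in c("Wr", "Wi")) {
    for (t in 1:4) {
      i <- sample(length(l[[bank]]), 1)
      o <- l[[bank]][i]
      l[[bank]][i] <- o + eps; fp <- fwd()
      l[[bank]][i] <- o - eps; fm <- fwd()
      l[[bank]][i] <- o
      expect_lt(abs((fp - fm) / (2 * eps) - l[[paste0("g_", bank)]][i]), 1e-5)
    }
  }
})

test_that("fusion module gradients match finite differences", {
  set.seed(34)
  m <- kspaceseg:::daffm_module(4, r = 2)
  xi <- array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2))
  xk <- array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2))
  y0 <- m$forward(xi, xk, TRUE)
  dy <- array(rnorm(length(y0)), dim(y0))
  kspaceseg:::zero_grads(kspaceseg:::collect_layers(m))
  gr <- m$backward(dy)
  eps <- 1e-6
  f <- function() sum(m$forward(xi, xk, TRUE) * dy)
  for (t in 1:8) {
    i <- sample(length(xi), 1)
    o <- xi[i]; xi[i] <- o + eps; fp <- f(); xi[i] <- o - eps; fm <- f(); xi[i] <- o
    expect_lt(abs((fp - fm) / (2 * eps) - gr$dxi[i]), 1e-5)
    o <- xk[i]; xk[i] <- o + eps; fp <- f(); xk[i] <- o - eps; fm <- f(); xk[i] <- o
    expect_lt(abs((fp - fm) / (2 * eps) - gr$dxk[i]), 1e-5)
  }
})

test_that("combined loss value and logit gradient match finite differences", {
  set.seed(35)
  logits <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  tgt <- array(sample(0:2, 32, TRUE), c(4, 4, 2))
  lg <- kspaceseg:::combined_loss_grad(logits, tgt, alpha = 0.8, beta = 1.2)
  # value agrees with the user-facing loss functions on the same softmax
  p <- softmax_classes(logits)
  expect_equal(lg$loss,
               0.8 * cross_entropy_loss(p, tgt) + 1.2 * dice_loss(p, tgt),
               tolerance = 1e-10)
  eps <- 1e-6
  for (t in 1:10) {
    i <- sample(length(logits), 1)
    lp <- logits; lp[i] <- lp[i] + eps
    lm <- logits; lm[i] <- lm[i] - eps
    fd <- (kspaceseg:::combined_loss_grad(lp, tgt, 0.8, 1.2)$loss -
           kspaceseg:::combined_loss_grad(lm, tgt, 0.8, 1.2)$loss) / (2 * eps)
    expect_lt(abs(fd - lg$dlogits[i]), 1e-6)
  }
})

test_that("assembled network gradients are exact through every module", {
  cfg <- ablation_config(5, image_size = 32, seed = 55, n_modalities = 2)
  # 32x32 keeps this cheap; the pyramid bottoms out at 1x1
  model <- build_model(cfg)
  ds <- generate_phantom_dataset(2, seed = 56, H = 32, W = 32,
                                 n_modalities = 2)
  x <- kspaceseg:::stack_images(ds)
  tgt <- kspaceseg:::stack_masks(ds, cfg$label_values)
  layers <- kspaceseg:::collect_layers(model)
  lg <- kspaceseg:::combined_loss_grad(model$forward(x, TRUE), tgt)
  kspaceseg:::zero_grads(layers)
  model$backward(lg$dlogits)
  eps <- 1e-5
  probe <- c("encoder.conv1", "kfem.cconv1", "kfem.cnorm2.im",
             "fusion2.l_conv1", "fusion5.g_conv2", "decoder.conv1",
             "decoder.head")
  # median over three probes per layer: a single probe can straddle a
  # ReLU / magnitude kink where finite differences are ill-defined
  set.seed(57)
  for (nm in probe) {
    l <- layers[[nm]]
    p <- l$params[1]
    errs <- vapply(sample(length(l[[p]]), 3), function(i) {
      o <- l[[p]][i]
      l[[p]][i] <- o + eps
      fp <- kspaceseg:::combined_loss_grad(model$forward(x, TRUE), tgt)$loss
      l[[p]][i] <- o - eps
      fm <- kspaceseg:::combined_loss_grad(model$forward(x, TRUE), tgt)$loss
      l[[p]][i] <- o
      an <- l[[paste0("g_", p)]][i]
      abs((fp - fm) / (2 * eps) - an) / max(1, abs(an))
    }, 0)
    expect_lt(median(errs), 1e-4, label = paste("gradient through", nm))
  }
})
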