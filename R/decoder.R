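# Up-sampling decoder with skip connections.
#
# Starting at the fused level-5 bottleneck: repeat {bilinear 2x up-sample ->
# concatenate the matching fused skip -> 3x3 conv -> instance norm -> ReLU}
# with output channels {256, 128, 64, 32}, then a final 2x up-sample and a
# 1x1 convolution to per-class logits at the input resolution. Skip merging
# is concatenation followed by convolution, which both joins the paths and
# reduces the channel count.

decoder_module <- function(num_classes, channels = PYRAMID_CHANNELS,
                           bias = TRUE) {
  self <- new_module("decoder")
  self$num_classes <- num_classes
  nl <- length(channels)
  for (i in (nl - 1):1) {
    self$layers[[paste0("up", i)]] <- nn_upsample2()
    self$layers[[paste0("conv", i)]] <-
      nn_conv2d(channels[i + 1] + channels[i], channels[i], 3, 1, 1,
                bias = bias)
    self$layers[[paste0("in", i)]] <- nn_instancenorm2d(channels[i])
    self$layers[[paste0("relu", i)]] <- nn_relu()
  }
  self$layers$up0 <- nn_upsample2()
  self$layers$head <- nn_conv2d(channels[1], num_classes, 1, 1, 0,
                                bias = bias)
  self$nl <- nl
  self$forward <- function(pyr, training = TRUE) {
    d1 <- dim(pyr[[1]])
    check_pyramid(pyr, d1[1] * 2L, d1[2] * 2L)
    self$skip_ch <- integer(self$nl - 1)
    x <- pyr[[self$nl]]
    for (i in (self$nl - 1):1) {
      x <- self$layers[[paste0("up", i)]]$forward(x, training)
      self$skip_ch[i] <- dim(x)[3]
      x <- cat_channels(x, pyr[[i]])
      x <- self$layers[[paste0("conv", i)]]$forward(x, training)
      x <- self$layers[[paste0("in", i)]]$forward(x, training)
      x <- self$layers[[paste0("relu", i)]]$forward(x, training)
    }
    x <- self$layers$up0$forward(x, training)
    self$layers$head$forward(x, training)
  }
  self$backward <- function(dlogits) {
    dpyr <- vector("list", self$nl)
    g <- self$layers$head$backward(dlogits)
    g <- self$layers$up0$backward(g)
    for (i in 1:(self$nl - 1)) {
      g <- self$layers[[paste0("relu", i)]]$backward(g)
      g <- self$layers[[paste0("in", i)]]$backward(g)
      g <- self$layers[[paste0("conv", i)]]$backward(g)
      parts <- split_channels(g, self$skip_ch[i])
      dpyr[[i]] <- parts[[2]]
      g <- self$layers[[paste0("up", i)]]$backward(parts[[1]])
    }
    dpyr[[self$nl]] <- g
    dpyr
  }
  self
}

#' Decode a fused feature pyramid to per-class logits
#'
#' @param decoder a decoder module (see [build_model()]).
#' @param pyr a five-level feature pyramid.
#' @param training use batch statistics in normalization layers.
#' @return logits `[H, W, num_classes, N]` at the input resolution.
#' @export
decode <- function(decoder, pyr, training = FALSE) {
  pyr <- lapply(pyr, as_hwcn)
  decoder$forward(pyr, training)
}
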