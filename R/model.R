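# Network assembly. The five ablation variants compose the modules:
#   No.1  CFEM -> decoder
#   No.2  TFEM -> decoder
#   No.3  CFEM + KFEM, parameter-free addition fusion
#   No.4  TFEM + KFEM + DAFFM
#   No.5  CFEM + KFEM + DAFFM (the full model)
# The K-space path simulates acquisition inside the forward pass: the
# (normalized, augmented) image batch is Fourier-transformed, reduced to the
# half-plus-one rows, completed by conjugate symmetry, and fed to KFEM, so
# both paths always see the same geometry.

#' Experiment configuration
#'
#' Validated hyperparameter bundle for [build_model()] and the training /
#' evaluation pipeline.
#'
#' @param encoder image-domain encoder: `"cfem"` (convolutional) or
#'   `"tfem"` (window attention).
#' @param use_kfem add the complex-valued K-space encoder path.
#' @param use_daffm use attention fusion (otherwise plain addition);
#'   requires `use_kfem`.
#' @param fusion_placement `"per_level"` (a fusion module at each pyramid
#'   level) or `"bottleneck"` (level 5 only; shallower skips pass the image
#'   features through).
#' @param r DAFFM bottleneck reduction ratio.
#' @param num_classes segmentation classes (internal contiguous labels).
#' @param label_values raw label vocabulary, mapped to `0..num_classes-1`
#'   internally and restored on output.
#' @param n_modalities input channels.
#' @param image_size square slice size, divisible by 32.
#' @param lr,batch_size,steps Adam learning rate, batch size, optimizer
#'   steps.
#' @param alpha,beta combined-loss weights.
#' @param seed RNG seed for weight init and batch sampling.
#' @param folds cross-validation folds.
#' @param window preferred attention window size.
#' @param augment apply the augmentation pipeline during training.
#' @param profile phantom/label profile (`"brats"` or `"acdc"`).
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(encoder = c("cfem", "tfem"), use_kfem = TRUE,
                              use_daffm = TRUE,
                              fusion_placement = c("per_level", "bottleneck"),
                              r = 4L, num_classes = 4L,
                              label_values = c(0, 1, 2, 4),
                              n_modalities = 4L, image_size = 64L,
                              lr = 3e-4, batch_size = 8L, steps = 200L,
                              alpha = 1, beta = 1, seed = 42L, folds = 5L,
                              window = 7L, augment = FALSE,
                              profile = c("brats", "acdc")) {
  encoder <- match.arg(encoder)
  fusion_placement <- match.arg(fusion_placement)
  profile <- match.arg(profile)
  if (use_daffm && !use_kfem)
    stopf("experiment_config: use_daffm requires use_kfem")
  if (length(label_values) != num_classes)
    stopf("experiment_config: label_values length must equal num_classes")
  if (image_size %% 32 != 0)
    stopf("experiment_config: image_size must be divisible by 32")
  structure(list(encoder = encoder, use_kfem = use_kfem,
                 use_daffm = use_daffm, fusion_placement = fusion_placement,
                 r = as.integer(r), num_classes = as.integer(num_classes),
                 label_values = label_values,
                 n_modalities = as.integer(n_modalities),
                 image_size = as.integer(image_size), lr = lr,
                 batch_size = as.integer(batch_size),
                 steps = as.integer(steps), alpha = alpha, beta = beta,
                 seed = as.integer(seed), folds = as.integer(folds),
                 window = as.integer(window), augment = augment,
                 profile = profile),
            class = "experiment_config")
}

#' Ablation configuration presets
#'
#' The five standard network variants, by number.
#'
#' @param no variant number 1-5.
#' @param ... overrides passed to [experiment_config()].
#' @return an `experiment_config`.
#' @export
ablation_config <- function(no, ...) {
  base <- switch(as.character(no),
    "1" = list(encoder = "cfem", use_kfem = FALSE, use_daffm = FALSE),
    "2" = list(encoder = "tfem", use_kfem = FALSE, use_daffm = FALSE),
    "3" = list(encoder = "cfem", use_kfem = TRUE, use_daffm = FALSE),
    "4" = list(encoder = "tfem", use_kfem = TRUE, use_daffm = TRUE),
    "5" = list(encoder = "cfem", use_kfem = TRUE, use_daffm = TRUE),
    stopf("ablation_config: no must be 1..5"))
  do.call(experiment_config, utils::modifyList(base, list(...)))
}

#' Build a segmentation network from a configuration
#'
#' Parameters are initialized from `config$seed`, so the same configuration
#' always builds the same network.
#'
#' @param config an [experiment_config()].
#' @return an object of class `kseg_model` (an environment) with `forward`,
#'   `backward` closures, the constituent modules under `$layers`, and the
#'   configuration under `$config`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  self <- new_module("kseg_model")
  class(self) <- c("kseg_model", class(self))
  self$config <- config
  with_seed(config$seed, {
    enc <- if (config$encoder == "cfem")
      cfem_module(config$n_modalities)
    else tfem_module(config$n_modalities, window = config$window)
    self$layers$encoder <- enc
    if (config$use_kfem) {
      self$layers$kfem <- kfem_module(config$n_modalities)
      lv <- if (config$fusion_placement == "per_level") 1:5 else 5L
      self$fused_levels <- lv
      for (i in lv)
        self$layers[[paste0("fusion", i)]] <-
          if (config$use_daffm) daffm_module(PYRAMID_CHANNELS[i], config$r)
          else add_fusion_module()
    }
    self$layers$decoder <- decoder_module(config$num_classes)
  })
  self$forward <- function(x, training = TRUE) {
    x <- as_hwcn(x)
    xi <- self$layers$encoder$forward(x, training)
    if (self$config$use_kfem) {
      xk <- self$layers$kfem$forward(batch_to_kspace(x), training)
      fused <- xi
      for (i in self$fused_levels)
        fused[[i]] <- self$layers[[paste0("fusion", i)]]$forward(
          xi[[i]], xk[[i]], training)
    } else fused <- xi
    self$layers$decoder$forward(fused, training)
  }
  self$backward <- function(dlogits) {
    dfused <- self$layers$decoder$backward(dlogits)
    if (self$config$use_kfem) {
      dxi <- dfused
      dxk <- lapply(dfused, function(g) g * 0)
      for (i in self$fused_levels) {
        gr <- self$layers[[paste0("fusion", i)]]$backward(dfused[[i]])
        dxi[[i]] <- gr$dxi
        dxk[[i]] <- gr$dxk
      }
      self$layers$kfem$backward(dxk)
      self$layers$encoder$backward(dxi)
    } else {
      self$layers$encoder$backward(dfused)
    }
    invisible(NULL)
  }
  self
}

#' @export
print.kseg_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<kseg_model> encoder=%s kfem=%s fusion=%s (%s), %d classes, %d params\n",
              cfg$encoder, cfg$use_kfem,
              if (cfg$use_daffm) "daffm" else if (cfg$use_kfem) "add" else "none",
              cfg$fusion_placement, cfg$num_classes, count_params(x)))
  invisible(x)
}

#' Predict label masks for a batch of slices
#'
#' Runs the network in evaluation mode and maps the argmax class back to the
#' raw label vocabulary.
#'
#' @param model a `kseg_model`.
#' @param images `[H, W, C, N]` array, `[H, W, C]` array, or list of
#'   `phantom_slice` / `[H, W, C]` arrays.
#' @return list of integer masks `[H, W]` in raw labels.
#' @export
predict_masks <- function(model, images) {
  x <- stack_images(images)
  logits <- model$forward(x, training = FALSE)
  d <- dim(logits)
  out <- vector("list", d[4])
  for (n in seq_len(d[4])) {
    cls <- apply(logits[, , , n, drop = FALSE][, , , 1], c(1, 2), which.max)
    out[[n]] <- matrix(as.integer(model$config$label_values[cls]), d[1], d[2])
  }
  out
}

stack_images <- function(images) {
  if (is.list(images)) {
    arrs <- lapply(images, function(s)
      if (inherits(s, "phantom_slice")) s$image else s)
    d <- dim(arrs[[1]])
    x <- array(0, c(d, length(arrs)))
    for (i in seq_along(arrs)) x[, , , i] <- arrs[[i]]
    x
  } else as_hwcn(images)
}

#' Save / load model checkpoints
#'
#' A checkpoint stores the configuration plus every parameter and buffer
#' (including normalization running statistics), so a reloaded model
#' reproduces predictions exactly.
#'
#' @param model a `kseg_model`.
#' @param path file path.
#' @return `save_checkpoint`: invisibly the path; `load_checkpoint`: the
#'   restored model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = model$config, state = state_dict(model)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$config)
  load_state_dict(model, ck$state)
  model
}
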