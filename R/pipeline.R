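# Training loop (Adam, combined CE + Dice loss), k-fold cross-validation
# split, and evaluation tables.

mask_to_internal <- function(mask, label_values) {
  out <- matrix(match(mask, label_values) - 1L, nrow(mask), ncol(mask))
  if (anyNA(out)) stopf("mask contains labels outside the configured vocabulary")
  out
}

stack_masks <- function(dataset, label_values) {
  ms <- lapply(dataset, function(s)
    mask_to_internal(if (inherits(s, "phantom_slice")) s$mask else s,
                     label_values))
  d <- dim(ms[[1]])
  tgt <- array(0L, c(d, length(ms)))
  for (i in seq_along(ms)) tgt[, , i] <- ms[[i]]
  tgt
}

#' Train a segmentation model
#'
#' Runs Adam on the combined cross-entropy + Dice loss over seeded
#' mini-batches of the dataset. Per-step losses are logged; the returned
#' summary adds the full-dataset loss and mean region Dice of the final
#' parameters.
#'
#' @param model a `kseg_model` from [build_model()].
#' @param dataset list of `phantom_slice` objects (normalize beforehand,
#'   e.g. via [generate_phantom_dataset()]).
#' @param steps number of optimizer steps (default from the model config).
#' @param batch_size mini-batch size (capped at the dataset size).
#' @param lr learning rate (default from the model config; `lr = 0` leaves
#'   parameters untouched).
#' @param seed seed for batch sampling (default from the model config).
#' @param log_every record the running loss every this many steps.
#' @return list with `model`, `history` (data.frame: step, loss, ce, dice),
#'   `final_loss`, `final_ce`, `final_dice_loss`, `final_dice` (mean region
#'   Dice of hard predictions on the training set).
#' @export
train_model <- function(model, dataset, steps = NULL, batch_size = NULL,
                        lr = NULL, seed = NULL, log_every = 10L) {
  cfg <- model$config
  steps <- steps %||% cfg$steps
  batch_size <- min(batch_size %||% cfg$batch_size, length(dataset))
  lr <- lr %||% cfg$lr
  seed <- seed %||% cfg$seed
  layers <- collect_layers(model)
  history <- data.frame(step = integer(), loss = numeric(),
                        ce = numeric(), dice = numeric())
  with_seed(seed, {
    for (step in seq_len(steps)) {
      idx <- sample.int(length(dataset), batch_size,
                        replace = batch_size > length(dataset))
      batch <- dataset[idx]
      if (isTRUE(cfg$augment))
        batch <- lapply(seq_along(batch), function(i)
          augment(batch[[i]], seed = as.numeric(seed) * 1000 + step * 100 + i))
      x <- stack_images(batch)
      tgt <- stack_masks(batch, cfg$label_values)
      logits <- model$forward(x, training = TRUE)
      lg <- combined_loss_grad(logits, tgt, cfg$alpha, cfg$beta)
      if (!is.finite(lg$loss))
        stopf("training diverged at step %d (loss = %s); lower the learning rate",
              step, format(lg$loss))
      zero_grads(layers)
      model$backward(lg$dlogits)
      if (lr > 0) adam_step(layers, lr)
      if (step %% log_every == 0 || step == 1 || step == steps)
        history[nrow(history) + 1, ] <- list(step, lg$loss, lg$ce, lg$dice)
    }
  })
  fin <- dataset_loss(model, dataset)
  list(model = model, history = history, final_loss = fin$loss,
       final_ce = fin$ce, final_dice_loss = fin$dice,
       final_dice = fin$mean_region_dice)
}

# Full-dataset loss and mean region Dice with the current parameters
# (training-mode statistics for the loss, eval-mode hard predictions for
# the Dice), computed in small chunks to bound memory.
dataset_loss <- function(model, dataset, chunk = 8L) {
  cfg <- model$config
  tot <- c(loss = 0, ce = 0, dice = 0)
  nb <- 0
  for (i0 in seq(1, length(dataset), by = chunk)) {
    sub <- dataset[i0:min(i0 + chunk - 1, length(dataset))]
    x <- stack_images(sub)
    tgt <- stack_masks(sub, cfg$label_values)
    lg <- combined_loss_grad(model$forward(x, training = TRUE), tgt,
                             cfg$alpha, cfg$beta)
    tot <- tot + c(lg$loss, lg$ce, lg$dice)
    nb <- nb + 1
  }
  ev <- evaluate_model(model, dataset)
  as.list(c(tot / nb, mean_region_dice = mean(ev$summary$dice)))
}

#' k-fold cross-validation split
#'
#' Partitions case indices into `k` folds whose sizes differ by at most one,
#' deterministically for a given seed.
#'
#' @param n_cases number of cases (must be >= k).
#' @param k number of folds.
#' @param seed shuffle seed.
#' @return integer vector of length `n_cases` with fold assignments `1..k`.
#' @export
crossval_split <- function(n_cases, k = 5L, seed = 1L) {
  if (n_cases < k) stopf("crossval_split: n_cases (%d) < k (%d)", n_cases, k)
  sizes <- rep(n_cases %/% k, k) + (seq_len(k) <= n_cases %% k)
  folds <- integer(n_cases)
  with_seed(seed, {
    folds[sample.int(n_cases)] <- rep(seq_len(k), times = sizes)
  })
  folds
}

#' Evaluate predicted masks against ground truth
#'
#' Computes per-case and averaged Dice and HD95 for each evaluation region.
#'
#' @param pred_masks,true_masks lists of integer label masks (raw
#'   vocabulary).
#' @param regions character vector of region names (see [region_spec()]).
#' @param spacing pixel spacing in mm.
#' @return object of class `kseg_eval`: list with `per_case` and `summary`
#'   data frames.
#' @export
evaluate_masks <- function(pred_masks, true_masks,
                           regions = c("WT", "TC", "ET"), spacing = 1) {
  stopifnot(length(pred_masks) == length(true_masks))
  rows <- list()
  for (i in seq_along(pred_masks)) {
    for (rn in regions) {
      rs <- region_spec(rn)
      rows[[length(rows) + 1]] <- data.frame(
        case = i, region = rn,
        dice = dice_score(pred_masks[[i]], true_masks[[i]], rs),
        hd95 = suppressWarnings(
          hd95(pred_masks[[i]], true_masks[[i]], spacing, rs)))
    }
  }
  per_case <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(per_case, per_case$region),
    function(g) data.frame(region = g$region[1], dice = mean(g$dice),
                           hd95 = mean(g$hd95))))
  summary <- summary[match(regions, summary$region), ]
  rownames(summary) <- NULL
  structure(list(per_case = per_case, summary = summary,
                 spacing = spacing), class = "kseg_eval")
}

#' @export
print.kseg_eval <- function(x, ...) {
  cat("<kseg_eval>", length(unique(x$per_case$case)), "case(s)\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Evaluate a model on a dataset
#'
#' Predicts hard masks in evaluation mode and scores them per region.
#'
#' @param model a `kseg_model`.
#' @param dataset list of `phantom_slice` objects.
#' @param spacing pixel spacing in mm.
#' @param regions region names; default chosen by the model's profile.
#' @return a `kseg_eval` object.
#' @export
evaluate_model <- function(model, dataset, spacing = 1, regions = NULL) {
  regions <- regions %||% region_names_for(model$config$profile)
  preds <- predict_masks(model, dataset)
  truths <- lapply(dataset, function(s)
    if (inherits(s, "phantom_slice")) s$mask else s)
  evaluate_masks(preds, truths, regions, spacing)
}

#' Write an evaluation table to CSV or JSON
#'
#' @param x a `kseg_eval` object.
#' @param path output path; format inferred from the extension
#'   (`.csv` or `.json`).
#' @return invisibly `path`.
#' @export
write_metrics <- function(x, path) {
  stopifnot(inherits(x, "kseg_eval"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(per_case = x$per_case, summary = x$summary),
                         path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  } else {
    utils::write.csv(x$per_case, path, row.names = FALSE)
  }
  invisible(path)
}

#' Run the five-configuration ablation harness
#'
#' Builds each network variant, trains it for a given number of steps on
#' the supplied dataset, and evaluates it, returning one summary row per
#' configuration. Intended for desk-scale comparisons; the ordering of the
#' variants on a small phantom benchmark is reported, not guaranteed.
#'
#' @param dataset list of `phantom_slice` objects.
#' @param steps optimizer steps per variant.
#' @param seed build/training seed.
#' @param ... configuration overrides for all variants.
#' @return data.frame with configuration flags, final loss and mean Dice.
#' @export
run_ablation <- function(dataset, steps = 50L, seed = 42L, ...) {
  rows <- lapply(1:5, function(no) {
    cfg <- ablation_config(no, seed = seed, steps = steps, ...)
    model <- build_model(cfg)
    fit <- train_model(model, dataset)
    data.frame(no = no, encoder = cfg$encoder, kfem = cfg$use_kfem,
               daffm = cfg$use_daffm, final_loss = fit$final_loss,
               mean_dice = fit$final_dice)
  })
  do.call(rbind, rows)
}
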