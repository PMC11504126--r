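# Evaluation metrics on hard label masks: Dice overlap 2TP/(2TP+FP+FN) and
# the 95th-percentile symmetric Hausdorff boundary distance (HD95), with the
# BraTS nested region sets WT = {1,2,4}, TC = {1,4}, ET = {4} and cardiac
# structure sets for the three-class profile.

#' Evaluation region specification
#'
#' Maps a region name to the set of raw labels it comprises. Brain-tumor
#' regions are nested (ET within TC within WT); cardiac structures are the
#' single-label sets.
#'
#' @param name one of `"WT"`, `"TC"`, `"ET"` (tumor profile, raw labels
#'   1/2/4) or `"RV"`, `"Myo"`, `"LV"` (cardiac profile, labels 1/2/3).
#' @return object of class `region_spec` with fields `name`, `labels`.
#' @export
region_spec <- function(name) {
  labels <- switch(name,
    WT = c(1, 2, 4), TC = c(1, 4), ET = 4,
    RV = 1, Myo = 2, LV = 3,
    stopf("unknown region '%s'", name))
  structure(list(name = name, labels = labels), class = "region_spec")
}

#' @export
print.region_spec <- function(x, ...) {
  cat(sprintf("<region_spec> %s = {%s}\n", x$name,
              paste(x$labels, collapse = ",")))
  invisible(x)
}

region_names_for <- function(profile = c("brats", "acdc")) {
  switch(match.arg(profile), brats = c("WT", "TC", "ET"),
         acdc = c("RV", "Myo", "LV"))
}

binarize_region <- function(mask, region = NULL) {
  if (is.null(region)) return(mask != 0)
  if (inherits(region, "region_spec")) region <- region$labels
  array(mask %in% region, dim(mask))
}

#' Confusion counts between two binary masks
#'
#' @param pred,truth logical/0-1 arrays of identical shape.
#' @return list with `TP`, `FP`, `FN` pixel counts.
#' @export
confusion_counts <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stopf("confusion_counts: mask shapes differ")
  p <- pred != 0; t <- truth != 0
  list(TP = sum(p & t), FP = sum(p & !t), FN = sum(!p & t))
}

#' Dice similarity coefficient on hard masks
#'
#' `2*TP / (2*TP + FP + FN)` after binarizing both masks with the region's
#' label set. When both masks are empty for the region the score is 1 by
#' convention.
#'
#' @param pred,truth integer label masks of identical shape (raw label
#'   vocabulary), or binary masks if `region` is `NULL`.
#' @param region a [region_spec()], a vector of raw labels, or `NULL`
#'   (any nonzero label counts as positive).
#' @return scalar in `[0, 1]`.
#' @export
dice_score <- function(pred, truth, region = NULL) {
  pb <- binarize_region(pred, region)
  tb <- binarize_region(truth, region)
  cc <- confusion_counts(pb, tb)
  if (cc$TP + cc$FP + cc$FN == 0) return(1)
  2 * cc$TP / (2 * cc$TP + cc$FP + cc$FN)
}

# Boundary pixels: positives with at least one 4-neighbor outside the mask
# (the image border counts as outside).
boundary_pixels <- function(bin) {
  d <- dim(bin)
  pad <- matrix(FALSE, d[1] + 2, d[2] + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1)] <- bin
  inner <- pad[2:(d[1] + 1), 2:(d[2] + 1)]
  nb <- pad[1:d[1], 2:(d[2] + 1)] & pad[3:(d[1] + 2), 2:(d[2] + 1)] &
        pad[2:(d[1] + 1), 1:d[2]] & pad[2:(d[1] + 1), 3:(d[2] + 2)]
  which(inner & !nb, arr.ind = TRUE)
}

# Directed boundary distances: for each boundary pixel of `a`, the Euclidean
# distance to the nearest boundary pixel of `b`.
directed_boundary_dists <- function(a, b) {
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  sqrt(apply(d2, 1, min))
}

#' 95th-percentile symmetric Hausdorff boundary distance
#'
#' Binarizes both masks (optionally via a region's label set), extracts
#' boundary pixels, computes the two directed distance distributions
#' (each boundary point of one mask to its nearest boundary point of the
#' other), and returns the larger of their 95th percentiles, scaled to
#' millimetres by `spacing`. `hd95(A, A) = 0`. If exactly one mask is empty
#' a penalty (the image diagonal, by default) is returned with a warning;
#' if both are empty the distance is 0.
#'
#' @inheritParams dice_score
#' @param spacing pixel size in mm (scalar).
#' @param penalty value for the one-empty-mask case; default image diagonal
#'   times `spacing`.
#' @return scalar distance in mm.
#' @export
hd95 <- function(pred, truth, spacing = 1, region = NULL, penalty = NULL) {
  pb <- binarize_region(pred, region)
  tb <- binarize_region(truth, region)
  if (!identical(dim(pb), dim(tb))) stopf("hd95: mask shapes differ")
  pe <- !any(pb); te <- !any(tb)
  if (pe && te) return(0)
  if (pe || te) {
    pen <- penalty %||% (sqrt(sum(dim(pb)^2)) * spacing)
    warning("hd95: one mask is empty; returning the configured penalty")
    return(pen)
  }
  ba <- boundary_pixels(pb)
  bb <- boundary_pixels(tb)
  dab <- directed_boundary_dists(ba, bb)
  dba <- directed_boundary_dists(bb, ba)
  max(stats::quantile(dab, 0.95, names = FALSE, type = 7),
      stats::quantile(dba, 0.95, names = FALSE, type = 7)) * spacing
}
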