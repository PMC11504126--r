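# Seeded multi-modal phantom slices with nested tumor-like label regions,
# z-score normalization, and the augmentation pipeline (histogram matching,
# rotation, translation, scaling, elastic deformation, mirroring).
#
# Geometry: an axis-aligned brain ellipse; inside it an edema ellipse
# (label 2); inside that a core ellipse whose outer annulus is the enhancing
# rim (label 4) and whose interior is necrosis (label 1). Containment is
# guaranteed by construction (child semi-axes plus the center offset never
# exceed the parent semi-axes), which mirrors the nested evaluation regions
# ET within TC within WT. The cardiac profile instead places a ventricle
# disc (label 3) with a myocardium ring (label 2) and an adjacent second
# ventricle (label 1).
#
# Per-modality contrast: each tissue class has a fixed signature across the
# four modality channels (qualitatively mimicking T1 / T1Gd / T2 / FLAIR);
# the `contrast` parameter scales all signatures, so region mean differences
# are proportional to it exactly when noise_sigma = 0.

# rows: tissue classes; columns recycled over modalities
.phantom_signatures <- function(n_mod, profile) {
  sig <- if (profile == "brats") {
    # tissue, edema(2), necrosis(1), enhancing(4) for T1, T1Gd, T2, FLAIR
    rbind(tissue = c(0.55, 0.50, 0.45, 0.40),
          l2     = c(0.35, 0.40, 0.85, 0.95),
          l1     = c(0.20, 0.15, 0.70, 0.55),
          l4     = c(0.65, 1.00, 0.60, 0.75))
  } else {
    rbind(tissue = c(0.45, 0.50, 0.40, 0.45),
          l1     = c(0.90, 0.85, 0.80, 0.85),   # RV blood pool
          l2     = c(0.25, 0.30, 0.20, 0.25),   # myocardium
          l3     = c(0.95, 0.90, 0.85, 0.90))   # LV blood pool
  }
  sig[, ((seq_len(n_mod) - 1) %% ncol(sig)) + 1, drop = FALSE]
}

ellipse_mask <- function(H, W, cy, cx, ay, ax) {
  ys <- matrix(seq_len(H), H, W)
  xs <- matrix(seq_len(W), H, W, byrow = TRUE)
  ((ys - cy) / ay)^2 + ((xs - cx) / ax)^2 <= 1
}

#' Generate a synthetic multi-modal phantom slice
#'
#' Deterministic for a given seed. Produces an `[H, W, n_modalities]` image
#' and an integer label mask with the raw tumor vocabulary `{0, 1, 2, 4}`
#' (`profile = "brats"`) or three cardiac structures `{0, 1, 2, 3}`
#' (`profile = "acdc"`). Tumor labels are nested by construction:
#' label 4 within labels {1,4} within labels {1,2,4}.
#'
#' @param seed integer seed controlling geometry, contrast jitter and noise.
#' @param H,W slice size (must be divisible by 32 so the networks can
#'   process it).
#' @param n_modalities number of image channels.
#' @param contrast positive scale factor for the inter-region intensity
#'   differences; with `noise_sigma = 0`, region mean differences are
#'   exactly proportional to it.
#' @param noise_sigma standard deviation of the additive Gaussian noise.
#' @param profile `"brats"` (nested tumor) or `"acdc"` (cardiac structures).
#' @return object of class `phantom_slice`: list with `image` `[H,W,C]`,
#'   `mask` `[H,W]`, `seed`, `profile`.
#' @export
generate_phantom <- function(seed, H = 64, W = 64, n_modalities = 4,
                             contrast = 1, noise_sigma = 0.05,
                             profile = c("brats", "acdc")) {
  profile <- match.arg(profile)
  if (contrast <= 0)
    stopf("generate_phantom: contrast must be > 0 (regions must be distinguishable)")
  check_divisible(H, W, 32L, "phantom")
  with_seed(seed, {
    m <- min(H, W)
    mask <- matrix(0L, H, W)
    # brain ellipse
    b_ay <- runif(1, 0.32, 0.42) * m; b_ax <- runif(1, 0.32, 0.42) * m
    b_cy <- H / 2 + runif(1, -0.04, 0.04) * m
    b_cx <- W / 2 + runif(1, -0.04, 0.04) * m
    brain <- ellipse_mask(H, W, b_cy, b_cx, b_ay, b_ax)

    inside <- function(p_ay, p_ax, p_cy, p_cx, frac_lo, frac_hi) {
      ay <- runif(1, frac_lo, frac_hi) * p_ay
      ax <- runif(1, frac_lo, frac_hi) * p_ax
      cy <- p_cy + runif(1, -1, 1) * (p_ay - ay) * 0.5
      cx <- p_cx + runif(1, -1, 1) * (p_ax - ax) * 0.5
      list(ay = ay, ax = ax, cy = cy, cx = cx)
    }

    if (profile == "brats") {
      ed <- inside(b_ay, b_ax, b_cy, b_cx, 0.50, 0.62)
      edema <- ellipse_mask(H, W, ed$cy, ed$cx, ed$ay, ed$ax)
      co <- inside(ed$ay, ed$ax, ed$cy, ed$cx, 0.55, 0.70)
      core <- ellipse_mask(H, W, co$cy, co$cx, co$ay, co$ax)
      rin <- runif(1, 0.48, 0.62)
      core_in <- ellipse_mask(H, W, co$cy, co$cx, rin * co$ay, rin * co$ax)
      mask[edema] <- 2L
      mask[core] <- 4L       # enhancing rim: core minus interior
      mask[core_in] <- 1L    # necrotic interior
      classes <- list(tissue = brain & mask == 0, l1 = mask == 1,
                      l2 = mask == 2, l4 = mask == 4)
    } else {
      lv <- inside(b_ay, b_ax, b_cy, b_cx + 0.1 * m, 0.30, 0.40)
      myo_f <- runif(1, 1.35, 1.55)
      myo <- ellipse_mask(H, W, lv$cy, lv$cx, myo_f * lv$ay, myo_f * lv$ax)
      lvm <- ellipse_mask(H, W, lv$cy, lv$cx, lv$ay, lv$ax)
      rv_ax <- runif(1, 0.8, 1.1) * lv$ax
      rv_cx <- lv$cx - myo_f * lv$ax - 0.6 * rv_ax
      rvm <- ellipse_mask(H, W, lv$cy, rv_cx, 1.1 * lv$ay, rv_ax) & brain
      mask[rvm] <- 1L
      mask[myo] <- 2L
      mask[lvm] <- 3L
      classes <- list(tissue = brain & mask == 0, l1 = mask == 1,
                      l2 = mask == 2, l3 = mask == 3)
    }

    sig <- .phantom_signatures(n_modalities, profile)
    image <- array(0, c(H, W, n_modalities))
    base <- 0.1
    for (ci in seq_len(n_modalities)) {
      plane <- matrix(0, H, W)
      for (ti in seq_along(classes))
        plane[classes[[ti]]] <- base + contrast * sig[ti, ci]
      if (noise_sigma > 0)
        plane <- plane + matrix(rnorm(H * W, sd = noise_sigma), H, W)
      image[, , ci] <- plane
    }
    structure(list(image = image, mask = mask, seed = seed,
                   profile = profile),
              class = "phantom_slice")
  })
}

#' @export
print.phantom_slice <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<phantom_slice> %dx%d, %d modalities, labels {%s}, seed %d (%s)\n",
              d[1], d[2], d[3], paste(sort(unique(as.vector(x$mask))),
                                      collapse = ","), x$seed, x$profile))
  invisible(x)
}

#' Per-modality z-score normalization
#'
#' Standardizes each channel of one case to mean 0 and unit (population)
#' variance. Channels with (near-)zero variance are mapped to zeros.
#'
#' @param image real array `[H, W, C]` (or a `phantom_slice`, normalized in
#'   place).
#' @return the normalized image (or slice).
#' @export
zscore_normalize <- function(image) {
  if (inherits(image, "phantom_slice")) {
    image$image <- zscore_normalize(image$image)
    return(image)
  }
  x <- as_hwcn(image, batch = FALSE)
  d <- dim(x)
  for (ci in seq_len(d[3])) {
    v <- x[, , ci]
    mu <- mean(v)
    s <- sqrt(mean((v - mu)^2))
    x[, , ci] <- if (s < 1e-8) v * 0 else (v - mu) / s
  }
  x
}

# ---- geometric warps ------------------------------------------------------

# Backward-mapping resampler. A is the 2x2 linear part acting on centered
# (row, col) coordinates, t a translation (pixels), disp an optional
# additive displacement field (list dr, dc of [H,W] matrices). Out-of-image
# samples read as `fill`.
warp_plane <- function(plane, A, t = c(0, 0), disp = NULL,
                       interp = c("bilinear", "nearest"), fill = 0) {
  interp <- match.arg(interp)
  H <- nrow(plane); W <- ncol(plane)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  ys <- matrix(seq_len(H), H, W) - cy
  xs <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  sr <- A[1, 1] * ys + A[1, 2] * xs + cy + t[1]
  sc <- A[2, 1] * ys + A[2, 2] * xs + cx + t[2]
  if (!is.null(disp)) { sr <- sr + disp$dr; sc <- sc + disp$dc }
  if (interp == "nearest") {
    ri <- round(sr); ci <- round(sc)
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    out <- matrix(fill, H, W)
    out[ok] <- plane[cbind(ri[ok], ci[ok])]
    return(out)
  }
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  gv <- function(r, c) {
    ok <- r >= 1 & r <= H & c >= 1 & c <= W
    v <- matrix(fill, H, W)
    v[ok] <- plane[cbind(r[ok], c[ok])]
    v
  }
  (1 - fr) * (1 - fc) * gv(r0, c0) + (1 - fr) * fc * gv(r0, c0 + 1) +
    fr * (1 - fc) * gv(r0 + 1, c0) + fr * fc * gv(r0 + 1, c0 + 1)
}

# Smooth random displacement field: coarse Gaussian grid, bilinearly
# interpolated to full resolution.
elastic_field <- function(H, W, grid = 4, alpha = 2) {
  up <- function(coarse) {
    gy <- seq_len(nrow(coarse)); gx <- seq_len(ncol(coarse))
    ty <- seq(1, nrow(coarse), length.out = H)
    tx <- seq(1, ncol(coarse), length.out = W)
    tmp <- apply(coarse, 2, function(col) stats::approx(gy, col, ty)$y)
    t(apply(tmp, 1, function(row) stats::approx(gx, row, tx)$y))
  }
  list(dr = up(matrix(rnorm((grid + 2)^2, sd = alpha), grid + 2)),
       dc = up(matrix(rnorm((grid + 2)^2, sd = alpha), grid + 2)))
}

# Exact histogram matching of x to the value distribution of ref
# (equal-length vectors: rank lookup into the sorted reference).
match_histogram <- function(x, ref) {
  r <- rank(x, ties.method = "first")
  sorted_ref <- sort(ref)
  idx <- ceiling(r * length(ref) / length(x))
  array(sorted_ref[idx], dim(x))
}

#' Augment a phantom slice
#'
#' Applies a seeded random subset of the six standard transforms (histogram
#' matching, rotation, translation, scaling, elastic deformation,
#' mirroring). Each requested transform fires independently with
#' probability `prob`. The identical geometric map is applied to image and
#' mask; the image is resampled bilinearly, the mask with nearest-neighbor,
#' so the label vocabulary (and the nesting of the tumor regions) is
#' preserved. With `transforms = character(0)` the slice is returned
#' unchanged.
#'
#' @param slice a `phantom_slice`.
#' @param seed integer seed for the transform draw.
#' @param transforms subset of
#'   `c("histmatch", "rotate", "translate", "scale", "elastic", "mirror")`.
#' @param prob per-transform firing probability (transforms explicitly
#'   requested with `prob = 1` always fire).
#' @param rot_range rotation range in degrees (`c(lo, hi)` or a single
#'   half-range).
#' @param trans_frac maximum translation as a fraction of the image size.
#' @param scale_range multiplicative zoom range.
#' @param elastic_alpha,elastic_grid displacement amplitude (pixels) and
#'   coarse grid size of the elastic field.
#' @param reference optional `phantom_slice` used as the histogram-matching
#'   reference; defaults to a freshly generated phantom from a derived seed.
#' @return the augmented `phantom_slice`.
#' @export
augment <- function(slice, seed,
                    transforms = c("histmatch", "rotate", "translate",
                                   "scale", "elastic", "mirror"),
                    prob = 0.5, rot_range = 15, trans_frac = 0.1,
                    scale_range = c(0.9, 1.1), elastic_alpha = 2,
                    elastic_grid = 4, reference = NULL) {
  stopifnot(inherits(slice, "phantom_slice"))
  if (length(transforms) == 0) return(slice)
  transforms <- match.arg(transforms, several.ok = TRUE)
  if (length(rot_range) == 1) rot_range <- c(-rot_range, rot_range)
  with_seed(seed, {
    fire <- stats::runif(length(transforms)) < prob
    names(fire) <- transforms
    on_t <- function(nm) nm %in% transforms && isTRUE(fire[[nm]])

    img <- slice$image
    msk <- slice$mask
    H <- nrow(msk); W <- ncol(msk)

    if (on_t("histmatch")) {
      ref <- reference %||% generate_phantom(
        (slice$seed + 777L) %% .Machine$integer.max,
        H, W, dim(img)[3], profile = slice$profile)
      for (ci in seq_len(dim(img)[3]))
        img[, , ci] <- match_histogram(img[, , ci], ref$image[, , ci])
    }

    # compose rotation/scaling into one linear map (backward mapping uses
    # the inverse transform)
    theta <- if (on_t("rotate")) runif(1, rot_range[1], rot_range[2]) * pi / 180 else 0
    s <- if (on_t("scale")) runif(1, scale_range[1], scale_range[2]) else 1
    tr <- if (on_t("translate"))
      c(runif(1, -trans_frac, trans_frac) * H,
        runif(1, -trans_frac, trans_frac) * W) else c(0, 0)
    disp <- if (on_t("elastic")) elastic_field(H, W, elastic_grid, elastic_alpha)
            else NULL
    need_warp <- theta != 0 || s != 1 || any(tr != 0) || !is.null(disp)
    if (need_warp) {
      A <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)),
                  2, 2, byrow = TRUE) / s
      for (ci in seq_len(dim(img)[3]))
        img[, , ci] <- warp_plane(img[, , ci], A, -tr, disp, "bilinear")
      msk <- warp_plane(msk, A, -tr, disp, "nearest")
      storage.mode(msk) <- "integer"
    }

    if (on_t("mirror")) {
      img <- img[, W:1, , drop = FALSE]
      msk <- msk[, W:1, drop = FALSE]
    }

    slice$image <- img
    slice$mask <- msk
    slice
  })
}

#' Generate a seeded phantom dataset
#'
#' @param n number of slices.
#' @param seed base seed; slice i uses `seed + i`.
#' @param ... forwarded to [generate_phantom()].
#' @param normalize apply [zscore_normalize()] per case.
#' @return list of `phantom_slice` objects.
#' @export
generate_phantom_dataset <- function(n, seed, ..., normalize = TRUE) {
  lapply(seq_len(n), function(i) {
    s <- generate_phantom((seed + i) %% .Machine$integer.max, ...)
    if (normalize) zscore_normalize(s) else s
  })
}

# ---- NIfTI interoperability ----------------------------------------------

#' Write a phantom slice as a NIfTI image/mask pair
#'
#' Requires the optional RNifti package.
#'
#' @param slice a `phantom_slice`.
#' @param image_path,mask_path output paths (`.nii` / `.nii.gz`).
#' @return invisibly the two paths.
#' @export
write_phantom_nifti <- function(slice, image_path, mask_path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stopf("write_phantom_nifti requires the RNifti package")
  RNifti::writeNifti(slice$image, image_path)
  RNifti::writeNifti(slice$mask, mask_path)
  invisible(c(image_path, mask_path))
}

#' Read axial slices from a NIfTI volume
#'
#' Reads a NIfTI file and returns the requested axial slices as
#' `[H, W, C]` arrays (channels = volumes for 4D files, one channel for 3D).
#'
#' @param path NIfTI file path.
#' @param slices integer indices along the third axis; default all.
#' @return list of `[H, W, C]` arrays.
#' @export
read_nifti_slices <- function(path, slices = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stopf("read_nifti_slices requires the RNifti package")
  v <- RNifti::readNifti(path)
  d <- dim(v)
  if (length(d) == 2) return(list(array(v, c(d, 1L))))
  slices <- slices %||% seq_len(d[3])
  lapply(slices, function(z) {
    if (length(d) == 3) array(v[, , z], c(d[1:2], 1L))
    else aperm(v[, , z, , drop = FALSE], c(1, 2, 4, 3))[, , , 1]
  })
}
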