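# K-space transforms, half-plus-one row sampling, conjugate completion.
#
# Convention: unshifted orthonormal 2D DFT per channel. The DC bin sits at
# index [1,1] (frequency u = v = 0) and the transform is unitary, so
# sum(|x|^2) == sum(|k|^2) and the conjugate partner of row u is row
# (-u) mod H. A centered (DC at H/2) view is available for display only.

#' K-space grid
#'
#' A complex-valued frequency-domain grid for a multi-modality 2D slice,
#' together with a row sampling mask and the coordinate convention.
#'
#' @param data complex array `[H, W, C]` (a matrix is treated as one channel).
#' @param mask logical vector of length `H`; `TRUE` marks acquired rows.
#' @param convention `"unshifted"` (DC at index 1) or `"centered"`.
#' @return an object of class `kspace_grid` with fields `data`, `mask`,
#'   `convention`.
#' @seealso [image_to_kspace()], [half_plus_one_mask()], [conjugate_complete()]
#' @export
kspace_grid <- function(data, mask = NULL,
                        convention = c("unshifted", "centered")) {
  convention <- match.arg(convention)
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 3) stopf("kspace_grid: data must be [H, W, C]")
  if (!is.complex(data)) storage.mode(data) <- "complex"
  H <- dim(data)[1]
  mask <- mask %||% rep(TRUE, H)
  if (length(mask) != H || !is.logical(mask))
    stopf("kspace_grid: mask must be a logical vector of length H = %d", H)
  structure(list(data = data, mask = mask, convention = convention),
            class = "kspace_grid")
}

#' @export
print.kspace_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<kspace_grid> %d x %d, %d channel(s), %d/%d rows acquired (%s)\n",
              d[1], d[2], d[3], sum(x$mask), d[1], x$convention))
  invisible(x)
}

#' Forward 2D Fourier transform of an image into K-space
#'
#' Applies the orthonormal (unitary) 2D DFT independently to each modality
#' channel. [kspace_to_image()] is its exact inverse.
#'
#' @param image real array `[H, W, C]` (or `[H, W]` for one channel).
#' @return a fully sampled [kspace_grid()].
#' @export
image_to_kspace <- function(image) {
  image <- as_hwcn(image, batch = FALSE)
  check_finite(image, "image")
  d <- dim(image)
  if (d[1] < 2 || d[2] < 2) stopf("image_to_kspace: H and W must be >= 2")
  k <- array(complex(real = 0), d)
  s <- sqrt(prod(d[1:2]))
  for (c in seq_len(d[3])) k[, , c] <- stats::fft(image[, , c]) / s
  kspace_grid(k)
}

#' Inverse Fourier transform of a K-space grid back to an image
#'
#' Requires a fully sampled grid (complete a half grid with
#' [conjugate_complete()] first). The inverse transform of a grid that came
#' from a real-valued image is real up to floating-point error; the imaginary
#' residue is checked and discarded.
#'
#' @param k a [kspace_grid()] with all rows acquired.
#' @param warn_tol,err_tol imaginary-residue thresholds: residues above
#'   `warn_tol` raise a warning, above `err_tol` an error (a non-real source
#'   or a corrupted grid).
#' @return real array `[H, W, C]`.
#' @export
kspace_to_image <- function(k, warn_tol = 1e-5, err_tol = 1e-3) {
  stopifnot(inherits(k, "kspace_grid"))
  if (!all(k$mask))
    stopf("kspace_to_image: grid is partially sampled; run conjugate_complete() first")
  if (k$convention != "unshifted")
    k <- kspace_uncenter(k)
  d <- dim(k$data)
  x <- array(0, d)
  s <- sqrt(prod(d[1:2]))
  resid <- 0
  for (c in seq_len(d[3])) {
    z <- stats::fft(k$data[, , c], inverse = TRUE) / s
    resid <- max(resid, max(abs(Im(z))))
    x[, , c] <- Re(z)
  }
  if (resid >= err_tol)
    stopf("kspace_to_image: imaginary residue %.3g >= %.1g; source was not real-valued",
          resid, err_tol)
  if (resid > warn_tol)
    warning(sprintf("kspace_to_image: imaginary residue %.3g discarded", resid))
  x
}

#' Half-plus-one row sampling mask
#'
#' Selects the DC row plus all non-negative frequency rows
#' `u = 0 .. floor(H/2)` in unshifted coordinates (for even `H` this includes
#' the Nyquist row), i.e. `floor(H/2) + 1` rows in total. The remaining rows
#' of a real image's K-space are recoverable by conjugate symmetry.
#'
#' @param H grid height (>= 2).
#' @return logical vector of length `H`.
#' @export
half_plus_one_mask <- function(H) {
  if (!is.numeric(H) || length(H) != 1 || H < 2 || H != round(H))
    stopf("half_plus_one_mask: H must be a single integer >= 2")
  H <- as.integer(H)
  seq_len(H) <= (H %/% 2L + 1L)
}

#' Apply a row sampling mask to a K-space grid
#'
#' Zeroes the unacquired rows and records the mask, emulating a partial
#' acquisition.
#'
#' @param k a [kspace_grid()].
#' @param mask logical row mask of length `H`.
#' @return a partially sampled [kspace_grid()].
#' @export
apply_sampling_mask <- function(k, mask) {
  stopifnot(inherits(k, "kspace_grid"))
  H <- dim(k$data)[1]
  if (length(mask) != H) stopf("apply_sampling_mask: mask length != H")
  k$data[!mask, , ] <- 0
  k$mask <- as.logical(mask)
  k
}

#' Complete a half-sampled K-space grid by conjugate symmetry
#'
#' For a real-valued source image, `k[u, v] = Conj(k[(-u) mod H, (-v) mod W])`,
#' so every row missing from a half-plus-one acquisition has an acquired
#' conjugate partner. Missing rows are filled from their partners; the result
#' is fully sampled. If the source image had a genuine imaginary component the
#' completed grid is wrong (conjugate symmetry does not hold) - this is a
#' documented limitation, not detectable from the half grid alone.
#'
#' @param k a partially sampled [kspace_grid()] (a fully sampled grid is
#'   returned unchanged).
#' @return a fully sampled [kspace_grid()].
#' @export
conjugate_complete <- function(k) {
  stopifnot(inherits(k, "kspace_grid"))
  if (all(k$mask)) return(k)
  d <- dim(k$data)
  H <- d[1]; W <- d[2]
  rev_w <- c(1L, if (W > 1) W:2L)          # column v -> (-v) mod W
  for (r in which(!k$mask)) {
    partner <- ((H - (r - 1L)) %% H) + 1L  # row u -> (-u) mod H
    if (!k$mask[partner])
      stopf("conjugate_complete: row %d has no acquired conjugate partner (row %d)",
            r, partner)
    k$data[r, , ] <- Conj(k$data[partner, rev_w, , drop = FALSE])
  }
  k$mask <- rep(TRUE, H)
  k
}

#' Centered view of a K-space grid (DC at H/2, W/2)
#'
#' For visualization only; all internal computation uses the unshifted
#' convention.
#'
#' @param k a [kspace_grid()].
#' @return a [kspace_grid()] with `convention = "centered"`.
#' @export
kspace_center <- function(k) {
  stopifnot(inherits(k, "kspace_grid"))
  if (k$convention == "centered") return(k)
  d <- dim(k$data)
  sh <- function(n) c((n %/% 2 + 1):n, 1:(n %/% 2))
  k$data <- k$data[sh(d[1]), sh(d[2]), , drop = FALSE]
  k$mask <- k$mask[sh(d[1])]
  k$convention <- "centered"
  k
}

kspace_uncenter <- function(k) {
  if (k$convention == "unshifted") return(k)
  d <- dim(k$data)
  sh <- function(n) c((n - n %/% 2 + 1):n, 1:(n - n %/% 2))
  k$data <- k$data[sh(d[1]), sh(d[2]), , drop = FALSE]
  k$mask <- k$mask[sh(d[1])]
  k$convention <- "unshifted"
  k
}

# Batched image [H,W,C,N] -> complex_tensor of its (optionally half-sampled
# and conjugate-completed) K-space. Used by the network forward pass.
batch_to_kspace <- function(x, half_sample = TRUE) {
  d <- dim(x)
  re <- array(0, d); im <- array(0, d)
  for (n in seq_len(d[4])) {
    k <- image_to_kspace(x[, , , n, drop = TRUE])
    if (half_sample) {
      k <- apply_sampling_mask(k, half_plus_one_mask(d[1]))
      k <- conjugate_complete(k)
    }
    re[, , , n] <- Re(k$data)
    im[, , , n] <- Im(k$data)
  }
  complex_tensor(re, im)
}
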