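#' Min-max normalize an image stack to [0, 1]
#'
#' Linear rescale over the whole stack (all images jointly), so that the
#' global minimum maps to 0 and the global maximum to 1. Invariant under
#' positive affine transforms of the input.
#'
#' @param x A numeric matrix, a list of matrices, or a `cm_contrast_stack`.
#' @return The same structure with intensities rescaled to `[0, 1]`.
#' @export
#' @examples
#' normalize_stack(matrix(c(10, 20, 30, 40), 2))
normalize_stack <- function(x) {
  imgs <- if (inherits(x, "cm_contrast_stack")) x$images
          else if (is.list(x)) x else list(x)
  lo <- min(vapply(imgs, min, 0)); hi <- max(vapply(imgs, max, 0))
  if (hi <= lo) abort("Constant stack cannot be normalized.", class = "cm_normalization_error")
  imgs <- lapply(imgs, function(im) (im - lo) / (hi - lo))
  if (inherits(x, "cm_contrast_stack")) { x$images <- imgs; x }
  else if (is.list(x) && !is.matrix(x)) imgs
  else imgs[[1]]
}

#' Quantize normalized intensities into evenly spaced bins
#'
#' Values in `[0, 1]` are mapped to integer gray levels
#' `min(floor(v * n_bins), n_bins - 1)`, i.e. `n_bins` evenly spaced bins
#' with the upper edge clamped into the last bin.
#'
#' @param values Numeric vector/matrix with all values in `[0, 1]`.
#' @param n_bins Number of bins, `>= 2` (default 200).
#' @return A list with `levels` (integers in `0 .. n_bins - 1`, same shape
#'   as the input) and `occupancy` (number of distinct levels present).
#' @export
#' @examples
#' quantize(c(0, 0.5, 1), n_bins = 200)$levels
quantize <- function(values, n_bins = 200L) {
  if (n_bins < 2L) abort("`n_bins` must be >= 2.", class = "cm_parameter_error")
  if (any(values < 0 | values > 1)) {
    abort("All values must lie in [0, 1]; normalize first.", class = "cm_range_error")
  }
  lev <- pmin(floor(values * n_bins), n_bins - 1L)
  storage.mode(lev) <- "integer"
  dim(lev) <- dim(values)
  list(levels = lev, occupancy = length(unique(as.vector(lev))))
}

#' First-order variance of ROI intensities
#'
#' Population variance (division by n) of the intensity values inside the
#' ROI, the first-order spread feature of the texture analysis.
#'
#' @param values Numeric vector of ROI intensities (normalized by
#'   convention, though any units work).
#' @return Population variance.
#' @export
first_order_variance <- function(values) {
  if (length(values) < 2L) abort("Need >= 2 values.", class = "cm_parameter_error")
  mean((values - mean(values))^2)
}

# default 2D distance-1 offsets: (drow, dcol) for the 4 unique directions
default_glcm_offsets <- function() {
  list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
}

#' Gray-level co-occurrence matrix of an ROI
#'
#' Counts how often pairs of quantized gray levels co-occur at each spatial
#' offset, with both voxels of a pair required to lie inside the ROI.
#' With `symmetric = TRUE` each pair is counted in both orders. Each
#' offset's matrix is normalized to sum 1; features are averaged across
#' offsets downstream.
#'
#' @param levels Integer matrix of gray levels in `0 .. n_levels - 1`
#'   (from [quantize()]).
#' @param roi_mask Logical matrix; `NULL` uses the whole image.
#' @param offsets List of `c(drow, dcol)` offsets; default the four unique
#'   distance-1 2D directions.
#' @param symmetric Count pairs in both orders? Default `TRUE`.
#' @param n_levels Number of gray levels; default `max(levels) + 1`.
#' @return A `cm_glcm`: list of normalized matrices (one per offset) plus
#'   metadata.
#' @export
compute_glcm <- function(levels, roi_mask = NULL, offsets = default_glcm_offsets(),
                         symmetric = TRUE, n_levels = NULL) {
  stopifnot(is.matrix(levels))
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, nrow(levels), ncol(levels))
  if (!all(dim(roi_mask) == dim(levels))) {
    abort("ROI mask geometry does not match.", class = "cm_shape_error")
  }
  if (!any(roi_mask)) abort("Empty ROI.", class = "cm_empty_roi")
  n_levels <- n_levels %||% (max(levels[roi_mask]) + 1L)
  nr <- nrow(levels); nc <- ncol(levels)
  mats <- vector("list", length(offsets))
  any_pairs <- FALSE
  for (k in seq_along(offsets)) {
    dr <- offsets[[k]][1]; dc <- offsets[[k]][2]
    r1 <- max(1L, 1L - dr):min(nr, nr - dr)
    c1 <- max(1L, 1L - dc):min(nc, nc - dc)
    ok <- roi_mask[r1, c1, drop = FALSE] & roi_mask[r1 + dr, c1 + dc, drop = FALSE]
    a <- levels[r1, c1, drop = FALSE][ok]
    b <- levels[r1 + dr, c1 + dc, drop = FALSE][ok]
    M <- matrix(0, n_levels, n_levels)
    if (length(a)) {
      counts <- tabulate(a * n_levels + b + 1L, nbins = n_levels^2)
      M <- matrix(counts, n_levels, n_levels, byrow = TRUE)
      if (symmetric) M <- M + t(M)
      M <- M / sum(M)
      any_pairs <- TRUE
    }
    mats[[k]] <- M
  }
  if (!any_pairs) abort("ROI has no valid neighbor pairs.", class = "cm_empty_roi")
  structure(list(matrices = mats, offsets = offsets, symmetric = symmetric,
                 n_levels = n_levels, normalized = TRUE),
            class = "cm_glcm")
}

#' GLCM texture features
#'
#' Joint energy `sum(p^2)`, joint entropy `-sum(p log2 p)` (zero cells are
#' skipped, the limit of the epsilon-guarded sum), and inverse difference
#' (homogeneity) `sum(p / (1 + |i - j|))`, each computed per offset matrix
#' and averaged across offsets.
#'
#' @param glcm A normalized [compute_glcm()] result.
#' @return One-row tibble with `energy`, `entropy`, `inverse_difference`.
#' @export
glcm_features <- function(glcm) {
  stopifnot(inherits(glcm, "cm_glcm"))
  if (!isTRUE(glcm$normalized)) {
    abort("GLCM must be normalized.", class = "cm_state_error")
  }
  ng <- glcm$n_levels
  idiff <- 1 / (1 + abs(outer(seq_len(ng), seq_len(ng), "-")))
  per_offset <- vapply(glcm$matrices, function(M) {
    nz <- M[M > 0]
    c(energy = sum(M^2),
      entropy = -sum(nz * log2(nz)),
      inverse_difference = sum(M * idiff))
  }, numeric(3))
  as_tibble(as.list(rowMeans(per_offset)))
}

#' Full texture feature set of a circular ROI
#'
#' Convenience wrapper reproducing the bone-texture analysis: intensities
#' (already normalized to `[0, 1]` across the stack) are quantized into
#' `n_bins` evenly spaced bins; the first-order variance is computed on the
#' raw normalized ROI values; energy, entropy and inverse difference come
#' from the offset-averaged symmetric distance-1 GLCM.
#'
#' @param image Normalized image matrix (values in `[0, 1]`).
#' @param roi_mask Logical ROI membership matrix.
#' @param n_bins Number of gray-level bins (default 200).
#' @param offsets,symmetric Passed to [compute_glcm()].
#' @return One-row tibble with `variance`, `energy`, `entropy`,
#'   `inverse_difference`, `bin_occupancy`.
#' @export
texture_features <- function(image, roi_mask, n_bins = 200L,
                             offsets = default_glcm_offsets(), symmetric = TRUE) {
  q <- quantize(image, n_bins)
  occ <- length(unique(as.vector(q$levels[roi_mask])))
  glcm <- compute_glcm(q$levels, roi_mask, offsets, symmetric, n_levels = n_bins)
  feats <- glcm_features(glcm)
  dplyr::bind_cols(
    tibble(variance = first_order_variance(image[roi_mask])),
    feats,
    tibble(bin_occupancy = occ)
  )
}
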