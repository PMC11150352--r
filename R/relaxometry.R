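#' Mono-exponential relaxation fit for one voxel
#'
#' Log-linear least-squares fit of `ln S = ln S0 - tau / T`. With two
#' points this reduces exactly to the closed form
#' `T = (tau2 - tau1) / ln(S1 / S2)`. The fit is unweighted and exact on
#' noiseless mono-exponential data.
#'
#' @param signals Positive signal intensities, one per preparation duration.
#' @param taus Preparation durations in ms, strictly increasing.
#' @return A list with `s0`, `t` (ms) and `valid`. Non-positive signals or
#'   non-decaying series (last signal >= first) are flagged invalid with
#'   `NA` estimates rather than raising, so voxel-wise mapping can mask them.
#' @export
#' @examples
#' fit_monoexp(c(1000, 1000 * exp(-1)), c(0, 50))  # T = 50 ms
fit_monoexp <- function(signals, taus) {
  if (length(signals) != length(taus) || length(taus) < 2L) {
    abort("`signals` and `taus` must have equal length >= 2.", class = "cm_parameter_error")
  }
  if (any(diff(taus) <= 0)) {
    abort("`taus` must be strictly increasing.", class = "cm_parameter_error")
  }
  if (any(signals <= 0) || signals[length(signals)] >= signals[1]) {
    return(list(s0 = NA_real_, t = NA_real_, valid = FALSE))
  }
  y <- log(signals)
  tc <- taus - mean(taus)
  slope <- sum(tc * y) / sum(tc^2)
  if (slope >= 0) return(list(s0 = NA_real_, t = NA_real_, valid = FALSE))
  list(s0 = exp(mean(y) - slope * mean(taus)), t = -1 / slope, valid = TRUE)
}

#' Voxel-wise relaxation mapping
#'
#' Applies the mono-exponential log-linear fit to every voxel of a
#' prep-weighted contrast stack, producing a T2 or T1rho map according to
#' the stack's contrast family. Voxels are marked invalid (mask `FALSE`,
#' value `NA`) when any echo signal falls at or below the noise floor, when
#' the signal does not decay, or when the fitted time exceeds `cap`.
#'
#' The default floor is three times the background noise sigma estimated
#' from the 10-pixel border frame of the first echo (Rayleigh mean over
#' `sqrt(pi/2)`); pass `floor = 0` for noise-free data.
#'
#' @param stack A [simulate_stack()] result (or compatible list).
#' @param mask Optional logical matrix restricting the fit.
#' @param floor Signal validity floor; `NULL` for the 3-sigma default.
#' @param cap Upper bound (ms) on reported relaxation times (default 500).
#' @return An object of class `cm_relaxation_map` with matrices `values`
#'   (ms, `NA` where invalid), `mask`, `s0`, plus the family tag and spacing.
#' @export
map_relaxation <- function(stack, mask = NULL, floor = NULL, cap = 500) {
  stopifnot(inherits(stack, "cm_contrast_stack") || is.list(stack))
  if (cap <= 0) abort("`cap` must be > 0.", class = "cm_parameter_error")
  dims <- dim(stack$images[[1]])
  if (is.null(mask)) mask <- matrix(TRUE, dims[1], dims[2])
  if (!all(dim(mask) == dims)) {
    abort("Mask geometry does not match the stack.", class = "cm_shape_error")
  }
  if (is.null(floor)) {
    floor <- 3 * estimate_background_sigma(stack$images[[1]],
                                           spacing = stack$spacing %||% NA_real_)
  }
  if (floor < 0) abort("`floor` must be >= 0.", class = "cm_parameter_error")

  taus <- stack$taus
  S <- vapply(stack$images, as.vector, numeric(prod(dims)))  # voxels x echoes
  ok <- as.vector(mask) & rowSums(S <= floor | S <= 0) == 0
  ok[ok] <- S[ok, ncol(S)] < S[ok, 1]
  values <- s0 <- rep(NA_real_, prod(dims))
  if (any(ok)) {
    Y <- log(S[ok, , drop = FALSE])
    tc <- taus - mean(taus)
    slope <- as.vector(Y %*% tc) / sum(tc^2)
    t_hat <- -1 / slope
    good <- slope < 0 & t_hat <= cap
    values[ok][good] <- t_hat[good]
    s0[ok][good] <- exp(rowMeans(Y)[good] - slope[good] * mean(taus))
    ok[ok] <- good
  }
  structure(
    list(values = matrix(values, dims[1], dims[2]),
         mask = matrix(ok, dims[1], dims[2]),
         s0 = matrix(s0, dims[1], dims[2]),
         family = stack$family %||% "unknown",
         spacing = stack$spacing %||% NA_real_,
         floor = floor, cap = cap),
    class = "cm_relaxation_map"
  )
}

# Rayleigh-corrected background sigma from the air frame of an image.
# The frame width defaults to 2 mm when the spacing is known; the median is
# used (Rayleigh median = sigma * sqrt(2 log 2)) so stray bright voxels in
# the frame do not inflate the estimate.
estimate_background_sigma <- function(image, spacing = NA_real_, border = NULL) {
  n <- dim(image)
  if (is.null(border)) {
    border <- if (is.finite(spacing) && spacing > 0) round(1.8 / spacing) else 10L
  }
  b <- max(2L, min(border, floor(min(n) / 4)))
  frame <- rbind(image[seq_len(b), ], image[n[1] - seq_len(b) + 1, ])
  frame <- c(frame, image[, seq_len(b)], image[, n[2] - seq_len(b) + 1])
  stats::median(frame) / sqrt(2 * log(2))
}

#' @export
print.cm_relaxation_map <- function(x, ...) {
  cat(sprintf("<cm_relaxation_map> %s: %d x %d, %d valid voxels, median %.1f ms\n",
              x$family, nrow(x$values), ncol(x$values), sum(x$mask),
              stats::median(x$values[x$mask])))
  invisible(x)
}

#' @rdname map_relaxation
#' @param x A `cm_relaxation_map`.
#' @param ... Unused.
#' @export
glance.cm_relaxation_map <- function(x, ...) {
  v <- x$values[x$mask]
  tibble(family = x$family, n_valid = sum(x$mask),
         mean = mean(v), sd = stats::sd(v), median = stats::median(v),
         floor = x$floor, cap = x$cap)
}
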