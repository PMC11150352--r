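#' Extract a signal-intensity line profile
#'
#' Samples an image by bilinear interpolation at uniform arc-length steps
#' along the world-space segment from `p0` to `p1`, emulating a manually
#' annotated line placed through a cartilage defect and its adjacent
#' cartilage.
#'
#' @param image Numeric matrix; world coordinates are
#'   `(index - 1) * spacing` mm in x (columns) and y (rows).
#' @param p0,p1 Segment endpoints, `c(x, y)` in mm.
#' @param spacing Pixel spacing in mm.
#' @param step Sampling step in mm; default one quarter of the spacing.
#' @return A `cm_line_profile`: a tibble with columns `position` (mm arc
#'   length from `p0`) and `intensity`, carrying the endpoints and step as
#'   attributes.
#' @export
#' @examples
#' img <- matrix(7, 32, 32)
#' prof <- extract_profile(img, c(1, 4), c(6, 4), spacing = 0.5)
#' all(prof$intensity == 7)
extract_profile <- function(image, p0, p1, spacing, step = 0.25 * spacing) {
  if (step <= 0) abort("`step` must be > 0.", class = "cm_parameter_error")
  L <- sqrt(sum((p1 - p0)^2))
  n <- floor(L / step + 1e-9) + 1L
  if (n < 10L) abort("Profile must contain at least 10 samples.", class = "cm_geometry_error")
  pos <- (seq_len(n) - 1L) * step
  u <- (p1 - p0) / L
  xs <- p0[1] + pos * u[1]
  ys <- p0[2] + pos * u[2]
  # continuous pixel coordinates, 1-based
  cx <- xs / spacing + 1
  cy <- ys / spacing + 1
  if (any(cx < 1 | cx > ncol(image) | cy < 1 | cy > nrow(image))) {
    abort("Profile endpoints lie outside the image.", class = "cm_geometry_error")
  }
  c0 <- pmin(floor(cx), ncol(image) - 1L); r0 <- pmin(floor(cy), nrow(image) - 1L)
  fx <- cx - c0; fy <- cy - r0
  val <- image[cbind(r0, c0)] * (1 - fx) * (1 - fy) +
    image[cbind(r0, c0 + 1)] * fx * (1 - fy) +
    image[cbind(r0 + 1, c0)] * (1 - fx) * fy +
    image[cbind(r0 + 1, c0 + 1)] * fx * fy
  new_line_profile(pos, val, p0, p1, step)
}

new_line_profile <- function(position, intensity, p0 = NULL, p1 = NULL, step = NULL) {
  out <- tibble(position = position, intensity = intensity)
  attr(out, "p0") <- p0
  attr(out, "p1") <- p1
  attr(out, "step") <- step %||% position[2] - position[1]
  class(out) <- c("cm_line_profile", class(out))
  out
}

#' Construct a line profile from raw samples
#'
#' @param position Strictly increasing, uniformly spaced positions (mm).
#' @param intensity Sample intensities.
#' @return A `cm_line_profile` tibble.
#' @export
line_profile <- function(position, intensity) {
  stopifnot(length(position) == length(intensity))
  d <- diff(position)
  if (length(position) < 10L || any(d <= 0) || max(abs(d - d[1])) > 1e-8 * d[1]) {
    abort("Positions must be uniform, strictly increasing, with >= 10 samples.",
          class = "cm_parameter_error")
  }
  new_line_profile(position, intensity)
}

#' Normalize a line profile to unit maximum
#'
#' @param profile A `cm_line_profile`.
#' @return The profile with intensities divided by their maximum (which
#'   becomes exactly 1). Idempotent.
#' @export
normalize_profile <- function(profile) {
  m <- max(profile$intensity)
  if (m <= 0) abort("Profile maximum must be > 0.", class = "cm_normalization_error")
  profile$intensity <- profile$intensity / m
  profile
}

#' Cartilage background level of a defect profile
#'
#' The background is the mean of the two flank means: the first and last
#' `flank_fraction` of samples are taken as the cartilage on either side of
#' the defect.
#'
#' @param profile A `cm_line_profile` (normalized or not).
#' @param flank_fraction Fraction of samples per flank, in (0, 0.4].
#' @return Background level (same units as the profile).
#' @export
estimate_background <- function(profile, flank_fraction = 0.2) {
  if (flank_fraction <= 0 || flank_fraction > 0.4) {
    abort("`flank_fraction` must be in (0, 0.4].", class = "cm_parameter_error")
  }
  n <- nrow(profile)
  k <- max(1L, floor(n * flank_fraction))
  (mean(profile$intensity[seq_len(k)]) +
      mean(profile$intensity[n - seq_len(k) + 1L])) / 2
}

# interpolated crossing of level h nearest the index `from`, scanning outward.
# side = -1 searches left of `from`, +1 right; returns NA if none.
.crossing <- function(x, y, h, from, side) {
  i <- from
  repeat {
    j <- i + side
    if (j < 1L || j > length(y)) return(NA_real_)
    if ((y[i] >= h) != (y[j] >= h)) {
      return(x[i] + (h - y[i]) / (y[j] - y[i]) * (x[j] - x[i]))
    }
    i <- j
  }
}

#' Full width at half maximum of a defect profile
#'
#' The half-maximum level sits halfway between the cartilage background and
#' the profile maximum. Crossings of that level are located by linear
#' interpolation between adjacent samples; the FWHM is the distance between
#' the crossings nearest the global maximum on its left and right.
#'
#' @param profile A normalized `cm_line_profile` (maximum 1).
#' @param background Cartilage background level, `< 1`;
#'   default [estimate_background()].
#' @return A list with `fwhm` (mm), `crossings` (left, right positions in
#'   mm), and `half_level`.
#' @export
compute_fwhm <- function(profile, background = estimate_background(profile)) {
  y <- profile$intensity; x <- profile$position
  if (abs(max(y) - 1) > 1e-6) {
    abort("Profile must be normalized to maximum 1.", class = "cm_parameter_error")
  }
  if (background >= 1) abort("`background` must be < 1.", class = "cm_parameter_error")
  h <- background + 0.5 * (1 - background)
  peak <- which.max(y)
  left <- .crossing(x, y, h, peak, -1L)
  right <- .crossing(x, y, h, peak, +1L)
  if (is.na(left) || is.na(right)) {
    abort("Profile never dips below the half-maximum level on both sides: no enclosed defect.",
          class = "cm_no_defect")
  }
  list(fwhm = right - left, crossings = c(left, right), half_level = h)
}

#' Edge width (10-90 % shoulder width) of a defect profile
#'
#' Per defect shoulder, the positions where the profile crosses the 10 % and
#' 90 % intensity levels are located by linear interpolation on the rising
#' (left) and falling (right) defect edges; the shoulder width is their
#' distance and the edge width is the mean of the two shoulder widths.
#'
#' With `relative = FALSE` (default) the levels are absolute fractions of
#' the normalized maximum, 0.10 and 0.90. With `relative = TRUE` they are
#' taken relative to the background-to-maximum range,
#' `background + f * (1 - background)` — the reading needed when the
#' cartilage background itself exceeds 10 % of the maximum.
#'
#' @inheritParams compute_fwhm
#' @param relative Measure the 10/90 % levels relative to the
#'   background-to-maximum range instead of the absolute maximum?
#' @return A list with `ew` (mm), `shoulders` (left, right widths in mm)
#'   and the two threshold levels used.
#' @export
compute_edge_width <- function(profile, background = estimate_background(profile),
                               relative = FALSE) {
  y <- profile$intensity; x <- profile$position
  if (abs(max(y) - 1) > 1e-6) {
    abort("Profile must be normalized to maximum 1.", class = "cm_parameter_error")
  }
  if (background >= 1) abort("`background` must be < 1.", class = "cm_parameter_error")
  lo <- if (relative) background + 0.10 * (1 - background) else 0.10
  hi <- if (relative) background + 0.90 * (1 - background) else 0.90
  if (background >= lo && !relative) {
    abort("Background exceeds the 10 % level; the absolute threshold is unreachable. Consider `relative = TRUE`.",
          class = "cm_threshold_unreachable")
  }
  peak <- which.max(y)
  l_hi <- .crossing(x, y, hi, peak, -1L)
  r_hi <- .crossing(x, y, hi, peak, +1L)
  if (is.na(l_hi) || is.na(r_hi)) {
    abort("No defect shoulders found at the 90 % level.", class = "cm_no_defect")
  }
  # continue outward from just inside the 90 % crossings to the 10 % level
  l_from <- min(which(x >= l_hi))
  r_from <- max(which(x <= r_hi))
  l_lo <- .crossing(x, y, lo, l_from, -1L)
  r_lo <- .crossing(x, y, lo, r_from, +1L)
  if (is.na(l_lo) || is.na(r_lo)) {
    abort("Profile never reaches the 10 % level on both shoulders.",
          class = "cm_threshold_unreachable")
  }
  shoulders <- c(left = l_hi - l_lo, right = r_lo - r_hi)
  list(ew = mean(shoulders), shoulders = shoulders, levels = c(lo = lo, hi = hi))
}

#' Defect delineability metrics from an image and a line annotation
#'
#' Chains [extract_profile()], [normalize_profile()],
#' [estimate_background()], [compute_fwhm()] and [compute_edge_width()] into
#' a one-row tibble, the per-defect record of the delineability analysis.
#'
#' @inheritParams extract_profile
#' @param flank_fraction Passed to [estimate_background()].
#' @param relative Passed to [compute_edge_width()].
#' @return One-row tibble with `fwhm`, `ew`, `shoulder_left`,
#'   `shoulder_right`, `background`, `half_level`.
#' @export
delineate_defect <- function(image, p0, p1, spacing, step = 0.25 * spacing,
                             flank_fraction = 0.2, relative = FALSE) {
  prof <- normalize_profile(extract_profile(image, p0, p1, spacing, step))
  bg <- estimate_background(prof, flank_fraction)
  fw <- compute_fwhm(prof, bg)
  ewr <- compute_edge_width(prof, bg, relative = relative)
  tibble(fwhm = fw$fwhm, ew = ewr$ew,
         shoulder_left = unname(ewr$shoulders["left"]),
         shoulder_right = unname(ewr$shoulders["right"]),
         background = bg, half_level = fw$half_level)
}
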