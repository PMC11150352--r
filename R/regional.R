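#' Regional relaxation-time statistics
#'
#' Mean, standard deviation and voxel count of a relaxation map over each
#' cartilage region, restricted to the map's validity mask, plus a pooled
#' "all" row combining the regions voxel-wise (so the pooled mean is the
#' voxel-count-weighted mean of the regional means). Regions with no valid
#' voxels are kept in the output with `n_voxels = 0` and `NA` statistics
#' rather than silently dropped.
#'
#' @param map A [map_relaxation()] result.
#' @param labels Integer region matrix as from [region_labels()] (0 outside
#'   the regions), or any matrix of the same geometry whose positive codes
#'   index `region_names`.
#' @param region_names Names of the region codes.
#' @return A tibble with columns `region`, `mean`, `sd`, `n_voxels`;
#'   the final row is the pooled `"all"` region.
#' @export
regional_stats <- function(map, labels,
                           region_names = attr(labels, "levels") %||% REGION_LEVELS) {
  stopifnot(inherits(map, "cm_relaxation_map"))
  if (!all(dim(labels) == dim(map$values))) {
    abort("Label geometry does not match the map.", class = "cm_shape_error")
  }
  rows <- purrr::map(seq_along(region_names), function(k) {
    v <- map$values[labels == k & map$mask]
    tibble(region = region_names[k],
           mean = if (length(v)) mean(v) else NA_real_,
           sd = if (length(v) > 1) stats::sd(v) else if (length(v)) 0 else NA_real_,
           n_voxels = length(v))
  })
  pooled <- map$values[labels > 0 & map$mask]
  dplyr::bind_rows(
    rows,
    tibble(region = "all",
           mean = if (length(pooled)) mean(pooled) else NA_real_,
           sd = if (length(pooled) > 1) stats::sd(pooled) else NA_real_,
           n_voxels = length(pooled))
  )
}

#' Digital-caliper cartilage thickness
#'
#' Thickness of the contiguous cartilage run through a point, measured along
#' a given direction: starting at the voxel containing `location`, voxels are
#' stepped one voxel-length at a time in both directions while they remain
#' inside the mask, and the count is multiplied by the spacing — a caliper
#' whose step size is one pixel.
#'
#' @param mask Logical cartilage mask matrix.
#' @param location Point `c(x, y)` in world mm; must lie inside the mask.
#' @param direction Direction vector `c(dx, dy)` (normalized internally);
#'   typically the local surface normal.
#' @param spacing Pixel spacing in mm.
#' @return Thickness in mm (a multiple of `spacing`).
#' @export
#' @examples
#' m <- matrix(FALSE, 40, 40); m[10:20, 15] <- TRUE
#' measure_thickness(m, location = c(14 * 0.27, 14 * 0.27),
#'                   direction = c(0, 1), spacing = 0.27)
measure_thickness <- function(mask, location, direction, spacing) {
  u <- direction / sqrt(sum(direction^2))
  at <- function(t) {
    x <- location[1] + t * u[1]; y <- location[2] + t * u[2]
    r <- round(y / spacing) + 1; c <- round(x / spacing) + 1
    if (r < 1 || r > nrow(mask) || c < 1 || c > ncol(mask)) return(FALSE)
    mask[r, c]
  }
  if (!at(0)) abort("`location` lies outside the cartilage mask.", class = "cm_geometry_error")
  count <- 1L
  t <- spacing
  while (at(t)) { count <- count + 1L; t <- t + spacing }
  t <- -spacing
  while (at(t)) { count <- count + 1L; t <- t - spacing }
  count * spacing
}

#' Cartilage thickness adjacent to a phantom defect
#'
#' Measures the femoral cartilage thickness along the local surface normal
#' at a point one millimeter beyond a defect's posterior edge, the
#' programmatic counterpart of placing the digital caliper next to the
#' defect.
#'
#' @inheritParams defect_line_endpoints
#' @param offset Arc-length offset (mm) beyond the defect edge.
#' @return Thickness in mm.
#' @export
thickness_adjacent_to_defect <- function(model, diameter = 8, offset = 1) {
  stopifnot(inherits(model, "cm_tissue_model"))
  i <- match(diameter, model$defect_centers$diameter)
  if (is.na(i)) abort("No defect with that nominal diameter.", class = "cm_parameter_error")
  g <- model$geom
  theta <- model$defect_centers$theta[i] -
    (diameter / 2 + offset) / g$rm_mid       # posterior side of the defect
  loc <- c(g$cx + g$rm_mid * cos(theta), g$cy + g$rm_mid * sin(theta))
  mask <- model$labels == tissue_code("cartilage") & model$region %in% 1:3
  measure_thickness(mask, loc, direction = c(cos(theta), sin(theta)),
                    spacing = model$spacing)
}
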