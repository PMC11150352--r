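#' Tissue and region label vocabularies
#'
#' `TISSUE_LEVELS` lists the phantom tissue classes in label-code order;
#' `REGION_LEVELS` the cartilage regions (anterior, central, posterior
#' femoral and tibial). [tissue_code()] converts a tissue name to its
#' integer label code.
#'
#' @export
TISSUE_LEVELS <- c("background", "cartilage", "bone", "marrow", "fluid", "muscle")

#' @rdname TISSUE_LEVELS
#' @export
REGION_LEVELS <- c("aF", "cF", "pF", "T")

#' @rdname TISSUE_LEVELS
#' @param name Tissue class name.
#' @export
tissue_code <- function(name) match(name, TISSUE_LEVELS)

# arc margins for defect placement along the femoral band (mm)
.DEFECT_EDGE_MARGIN <- 4
.DEFECT_GAP <- 6

#' Build a digital knee phantom
#'
#' Rasterizes the tissue model described by a [phantom_spec()]: a femoral
#' condyle (textured marrow inside a cortical shell) carrying a curved
#' cartilage band of uniform thickness, a thin intra-articular fluid film, a
#' flat tibial plateau with its own cartilage layer, muscle and an air
#' background. When `defects = TRUE`, full-thickness fluid-filled gaps whose
#' width across the band mid-surface equals the nominal punch diameter are
#' cut into the femoral band, ordered anterior to posterior. The femoral band
#' is partitioned into anterior/central/posterior regions by arc-length
#' thirds; tibial cartilage forms the fourth region.
#'
#' Two calls with the same spec (and hence seed) are voxel-identical, and a
#' paired pre-defect model is obtained by `defects = FALSE` with the same
#' spec, so pre/post comparisons see the identical anatomy.
#'
#' @param spec A [phantom_spec()].
#' @param defects Place the cartilage defects? Default `TRUE`.
#'
#' @return An object of class `cm_tissue_model`: tissue label matrix,
#'   region label matrix, parameter maps (`pd`, `t2`, `t1rho`), fat mask,
#'   spacing/origin, and a tibble of defect centers.
#' @export
#' @examples
#' model <- build_phantom(phantom_spec())
#' table(TISSUE_LEVELS[model$labels])
build_phantom <- function(spec, defects = TRUE) {
  stopifnot(inherits(spec, "cm_phantom_spec"))
  ny <- spec$grid_shape[1]; nx <- spec$grid_shape[2]; sp <- spec$spacing
  H <- (ny - 1) * sp; W <- (nx - 1) * sp
  th <- spec$cartilage_thickness
  R <- spec$condyle_radius
  cx <- W / 2
  cy <- max(4, 0.13 * H)

  if (cy + R + th + 1.5 > H) {
    abort("Grid too small for the condyle geometry; enlarge `grid_shape` or shrink `condyle_radius`.",
          class = "cm_parameter_error")
  }

  X <- matrix((seq_len(nx) - 1) * sp, ny, nx, byrow = TRUE)
  Y <- matrix((seq_len(ny) - 1) * sp, ny, nx)
  dx <- X - cx; dy <- Y - cy
  r <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)                     # y grows downward; lower arc has theta in (0, pi)
  span <- c(35, 145) * pi / 180              # angular extent of the femoral band
  in_span <- theta >= span[1] & theta <= span[2]
  rm_mid <- R + th / 2                       # band mid-surface radius
  arc_len <- rm_mid * diff(span)
  # arc coordinate from the anterior end (anterior = large theta = small x)
  s_arc <- (span[2] - theta) * rm_mid

  lab <- matrix(tissue_code("muscle"), ny, nx)
  lab[r <= R - 2] <- tissue_code("marrow")
  lab[r > R - 2 & r <= R] <- tissue_code("bone")
  lab[r > R & r <= R + th & in_span] <- tissue_code("cartilage")
  lab[r > R + th & r <= R + th + 0.8 & in_span] <- tissue_code("fluid")

  # tibial plateau: flat cartilage layer over bone, spanning the condyle width
  yt <- cy + R + th + 1.2
  tib_x <- abs(dx) <= 0.75 * R
  tib_cart <- Y >= yt & Y < yt + 2 & tib_x
  lab[tib_cart] <- tissue_code("cartilage")
  lab[Y >= yt + 2 & Y < yt + 4 & tib_x] <- tissue_code("bone")
  lab[Y >= yt + 4 & tib_x] <- tissue_code("marrow")
  lab[Y > cy + R + th + 0.8 & Y < yt & tib_x] <- tissue_code("fluid")

  # 2 mm air frame
  frame <- X < 2 | X > W - 2 | Y < 2 | Y > H - 2
  lab[frame] <- tissue_code("background")

  femoral_cart <- lab == tissue_code("cartilage") & !tib_cart

  # defect placement along the mid-surface, anterior to posterior
  centers <- place_defects(spec$defect_diameters, arc_len)
  defect_tbl <- tibble(
    diameter = spec$defect_diameters,
    s = centers,
    theta = span[2] - centers / rm_mid,
    x = cx + rm_mid * cos(span[2] - centers / rm_mid),
    y = cy + rm_mid * sin(span[2] - centers / rm_mid)
  )
  if (defects) {
    for (i in seq_len(nrow(defect_tbl))) {
      gap <- femoral_cart & abs(s_arc - defect_tbl$s[i]) <= defect_tbl$diameter[i] / 2
      lab[gap] <- tissue_code("fluid")
      femoral_cart[gap] <- FALSE
    }
  }

  # regions: femoral arc-length thirds + tibial cartilage
  region <- matrix(0L, ny, nx)
  thirds <- findInterval(s_arc, c(arc_len / 3, 2 * arc_len / 3)) + 1L
  region[femoral_cart] <- thirds[femoral_cart]
  region[tib_cart & lab == tissue_code("cartilage")] <- 4L

  # parameter maps
  tp <- spec$tissue_params[match(TISSUE_LEVELS, spec$tissue_params$tissue), ]
  pd <- matrix(tp$pd[lab], ny, nx)
  t2 <- matrix(tp$t2[lab], ny, nx)
  t1rho <- matrix(tp$t1rho[lab], ny, nx)
  fat <- matrix(tp$fat[lab], ny, nx)
  for (k in 1:4) {
    t2[region == k] <- spec$regional_t2[[REGION_LEVELS[k]]]
    t1rho[region == k] <- spec$regional_t1rho[[REGION_LEVELS[k]]]
  }

  # trabecular marrow texture: smoothed seeded noise on proton density
  if (spec$marrow_texture_sd > 0) {
    marrow <- lab == tissue_code("marrow")
    set.seed(derive_seed(spec$seed, 11L))
    field <- matrix(rnorm(ny * nx), ny, nx)
    if (spec$marrow_texture_scale > 0) {
      field <- blur_gaussian(field, spec$marrow_texture_scale, sp)
    }
    field <- field / stats::sd(field[marrow])
    pd[marrow] <- pmax(0, pd[marrow] * (1 + spec$marrow_texture_sd * field[marrow]))
  }

  structure(
    list(labels = lab, region = region, pd = pd, t2 = t2, t1rho = t1rho,
         fat = fat, spacing = sp, origin = c(0, 0), spec = spec,
         defects_enabled = defects, defect_centers = defect_tbl,
         geom = list(cx = cx, cy = cy, R = R, th = th, rm_mid = rm_mid,
                     span = span, arc_len = arc_len)),
    class = "cm_tissue_model"
  )
}

# sequential anterior->posterior placement; errors if the band cannot hold them
place_defects <- function(diameters, arc_len) {
  cursor <- .DEFECT_EDGE_MARGIN
  centers <- numeric(length(diameters))
  for (i in seq_along(diameters)) {
    centers[i] <- cursor + diameters[i] / 2
    cursor <- cursor + diameters[i] + .DEFECT_GAP
    if (centers[i] + diameters[i] / 2 + .DEFECT_EDGE_MARGIN > arc_len) {
      abort(sprintf("Cannot place the %.1f mm defect without overlap on a %.1f mm band.",
                    diameters[i], arc_len),
            class = "cm_placement_error")
    }
  }
  centers
}

#' @export
print.cm_tissue_model <- function(x, ...) {
  cat("<cm_tissue_model>\n")
  cat(sprintf("  grid: %d x %d @ %.3f mm; defects %s\n",
              nrow(x$labels), ncol(x$labels), x$spacing,
              if (x$defects_enabled) "on" else "off"))
  print(table(factor(TISSUE_LEVELS[x$labels], levels = TISSUE_LEVELS)))
  invisible(x)
}

#' Region label map of a phantom
#'
#' @param model A [build_phantom()] result.
#' @return Integer matrix with 0 outside cartilage and 1..4 for the
#'   anterior/central/posterior femoral and tibial regions; the level names
#'   are in `attr(, "levels")`.
#' @export
region_labels <- function(model) {
  stopifnot(inherits(model, "cm_tissue_model"))
  structure(model$region, levels = REGION_LEVELS)
}

#' Line-profile endpoints through a phantom defect
#'
#' Returns the endpoints (world mm) of the straight line tangent to the
#' cartilage band mid-surface at a defect's center, extended by `flank` mm of
#' adjacent cartilage on either side — the programmatic equivalent of the
#' manual line placement through a defect and its neighboring cartilage.
#'
#' @param model A [build_phantom()] result.
#' @param diameter Nominal diameter (mm) of the defect to transect.
#' @param flank Cartilage flank length (mm) beyond each defect edge.
#' @return List with numeric `p0`, `p1` (x, y world coordinates in mm).
#' @export
defect_line_endpoints <- function(model, diameter, flank = 3) {
  stopifnot(inherits(model, "cm_tissue_model"))
  i <- match(diameter, model$defect_centers$diameter)
  if (is.na(i)) abort("No defect with that nominal diameter.", class = "cm_parameter_error")
  ct <- model$defect_centers[i, ]
  g <- model$geom
  p <- c(ct$x, ct$y)
  tangent <- c(sin(ct$theta), -cos(ct$theta))   # unit vector along the band
  half <- diameter / 2 + flank
  list(p0 = p - half * tangent, p1 = p + half * tangent)
}

#' Circular texture ROI under a phantom defect
#'
#' Places a circular region of interest of the given pixel diameter in the
#' subchondral/trabecular bone radially beneath a defect, mirroring the
#' manual ROI placed directly adjacent to the 5-mm defect.
#'
#' @inheritParams defect_line_endpoints
#' @param roi_diameter_px ROI diameter in pixels (default 40).
#' @return List with `center` (world mm), `center_px` (row, col),
#'   `diameter_px`, and a logical `mask` matrix of ROI membership.
#' @export
texture_roi <- function(model, diameter = 5, roi_diameter_px = 40) {
  stopifnot(inherits(model, "cm_tissue_model"))
  i <- match(diameter, model$defect_centers$diameter)
  if (is.na(i)) abort("No defect with that nominal diameter.", class = "cm_parameter_error")
  g <- model$geom; sp <- model$spacing
  theta <- model$defect_centers$theta[i]
  roi_r_mm <- roi_diameter_px * sp / 2
  rc <- g$R - 2 - roi_r_mm - 1           # ROI fully inside the marrow compartment
  if (rc - roi_r_mm < 0) {
    abort("ROI does not fit inside the marrow compartment.", class = "cm_parameter_error")
  }
  center <- c(g$cx + rc * cos(theta), g$cy + rc * sin(theta))
  center_px <- c(round(center[2] / sp) + 1, round(center[1] / sp) + 1)
  mask <- circular_mask(dim(model$labels), center_px, roi_diameter_px)
  list(center = center, center_px = center_px,
       diameter_px = roi_diameter_px, mask = mask)
}

#' Circular ROI membership mask
#'
#' Voxel centers within `diameter_px / 2` of the ROI center belong to the ROI.
#'
#' @param dim Image dimensions `c(rows, cols)`.
#' @param center_px ROI center as (row, col), 1-based.
#' @param diameter_px ROI diameter in pixels.
#' @return Logical matrix.
#' @export
circular_mask <- function(dim, center_px, diameter_px) {
  if (diameter_px <= 0) abort("`diameter_px` must be > 0.", class = "cm_parameter_error")
  rows <- matrix(seq_len(dim[1]), dim[1], dim[2])
  cols <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  m <- (rows - center_px[1])^2 + (cols - center_px[2])^2 <= (diameter_px / 2)^2
  if (center_px[1] - diameter_px / 2 < 0.5 || center_px[1] + diameter_px / 2 > dim[1] + 0.5 ||
      center_px[2] - diameter_px / 2 < 0.5 || center_px[2] + diameter_px / 2 > dim[2] + 0.5) {
    abort("ROI extends outside the image.", class = "cm_geometry_error")
  }
  m
}

#' Measure a defect gap across the band mid-surface
#'
#' Samples the cartilage-band mid-surface at fine arc steps and measures the
#' contiguous non-cartilage gap nearest a defect center, in mm. Used to
#' verify that rasterized defects have their nominal width.
#'
#' @inheritParams defect_line_endpoints
#' @return Gap width in mm.
#' @export
measure_defect_gap <- function(model, diameter) {
  stopifnot(inherits(model, "cm_tissue_model"))
  i <- match(diameter, model$defect_centers$diameter)
  if (is.na(i)) abort("No defect with that nominal diameter.", class = "cm_parameter_error")
  g <- model$geom; sp <- model$spacing
  step <- sp / 4
  s <- seq(0, g$arc_len, by = step)
  theta <- g$span[2] - s / g$rm_mid
  xs <- g$cx + g$rm_mid * cos(theta)
  ys <- g$cy + g$rm_mid * sin(theta)
  rows <- pmin(pmax(round(ys / sp) + 1, 1), nrow(model$labels))
  cols <- pmin(pmax(round(xs / sp) + 1, 1), ncol(model$labels))
  is_cart <- model$labels[cbind(rows, cols)] == tissue_code("cartilage")
  # walk outward from the defect center until cartilage is met on both sides
  i0 <- which.min(abs(s - model$defect_centers$s[i]))
  if (is_cart[i0]) return(0)
  left <- i0; while (left > 1 && !is_cart[left - 1]) left <- left - 1
  right <- i0; while (right < length(s) && !is_cart[right + 1]) right <- right + 1
  (right - left + 1) * step
}
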