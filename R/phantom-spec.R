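#' Default tissue parameter table
#'
#' One row per tissue class with proton density (arbitrary units),
#' T2 and T1rho relaxation times (ms) and a fat flag. Cartilage relaxation
#' times given here are base values; [phantom_spec()] assigns region-specific
#' cartilage values via its `regional_t2` / `regional_t1rho` arguments.
#'
#' @return A tibble with columns `tissue`, `pd`, `t2`, `t1rho`, `fat`.
#' @export
#' @examples
#' default_tissue_params()
default_tissue_params <- function() {
  tibble::tribble(
    ~tissue,      ~pd,   ~t2, ~t1rho, ~fat,
    "background",   0,     1,      1, FALSE,
    "cartilage", 1000,    50,     40, FALSE,
    "bone",       150,    10,     10, FALSE,
    "marrow",     900,    60,     50, TRUE,
    "fluid",     2000,   400,    300, FALSE,
    "muscle",     600,    35,     30, FALSE
  )
}

#' Specify a digital knee phantom
#'
#' Collects the geometric and tissue parameters of a sagittal knee-like
#' phantom: a femoral condyle (cortical bone shell around textured marrow)
#' carrying a curved cartilage band, a flat tibial plateau, intra-articular
#' fluid, muscle, and an air background. Full-thickness, fluid-filled
#' punch-type cartilage defects of the nominal diameters can be placed along
#' the femoral band, ordered anterior to posterior.
#'
#' @param grid_shape Integer vector `c(rows, cols)` of the voxel grid.
#' @param spacing In-plane voxel spacing in mm (isotropic). The default,
#'   0.27 mm, corresponds to a 140 mm field of view reconstructed on a
#'   512-pixel matrix (see [pixel_spacing()]).
#' @param defect_diameters Nominal defect diameters in mm, anterior to
#'   posterior. Default `c(3, 5, 8)`.
#' @param tissue_params Tissue parameter table as from
#'   [default_tissue_params()].
#' @param regional_t2,regional_t1rho Named numeric vectors giving the
#'   cartilage relaxation times (ms) of the anterior (`aF`), central (`cF`),
#'   posterior (`pF`) femoral regions and the tibial region (`T`). Defaults
#'   are representative pre-defect means of healthy-to-moderately degenerated
#'   human cartilage at 3 T.
#' @param cartilage_thickness Femoral cartilage thickness in mm.
#' @param condyle_radius Subchondral bone radius of the condyle model in mm.
#' @param marrow_texture_sd Relative standard deviation of the trabecular
#'   proton-density texture in marrow (0 disables texture).
#' @param marrow_texture_scale Correlation length (mm) of the marrow texture.
#' @param noise_sigma Default Rician noise sigma (arbitrary units) used by
#'   [simulate_stack()] when not overridden there.
#' @param seed Integer seed controlling the marrow texture field.
#'
#' @return An object of class `cm_phantom_spec`.
#' @export
#' @examples
#' spec <- phantom_spec(grid_shape = c(128, 128))
#' spec$defect_diameters
phantom_spec <- function(grid_shape = c(224L, 224L),
                         spacing = 0.27,
                         defect_diameters = c(3, 5, 8),
                         tissue_params = default_tissue_params(),
                         regional_t2 = c(aF = 48, cF = 51, pF = 64, T = 41),
                         regional_t1rho = c(aF = 43, cF = 41, pF = 34, T = 36),
                         cartilage_thickness = 3,
                         condyle_radius = 20,
                         marrow_texture_sd = 0.25,
                         marrow_texture_scale = 0.4,
                         noise_sigma = 0,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape < 32L)) {
    abort("`grid_shape` must be two integers >= 32.", class = "cm_parameter_error")
  }
  if (spacing <= 0) abort("`spacing` must be > 0.", class = "cm_parameter_error")
  if (any(defect_diameters <= 0)) {
    abort("All defect diameters must be > 0.", class = "cm_parameter_error")
  }
  required <- c("background", "cartilage", "bone", "marrow", "fluid", "muscle")
  if (!all(required %in% tissue_params$tissue)) {
    abort("`tissue_params` must cover all six tissue classes.",
          class = "cm_parameter_error")
  }
  if (any(tissue_params$pd < 0)) {
    abort("Proton densities must be >= 0.", class = "cm_parameter_error")
  }
  if (any(tissue_params$t2 <= 0) || any(tissue_params$t1rho <= 0)) {
    abort("All relaxation times must be > 0.", class = "cm_parameter_error")
  }
  regs <- c("aF", "cF", "pF", "T")
  stopifnot(all(regs %in% names(regional_t2)), all(regs %in% names(regional_t1rho)))
  if (any(regional_t2 <= 0) || any(regional_t1rho <= 0)) {
    abort("Regional relaxation times must be > 0.", class = "cm_parameter_error")
  }
  if (noise_sigma < 0) abort("`noise_sigma` must be >= 0.", class = "cm_parameter_error")
  if (cartilage_thickness <= 0 || condyle_radius <= 0) {
    abort("Geometry parameters must be > 0.", class = "cm_parameter_error")
  }
  structure(
    list(
      grid_shape = grid_shape,
      spacing = spacing,
      defect_diameters = as.numeric(defect_diameters),
      tissue_params = tissue_params,
      regional_t2 = regional_t2[regs],
      regional_t1rho = regional_t1rho[regs],
      cartilage_thickness = cartilage_thickness,
      condyle_radius = condyle_radius,
      marrow_texture_sd = marrow_texture_sd,
      marrow_texture_scale = marrow_texture_scale,
      noise_sigma = noise_sigma,
      seed = as.integer(seed)
    ),
    class = "cm_phantom_spec"
  )
}

#' @export
print.cm_phantom_spec <- function(x, ...) {
  cat("<cm_phantom_spec>\n")
  cat(sprintf("  grid: %d x %d @ %.3f mm\n", x$grid_shape[1], x$grid_shape[2], x$spacing))
  cat(sprintf("  defects: %s mm\n", paste(x$defect_diameters, collapse = ", ")))
  cat(sprintf("  cartilage T2 (aF/cF/pF/T): %s ms\n",
              paste(x$regional_t2, collapse = "/")))
  invisible(x)
}

#' Specify a simulated acquisition
#'
#' Describes one magnetization-prepared multi-contrast acquisition: the
#' contrast family (T2-preparation proton-density fat-saturated, or
#' spin-lock-prepared T1-weighted), its preparation durations, which echoes
#' are fat-suppressed, and the point-spread blur of the readout.
#'
#' @param family `"T2prep-PDFS"` or `"SLprep-T1w"`.
#' @param taus Preparation durations in ms, strictly increasing and starting
#'   at 0. Defaults: `c(0, 50)` for T2 preparation, `c(0, 25, 50)` for
#'   spin-lock preparation.
#' @param fat_suppressed Logical per echo. Defaults mirror the interleaved
#'   protocol: the proton-density echo of the T2-prep family is
#'   fat-saturated and its T2-weighted echo is not; the T1-weighted echo of
#'   the spin-lock family is not fat-saturated while the spin-lock-prepared
#'   echoes are.
#' @param blur_sigma Gaussian point-spread sigma in mm (0 = no blur).
#' @param sl_freq_hz Spin-lock frequency in Hz (metadata only).
#' @param label Free-text sequence label carried into study tables.
#'
#' @return An object of class `cm_sequence_params`.
#' @export
#' @examples
#' sequence_params("T2prep-PDFS", blur_sigma = 0.4)
sequence_params <- function(family = c("T2prep-PDFS", "SLprep-T1w"),
                            taus = NULL,
                            fat_suppressed = NULL,
                            blur_sigma = 0,
                            sl_freq_hz = 500,
                            label = NULL) {
  family <- match.arg(family)
  if (is.null(taus)) {
    taus <- if (family == "T2prep-PDFS") c(0, 50) else c(0, 25, 50)
  }
  if (length(taus) < 2L || taus[1] != 0 || any(diff(taus) <= 0)) {
    abort("`taus` must be strictly increasing, start at 0, and have >= 2 entries.",
          class = "cm_parameter_error")
  }
  if (is.null(fat_suppressed)) {
    fat_suppressed <- if (family == "T2prep-PDFS") {
      c(TRUE, rep(FALSE, length(taus) - 1L))
    } else {
      c(FALSE, rep(TRUE, length(taus) - 1L))
    }
  }
  if (length(fat_suppressed) != length(taus)) {
    abort("`fat_suppressed` must match `taus` in length.", class = "cm_parameter_error")
  }
  if (blur_sigma < 0) abort("`blur_sigma` must be >= 0.", class = "cm_parameter_error")
  structure(
    list(family = family, taus = as.numeric(taus),
         fat_suppressed = as.logical(fat_suppressed),
         blur_sigma = blur_sigma, sl_freq_hz = sl_freq_hz,
         label = label %||% family),
    class = "cm_sequence_params"
  )
}

#' @export
print.cm_sequence_params <- function(x, ...) {
  cat(sprintf("<cm_sequence_params> %s (%s): tau = %s ms, blur sigma %.2f mm\n",
              x$label, x$family, paste(x$taus, collapse = "/"), x$blur_sigma))
  invisible(x)
}
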