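#' Write a contrast stack as NIfTI files with a JSON sidecar
#'
#' Each echo is written as `<prefix>_echo<k>.nii.gz` with the correct pixel
#' dimensions; a `<prefix>.json` sidecar records the contrast family,
#' preparation durations, fat-suppression flags and blur/noise settings.
#'
#' @param stack A [simulate_stack()] result.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return The sidecar path, invisibly.
#' @export
write_stack <- function(stack, dir, prefix = "stack") {
  stopifnot(inherits(stack, "cm_contrast_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (e in seq_along(stack$images)) {
    img <- RNifti::asNifti(stack$images[[e]],
                           pixdim = c(stack$spacing, stack$spacing))
    RNifti::writeNifti(img, file.path(dir, sprintf("%s_echo%d.nii.gz", prefix, e)))
  }
  side <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(
    list(family = stack$family, label = stack$label, taus = stack$taus,
         fat_suppressed = stack$fat_suppressed, spacing = stack$spacing,
         blur_sigma = stack$blur_sigma, noise_sigma = stack$noise_sigma),
    side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

#' Read a contrast stack written by [write_stack()]
#'
#' @param dir Directory containing the files.
#' @param prefix File name prefix used when writing.
#' @return A `cm_contrast_stack`.
#' @export
read_stack <- function(dir, prefix = "stack") {
  meta <- jsonlite::read_json(file.path(dir, paste0(prefix, ".json")),
                              simplifyVector = TRUE)
  images <- lapply(seq_along(meta$taus), function(e) {
    v <- RNifti::readNifti(file.path(dir, sprintf("%s_echo%d.nii.gz", prefix, e)))
    matrix(as.vector(v), dim(v)[1], dim(v)[2])
  })
  structure(
    list(images = images, taus = meta$taus, fat_suppressed = meta$fat_suppressed,
         family = meta$family, label = meta$label, spacing = meta$spacing,
         blur_sigma = meta$blur_sigma, noise_sigma = meta$noise_sigma),
    class = "cm_contrast_stack"
  )
}

#' Write a relaxation map (values + validity mask) as NIfTI
#'
#' Invalid voxels are encoded as NaN in the value image; the mask is written
#' alongside as `<prefix>_mask.nii.gz`.
#'
#' @param map A [map_relaxation()] result.
#' @param dir Output directory.
#' @param prefix File name prefix.
#' @return The value-image path, invisibly.
#' @export
write_map <- function(map, dir, prefix = "map") {
  stopifnot(inherits(map, "cm_relaxation_map"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vals <- map$values
  vals[!map$mask] <- NaN
  pix <- c(map$spacing, map$spacing)
  RNifti::writeNifti(RNifti::asNifti(vals, pixdim = pix),
                     file.path(dir, paste0(prefix, ".nii.gz")))
  RNifti::writeNifti(RNifti::asNifti(map$mask * 1, pixdim = pix),
                     file.path(dir, paste0(prefix, "_mask.nii.gz")))
  invisible(file.path(dir, paste0(prefix, ".nii.gz")))
}

#' Read a relaxation map written by [write_map()]
#'
#' @param dir Directory containing the files.
#' @param prefix File name prefix used when writing.
#' @param family Contrast family tag to attach.
#' @return A `cm_relaxation_map`.
#' @export
read_map <- function(dir, prefix = "map", family = "unknown") {
  v <- RNifti::readNifti(file.path(dir, paste0(prefix, ".nii.gz")))
  m <- RNifti::readNifti(file.path(dir, paste0(prefix, "_mask.nii.gz")))
  vals <- matrix(as.vector(v), dim(v)[1], dim(v)[2])
  mask <- matrix(as.vector(m) > 0, dim(m)[1], dim(m)[2])
  vals[!mask] <- NA_real_
  structure(list(values = vals, mask = mask, s0 = NULL, family = family,
                 spacing = RNifti::pixdim(v)[1], floor = NA_real_, cap = NA_real_),
            class = "cm_relaxation_map")
}

# study outputs: CSV tables (+ per-table JSON of the config)
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$study_table, file.path(dir, "study_table.csv"),
                   row.names = FALSE)
  for (nm in c("delineability", "regional", "thickness")) {
    utils::write.csv(study[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(dplyr::select(study$texture, -dplyr::any_of("tukey")),
                   file.path(dir, "texture.csv"), row.names = FALSE)
  cfg <- study$config
  jsonlite::write_json(
    list(n_specimens = cfg$n_specimens, seed = cfg$seed, alpha = cfg$alpha,
         noise_sigma = cfg$noise_sigma, specimen_rel_sd = cfg$specimen_rel_sd,
         sequences = cfg$sequences),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
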