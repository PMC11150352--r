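#' In-plane pixel spacing from field of view and matrix size
#'
#' @param fov_mm Field of view in mm.
#' @param matrix_size Reconstruction matrix size in pixels.
#' @return Pixel spacing in mm at full precision; round to two decimals for
#'   the conventional printed value (e.g. `140 / 512 = 0.2734 -> "0.27"`).
#' @export
#' @examples
#' round(pixel_spacing(140, 512), 2)
pixel_spacing <- function(fov_mm, matrix_size) {
  if (fov_mm <= 0 || matrix_size <= 0) {
    abort("`fov_mm` and `matrix_size` must be > 0.", class = "cm_input_error")
  }
  fov_mm / matrix_size
}

#' Configure an end-to-end simulated study
#'
#' Bundles everything [run_study()] needs: the cohort size, the phantom
#' template, inter-specimen variability, the defect-induced relaxation-time
#' shifts, the morphologic sequences compared, noise, and the family-wise
#' significance level. Per-specimen seeds are derived deterministically from
#' the study seed.
#'
#' Inter-specimen variability is modeled as a lognormal multiplier (mean 1,
#' relative SD `specimen_rel_sd`) applied per specimen to all cartilage
#' relaxation times, for T2 and T1rho independently. Post-defect shifts are
#' added to the regional relaxation times before the multiplier, so every
#' specimen's paired pre/post difference is positive when the shift is.
#'
#' @param n_specimens Cohort size (default 10, `>= 3`).
#' @param seed Study master seed.
#' @param phantom A [phantom_spec()] template shared by all specimens.
#' @param specimen_rel_sd Relative SD of the lognormal inter-specimen
#'   multiplier on relaxation times.
#' @param t2_post_shift,t1rho_post_shift Named additive shifts (ms) of the
#'   regional relaxation times after defect creation; defaults follow the
#'   regional post-minus-pre differences reported for surgically created
#'   defects (T2 +1/+5/+5/+4 and T1rho +3/+2/+5/+4 ms for aF/cF/pF/T).
#' @param sequences Tibble with columns `label` and `blur_sigma` describing
#'   the morphologic sequences compared; the default point-spread sigmas
#'   (0.40 / 0.55 / 0.60 mm for 2D TSE / 3D TSE / MIXTURE) encode the 2D
#'   TSE's sharper readout.
#' @param noise_sigma Rician noise sigma (default 20, about SNR 50 on
#'   cartilage at the default proton density of 1000).
#' @param alpha Family-wise significance level (default 0.01).
#' @param out_dir Optional directory for NIfTI/CSV outputs (`NULL` = none).
#' @return A `cm_study_config`.
#' @export
study_config <- function(n_specimens = 10,
                         seed = 20220101,
                         phantom = phantom_spec(),
                         specimen_rel_sd = 0.08,
                         t2_post_shift = c(aF = 1, cF = 5, pF = 5, T = 4),
                         t1rho_post_shift = c(aF = 3, cF = 2, pF = 5, T = 4),
                         sequences = tibble(
                           label = c("2D TSE", "3D TSE", "MIXTURE"),
                           blur_sigma = c(0.40, 0.55, 0.60)
                         ),
                         noise_sigma = 20,
                         alpha = 0.01,
                         out_dir = NULL) {
  if (n_specimens < 3) abort("Need at least 3 specimens.", class = "cm_input_error")
  if (specimen_rel_sd < 0 || noise_sigma < 0) {
    abort("`specimen_rel_sd` and `noise_sigma` must be >= 0.", class = "cm_input_error")
  }
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).", class = "cm_input_error")
  stopifnot(all(c("label", "blur_sigma") %in% names(sequences)))
  specimen_seeds <- vapply(seq_len(n_specimens), function(i) derive_seed(seed, 1000 + i), 1L)
  if (anyDuplicated(specimen_seeds)) abort("Derived specimen seeds collide.", class = "cm_input_error")
  structure(
    list(n_specimens = as.integer(n_specimens), seed = as.integer(seed),
         specimen_seeds = specimen_seeds, phantom = phantom,
         specimen_rel_sd = specimen_rel_sd,
         t2_post_shift = t2_post_shift, t1rho_post_shift = t1rho_post_shift,
         sequences = sequences, noise_sigma = noise_sigma, alpha = alpha,
         out_dir = out_dir),
    class = "cm_study_config"
  )
}

# lognormal multiplier with mean 1 and relative sd `rel_sd`
lognormal_multiplier <- function(rel_sd) {
  if (rel_sd == 0) return(1)
  sl <- sqrt(log(1 + rel_sd^2))
  exp(rnorm(1, -sl^2 / 2, sl))
}

specimen_specs <- function(config, i) {
  tmpl <- config$phantom
  set.seed(config$specimen_seeds[i])
  m_t2 <- lognormal_multiplier(config$specimen_rel_sd)
  m_rho <- lognormal_multiplier(config$specimen_rel_sd)
  mk <- function(t2, t1rho) {
    s <- tmpl
    s$regional_t2 <- t2
    s$regional_t1rho <- t1rho
    s$seed <- config$specimen_seeds[i]
    s
  }
  list(
    pre = mk(tmpl$regional_t2 * m_t2, tmpl$regional_t1rho * m_rho),
    post = mk((tmpl$regional_t2 + config$t2_post_shift[names(tmpl$regional_t2)]) * m_t2,
              (tmpl$regional_t1rho + config$t1rho_post_shift[names(tmpl$regional_t1rho)]) * m_rho)
  )
}

#' Run the end-to-end simulated study
#'
#' For each simulated specimen, builds paired pre-defect and post-defect
#' phantoms, simulates the magnetization-prepared stacks, fits T2 and T1rho
#' maps, extracts regional relaxation statistics (pre and post), measures
#' per-defect delineability (FWHM, edge width) and subchondral bone texture
#' on each morphologic sequence (post), and measures cartilage thickness
#' adjacent to the largest defect. The statistical battery is then applied:
#' repeated-measures ANOVA with Tukey-Kramer post hoc comparisons across
#' sequences (delineability, texture), exact Wilcoxon matched-pairs
#' signed-rank tests pre vs post per region (with Holm multiplicity
#' adjustment across regions), and a paired t-test on thickness. Fully
#' deterministic given the config seed.
#'
#' @param config A [study_config()].
#' @param verbose Print per-stage progress?
#' @return A `cm_study` list: `study_table` (long per-specimen records),
#'   `delineability`, `texture`, `regional`, `thickness` (report tibbles),
#'   and the `config`.
#' @export
run_study <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "cm_study_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  sp <- config$phantom$spacing
  records <- vector("list", config$n_specimens)

  for (i in seq_len(config$n_specimens)) {
    say("specimen %d/%d", i, config$n_specimens)
    specs <- specimen_specs(config, i)
    models <- list(pre = build_phantom(specs$pre, defects = FALSE),
                   post = build_phantom(specs$post, defects = TRUE))
    rows <- list()

    # --- quantitative maps (combined morphologic/quantitative sequence) ---
    mix_blur <- config$sequences$blur_sigma[config$sequences$label == "MIXTURE"]
    if (!length(mix_blur)) mix_blur <- max(config$sequences$blur_sigma)
    for (tp in c("pre", "post")) {
      for (fam in c("T2prep-PDFS", "SLprep-T1w")) {
        sq <- sequence_params(fam, blur_sigma = mix_blur)
        stack <- simulate_stack(models[[tp]], sq, noise_sigma = config$noise_sigma,
                                seed = derive_seed(config$specimen_seeds[i],
                                                   match(tp, c("pre", "post")) * 10 +
                                                     match(fam, c("T2prep-PDFS", "SLprep-T1w"))))
        cart <- models[[tp]]$region > 0
        rmap <- map_relaxation(stack, mask = cart)
        st <- regional_stats(rmap, region_labels(models[[tp]]))
        rows[[length(rows) + 1]] <- st |>
          dplyr::mutate(specimen = i, timepoint = tp,
                        metric = if (fam == "T2prep-PDFS") "T2" else "T1rho",
                        stage = "regional", sequence = "MIXTURE",
                        value = .data$mean) |>
          dplyr::select("specimen", "stage", "sequence", "timepoint",
                        "metric", "region", "value", "sd", "n_voxels")
      }
    }

    # --- morphologic analyses on the post-defect phantom ---
    for (s in seq_len(nrow(config$sequences))) {
      lab <- config$sequences$label[s]
      blur <- config$sequences$blur_sigma[s]

      pd_stack <- simulate_stack(models$post,
                                 sequence_params("T2prep-PDFS", blur_sigma = blur,
                                                 label = lab),
                                 noise_sigma = config$noise_sigma,
                                 seed = derive_seed(config$specimen_seeds[i], 100 + s))
      pdfs <- pd_stack$images[[1]]
      for (dmm in models$post$defect_centers$diameter) {
        ends <- defect_line_endpoints(models$post, dmm)
        del <- delineate_defect(pdfs, ends$p0, ends$p1, sp, relative = TRUE)
        rows[[length(rows) + 1]] <- tibble(
          specimen = i, stage = "delineability", sequence = lab,
          timepoint = "post", metric = c("FWHM", "EW"),
          region = sprintf("%g mm", dmm), value = c(del$fwhm, del$ew),
          sd = NA_real_, n_voxels = NA_integer_)
      }

      t1_stack <- simulate_stack(models$post,
                                 sequence_params("SLprep-T1w", blur_sigma = blur,
                                                 label = lab),
                                 noise_sigma = config$noise_sigma,
                                 seed = derive_seed(config$specimen_seeds[i], 200 + s))
      t1w <- normalize_stack(t1_stack)$images[[1]]
      roi <- texture_roi(models$post, diameter = 5)
      feats <- texture_features(t1w, roi$mask)
      rows[[length(rows) + 1]] <- tibble(
        specimen = i, stage = "texture", sequence = lab, timepoint = "post",
        metric = c("variance", "energy", "entropy", "inverse_difference",
                   "bin_occupancy"),
        region = "subchondral", value = as.numeric(feats[1, 1:5]),
        sd = NA_real_, n_voxels = NA_integer_)
    }

    # --- caliper thickness adjacent to the largest defect ---
    dmax <- max(models$post$defect_centers$diameter)
    for (tp in c("pre", "post")) {
      rows[[length(rows) + 1]] <- tibble(
        specimen = i, stage = "thickness", sequence = "MIXTURE", timepoint = tp,
        metric = "thickness", region = sprintf("%g mm", dmax),
        value = thickness_adjacent_to_defect(models[[tp]], dmax),
        sd = NA_real_, n_voxels = NA_integer_)
    }
    records[[i]] <- dplyr::bind_rows(rows)
  }

  study_table <- dplyr::bind_rows(records)
  out <- structure(
    list(study_table = study_table,
         delineability = report_delineability(study_table, config$alpha),
         texture = report_texture(study_table, config$alpha),
         regional = report_regional(study_table, config$alpha),
         thickness = report_thickness(study_table, config$alpha),
         config = config),
    class = "cm_study"
  )
  if (!is.null(config$out_dir)) write_study(out, config$out_dir)
  out
}

report_delineability <- function(study_table, alpha) {
  d <- dplyr::filter(study_table, .data$stage == "delineability")
  if (!nrow(d)) return(tibble())
  d |>
    dplyr::group_by(.data$metric, diameter = .data$region) |>
    dplyr::group_modify(function(g, key) {
      an <- rm_anova(g, specimen, sequence, value)
      g |>
        dplyr::group_by(.data$sequence) |>
        dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                         .groups = "drop") |>
        dplyr::mutate(p_anova = an$p_value)
    }) |>
    dplyr::ungroup()
}

report_texture <- function(study_table, alpha) {
  d <- dplyr::filter(study_table, .data$stage == "texture",
                     .data$metric != "bin_occupancy")
  if (!nrow(d)) return(tibble())
  d |>
    dplyr::group_by(.data$metric) |>
    dplyr::group_modify(function(g, key) {
      an <- rm_anova(g, specimen, sequence, value)
      tk <- tidy(tukey_kramer(g, specimen, sequence, value))
      summ <- g |>
        dplyr::group_by(.data$sequence) |>
        dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                         .groups = "drop")
      summ$p_anova <- an$p_value
      summ$tukey <- list(tk)
      summ
    }) |>
    dplyr::ungroup()
}

report_regional <- function(study_table, alpha) {
  d <- dplyr::filter(study_table, .data$stage == "regional")
  if (!nrow(d)) return(tibble())
  out <- d |>
    dplyr::group_by(.data$metric, .data$region) |>
    dplyr::group_modify(function(g, key) {
      w <- tidyr::pivot_wider(g[, c("specimen", "timepoint", "value")],
                              names_from = "timepoint", values_from = "value")
      ws <- wilcoxon_signed_rank(w$post, w$pre)
      tibble(pre_mean = mean(w$pre), pre_sd = sd(w$pre),
             post_mean = mean(w$post), post_sd = sd(w$post),
             n = nrow(w), p = ws$p_value)
    }) |>
    dplyr::ungroup()
  out |>
    dplyr::group_by(.data$metric) |>
    dplyr::mutate(p_adj = p.adjust(.data$p, method = "holm"),
                  significant = .data$p_adj <= alpha) |>
    dplyr::ungroup()
}

report_thickness <- function(study_table, alpha) {
  d <- dplyr::filter(study_table, .data$stage == "thickness")
  if (!nrow(d)) return(tibble())
  w <- tidyr::pivot_wider(d[, c("specimen", "timepoint", "value")],
                          names_from = "timepoint", values_from = "value")
  tt <- paired_t(w$post, w$pre)
  tibble(pre_mean = mean(w$pre), pre_sd = sd(w$pre),
         post_mean = mean(w$post), post_sd = sd(w$post),
         t = tt$statistic, df = tt$df[1], p = tt$p_value,
         significant = tt$p_value <= alpha)
}

#' @export
print.cm_study <- function(x, ...) {
  cat(sprintf("<cm_study> %d specimens, seed %d\n",
              x$config$n_specimens, x$config$seed))
  cat(sprintf("  study table: %d records\n", nrow(x$study_table)))
  cat("  reports: delineability, texture, regional, thickness\n")
  invisible(x)
}

#' @rdname run_study
#' @param x A `cm_study`.
#' @param ... Unused.
#' @export
glance.cm_study <- function(x, ...) {
  tibble(n_specimens = x$config$n_specimens, seed = x$config$seed,
         n_records = nrow(x$study_table),
         alpha = x$config$alpha)
}
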