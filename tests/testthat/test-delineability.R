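test_that("profile extraction is exact on constant and linear images", {
  img <- matrix(7, 32, 32)
  prof <- extract_profile(img, c(1, 4), c(6, 4), spacing = 0.5)
  expect_true(all(prof$intensity == 7))
  # bilinear sampling reproduces a linear ramp to 1e-9
  ramp <- matrix(rep(seq_len(40), each = 40), 40, 40)   # intensity = column
  prof <- extract_profile(ramp, c(0.5, 5), c(8.7, 5), spacing = 1, step = 0.13)
  expect_equal(prof$intensity, prof$position + 1.5, tolerance = 1e-9)
  # sample count is floor(L / step) + 1
  prof <- extract_profile(matrix(1, 80, 80), c(1, 1), c(11, 1),
                          spacing = 0.27, step = 0.25)
  expect_identical(nrow(prof), 41L)
  expect_error(extract_profile(img, c(-5, 4), c(6, 4), spacing = 0.5),
               class = "cm_geometry_error")
})

test_that("normalization scales to unit maximum and is idempotent", {
  p <- line_profile(seq(0, 0.9, by = 0.1), c(2, 4, 8, 6, 4, 2, 2, 2, 2, 2))
  n1 <- normalize_profile(p)
  expect_equal(max(n1$intensity), 1)
  expect_equal(n1$intensity[1:3], c(0.25, 0.5, 1))
  expect_identical(normalize_profile(n1)$intensity, n1$intensity)
  zero <- line_profile(seq(0, 0.9, by = 0.1), rep(0, 10))
  expect_error(normalize_profile(zero), class = "cm_normalization_error")
})

test_that("background is the mean of the two flank means", {
  x <- seq(0, 1.9, by = 0.1)
  flat <- line_profile(x, c(rep(0.3, 5), rep(1, 10), rep(0.3, 5)))
  expect_equal(estimate_background(flat, 0.2), 0.3)
  asym <- line_profile(x, c(rep(0.2, 5), rep(1, 10), rep(0.4, 5)))
  expect_equal(estimate_background(asym, 0.25), 0.3)
  expect_error(estimate_background(flat, 0.5), class = "cm_parameter_error")
  expect_error(estimate_background(flat, 0), class = "cm_parameter_error")
})

test_that("FWHM of rectangular and blurred defects matches the geometry", {
  # ideal rectangle: background 0.2, plateau 1.0, width 5 mm
  step <- 0.05
  x <- seq(0, 12, by = step)
  y <- ifelse(abs(x - 6) <= 2.5, 1, 0.2)
  fw <- compute_fwhm(line_profile(x, y), background = 0.2)
  expect_lte(abs(fw$fwhm - 5), step + 1e-9)
  # brute-force convolution oracle: 5 mm rectangle, Gaussian sigma 0.5 mm
  prof <- oracle_blurred_rect_profile(5, 0.5)
  fw <- compute_fwhm(prof, background = 0)
  expect_lte(abs(fw$fwhm - 5), 0.05)
  # a monotone ramp has no enclosed defect
  ramp <- line_profile(seq(0, 1.9, 0.1), seq(0.05, 1, length.out = 20))
  expect_error(compute_fwhm(ramp, background = 0.05), class = "cm_no_defect")
})

test_that("FWHM is invariant under intensity scaling of the raw profile", {
  prof <- oracle_blurred_rect_profile(5, 0.4, background = 0.3)
  raw <- prof
  raw$intensity <- raw$intensity * 1234
  f1 <- compute_fwhm(normalize_profile(prof), 0.3)
  f2 <- compute_fwhm(normalize_profile(raw), 0.3)
  expect_equal(f1$fwhm, f2$fwhm, tolerance = 1e-12)
})

test_that("edge width recovers the 10-90 % width of known edges", {
  # instantaneous edges: EW bounded by one sampling step
  step <- 0.05
  x <- seq(0, 12, by = step)
  y <- ifelse(abs(x - 6) <= 2.5, 1, 0)
  ew <- compute_edge_width(line_profile(x, y), background = 0)
  expect_lte(ew$ew, step)
  # erf-shaped edges, sigma 0.5 mm: each shoulder 2.563 * sigma / 2 per side,
  # i.e. 1.281 mm for the full 10-90 % transition
  prof <- oracle_blurred_rect_profile(5, 0.5)
  ew <- compute_edge_width(prof, background = 0)
  expect_equal(unname(ew$shoulders["left"]), 1.2816 * 0.5 * 2, tolerance = 0.05)
  expect_equal(unname(ew$shoulders["right"]), 1.2816 * 0.5 * 2, tolerance = 0.05)
  expect_equal(ew$ew, mean(ew$shoulders))
  # symmetric profile: both shoulders agree
  expect_equal(unname(ew$shoulders["left"]), unname(ew$shoulders["right"]),
               tolerance = 1e-6)
})

test_that("the absolute 10 % level is refused when background sits above it", {
  prof <- oracle_blurred_rect_profile(5, 0.4, background = 0.3)
  prof <- normalize_profile(prof)
  expect_error(compute_edge_width(prof, background = 0.3, relative = FALSE),
               class = "cm_threshold_unreachable")
  ew <- compute_edge_width(prof, background = 0.3, relative = TRUE)
  expect_gt(ew$ew, 0)
})

test_that("phantom defect FWHM recovers nominal diameters under moderate blur", {
  m <- build_phantom(phantom_spec())
  st <- simulate_stack(m, sequence_params("T2prep-PDFS", blur_sigma = 0.5))
  img <- st$images[[1]]
  for (d in c(3, 5, 8)) {
    e <- defect_line_endpoints(m, d)
    del <- delineate_defect(img, e$p0, e$p1, m$spacing, relative = TRUE)
    expect_lte(abs(del$fwhm - d), 0.5)
  }
})

test_that("edge width grows strictly with the point-spread blur", {
  m <- build_phantom(phantom_spec())
  e <- defect_line_endpoints(m, 5)
  ews <- vapply(seq(0.1, 1.0, by = 0.1), function(sig) {
    st <- simulate_stack(m, sequence_params("T2prep-PDFS", blur_sigma = sig))
    delineate_defect(st$images[[1]], e$p0, e$p1, m$spacing, relative = TRUE)$ew
  }, 0)
  expect_true(all(diff(ews) > 0))
})
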