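test_that("stack normalization spans [0, 1] and ignores affine intensity maps", {
  expect_equal(normalize_stack(matrix(c(10, 20, 30, 30), 2)),
               matrix(c(0, 0.5, 1, 1), 2))
  set.seed(3)
  imgs <- list(matrix(runif(36), 6), matrix(runif(36), 6))
  n1 <- normalize_stack(imgs)
  expect_equal(min(unlist(n1)), 0)
  expect_equal(max(unlist(n1)), 1)
  n2 <- normalize_stack(lapply(imgs, function(im) 3.7 * im + 11))
  expect_equal(n1, n2, tolerance = 1e-12)
  expect_error(normalize_stack(matrix(5, 4, 4)), class = "cm_normalization_error")
})

test_that("quantization clamps edges and matches the floor-rule enumeration", {
  expect_identical(quantize(1.0, 200)$levels, 199L)
  expect_identical(quantize(0.0, 200)$levels, 0L)
  v <- seq(0, 1, length.out = 200)
  q <- quantize(v, 200)
  # oracle: direct enumeration of the floor rule
  oracle_levels <- pmin(floor(v * 200), 199)
  expect_identical(q$levels, as.integer(oracle_levels))
  expect_identical(q$occupancy, length(unique(oracle_levels)))
  expect_identical(q$occupancy, 200L)
  expect_error(quantize(c(0.5, 1.2)), class = "cm_range_error")
})

test_that("first-order variance matches closed forms and the uniform moment", {
  expect_equal(first_order_variance(rep(4, 10)), 0)
  expect_equal(first_order_variance(c(0, 1)), 0.25)
  set.seed(21)
  expect_equal(first_order_variance(runif(1e4)), 1 / 12, tolerance = 0.005)
})

test_that("GLCM matches hand-computable configurations", {
  # constant ROI: a single diagonal entry
  g <- compute_glcm(matrix(3L, 5, 5), n_levels = 5)
  for (M in g$matrices) {
    expect_equal(M[4, 4], 1)
    expect_equal(sum(M), 1)
  }
  # 2-level checkerboard, offset (0,1): all mass off-diagonal, split evenly
  cb <- outer(1:6, 1:6, function(r, c) (r + c) %% 2L)
  g <- compute_glcm(cb, offsets = list(c(0L, 1L)), n_levels = 2)
  expect_equal(g$matrices[[1]], matrix(c(0, 0.5, 0.5, 0), 2))
})

test_that("GLCM equals the brute-force double loop on random patches", {
  set.seed(14)
  for (rep in 1:5) {
    patch <- matrix(sample(0:7, 64, replace = TRUE), 8, 8)
    roi <- matrix(sample(c(TRUE, TRUE, TRUE, FALSE), 64, replace = TRUE), 8, 8)
    g <- compute_glcm(patch, roi, n_levels = 8)
    for (k in seq_along(g$offsets)) {
      expect_equal(g$matrices[[k]],
                   oracle_glcm(patch, roi, g$offsets[[k]], 8),
                   tolerance = 1e-14)
    }
  }
})

test_that("GLCM features match closed-form evaluations", {
  flat <- compute_glcm(matrix(2L, 6, 6), n_levels = 4)
  f <- glcm_features(flat)
  expect_equal(f$energy, 1)
  expect_equal(f$entropy, 0)
  expect_equal(f$inverse_difference, 1)
  # checkerboard: p = (0.5, 0.5) off-diagonal
  cb <- outer(1:6, 1:6, function(r, c) (r + c) %% 2L)
  f <- glcm_features(compute_glcm(cb, offsets = list(c(0L, 1L)), n_levels = 2))
  expect_equal(f$energy, 0.5)
  expect_equal(f$entropy, 1)
  expect_equal(f$inverse_difference, 0.5)
  # uniform GLCM over N^2 cells
  N <- 5
  g <- structure(list(matrices = list(matrix(1 / N^2, N, N)),
                      offsets = list(c(0L, 1L)), symmetric = TRUE,
                      n_levels = N, normalized = TRUE), class = "cm_glcm")
  f <- glcm_features(g)
  expect_equal(f$energy, 1 / N^2)
  expect_equal(f$entropy, 2 * log2(N))
})

test_that("degenerate ROIs and unnormalized matrices are refused", {
  expect_error(compute_glcm(matrix(1L, 4, 4), roi_mask = matrix(FALSE, 4, 4)),
               class = "cm_empty_roi")
  g <- compute_glcm(matrix(1L, 4, 4))
  g$normalized <- FALSE
  expect_error(glcm_features(g), class = "cm_state_error")
})

test_that("texture features are invariant under positive affine intensity maps", {
  set.seed(9)
  img <- matrix(runif(400, 50, 150), 20, 20)
  roi <- circular_mask(c(20, 20), c(10, 10), 14)
  f1 <- texture_features(normalize_stack(img), roi)
  f2 <- texture_features(normalize_stack(2.5 * img + 40), roi)
  expect_equal(f1, f2, tolerance = 1e-9)
})

test_that("blurring drives energy and homogeneity up and entropy down", {
  m <- build_phantom(phantom_spec())
  roi <- texture_roi(m, 5)
  feats <- purrr::map_dfr(c(0.2, 0.4, 0.6, 0.8), function(sig) {
    st <- simulate_stack(m, sequence_params("SLprep-T1w", blur_sigma = sig))
    texture_features(normalize_stack(st)$images[[1]], roi$mask)
  })
  expect_true(all(diff(feats$energy) > 0))
  expect_true(all(diff(feats$inverse_difference) > 0))
  expect_true(all(diff(feats$entropy) < 0))
})
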