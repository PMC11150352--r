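test_that("defect gaps across the band mid-surface match the nominal diameters", {
  spec <- phantom_spec()
  post <- build_phantom(spec, defects = TRUE)
  pre <- build_phantom(spec, defects = FALSE)
  for (d in c(3, 5, 8)) {
    expect_lte(abs(measure_defect_gap(post, d) - d), spec$spacing)
    expect_identical(measure_defect_gap(pre, d), 0)
  }
  # without defects there is no fluid inside the femoral band
  band <- pre$region %in% 1:3
  expect_false(any(pre$labels[band] == tissue_code("fluid")))
  expect_gt(sum(pre$labels == tissue_code("cartilage")),
            sum(post$labels == tissue_code("cartilage")))
})

test_that("phantom construction is deterministic and pre/post share anatomy", {
  spec <- phantom_spec()
  m1 <- build_phantom(spec)
  m2 <- build_phantom(spec)
  expect_identical(m1$labels, m2$labels)
  expect_identical(m1$pd, m2$pd)
  # pre-defect model has identical anatomy outside the defect gaps
  pre <- build_phantom(spec, defects = FALSE)
  gap <- m1$labels == tissue_code("fluid") & pre$labels == tissue_code("cartilage")
  expect_identical(m1$labels[!gap], pre$labels[!gap])
})

test_that("defects that cannot be placed raise a placement error naming the diameter", {
  expect_error(
    build_phantom(phantom_spec(grid_shape = c(144, 144), condyle_radius = 10,
                               defect_diameters = c(3, 5, 8))),
    "8.0 mm", class = "cm_placement_error"
  )
})

test_that("prep-weighted signal follows PD * exp(-tau / Tc) with fat suppression", {
  spec <- phantom_spec(regional_t2 = c(aF = 50, cF = 50, pF = 50, T = 50),
                       marrow_texture_sd = 0)
  m <- build_phantom(spec)
  st <- simulate_stack(m, sequence_params("T2prep-PDFS"))  # no blur, no noise
  cart <- m$labels == tissue_code("cartilage")
  # tau = 0, fat-suppressed echo: non-fat voxels equal PD, fat voxels 0.05 * PD
  expect_equal(st$images[[1]][cart], m$pd[cart])
  expect_equal(st$images[[1]][m$fat], 0.05 * m$pd[m$fat])
  # tau = 50, T2 = 50: cartilage signal is exactly 1000 / e = 367.879
  expect_equal(unique(st$images[[2]][cart]), 1000 * exp(-1), tolerance = 1e-12)
  # monotone decay with tau on every positive-PD voxel
  sl <- simulate_stack(m, sequence_params("SLprep-T1w", fat_suppressed = rep(FALSE, 3)))
  pos <- m$pd > 0
  expect_true(all(sl$images[[2]][pos] < sl$images[[1]][pos]))
  expect_true(all(sl$images[[3]][pos] < sl$images[[2]][pos]))
})

test_that("Rician noise has the documented floor, determinism and identity cases", {
  img <- matrix(0, 1000, 1000)
  expect_identical(add_rician_noise(img, 0), img)
  n1 <- add_rician_noise(img, 1, seed = 42)
  n2 <- add_rician_noise(img, 1, seed = 42)
  expect_identical(n1, n2)
  # Rayleigh mean sqrt(pi/2) = 1.2533 at zero signal, sigma 1 (1e6 draws)
  expect_equal(mean(n1), sqrt(pi / 2), tolerance = 0.01 / sqrt(pi / 2))
  expect_error(add_rician_noise(img, -1), class = "cm_parameter_error")
})

test_that("Gaussian blur conserves intensity and degenerates to identity", {
  set.seed(7)
  img <- matrix(runif(64 * 64, 0, 100), 64, 64)
  expect_identical(blur_gaussian(img, 0, 0.27), img)
  for (sig in c(0.3, 0.8)) {
    b <- blur_gaussian(img, sig, 0.27)
    expect_equal(sum(b), sum(img), tolerance = 1e-3)
    expect_identical(dim(b), dim(img))
  }
  # blurring a constant image is exact (kernel normalized, reflective edges)
  flat <- matrix(5, 32, 48)
  expect_equal(blur_gaussian(flat, 0.6, 0.27), flat, tolerance = 1e-12)
})

test_that("spec validation rejects nonphysical parameters", {
  expect_error(phantom_spec(spacing = 0), class = "cm_parameter_error")
  expect_error(phantom_spec(defect_diameters = c(3, -5)), class = "cm_parameter_error")
  expect_error(phantom_spec(noise_sigma = -1), class = "cm_parameter_error")
  expect_error(sequence_params(taus = c(10, 50)), class = "cm_parameter_error")
  expect_error(sequence_params(taus = c(0, 50, 25)), class = "cm_parameter_error")
  tp <- default_tissue_params()
  tp$t2[2] <- -1
  expect_error(phantom_spec(tissue_params = tp), class = "cm_parameter_error")
})
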