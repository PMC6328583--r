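test_that("striation phantoms carry the constructed period", {
  st <- gen_striated_stack(2.0, noise_sd = 0, seed = 1)
  img <- st$channels$actinin
  # autocorrelation of the mean axial profile peaks at 2.0 um = 20 px
  prof <- rowMeans(img)
  ac <- acf(prof - mean(prof), lag.max = 30, plot = FALSE)$acf[-1]
  # first non-trivial autocorrelation peak sits at one period (20 px)
  expect_equal(which.max(ac[10:30]) + 9, 20)
  # seed-reproducible
  a <- gen_striated_stack(1.8, noise_sd = 0.1, seed = 5)
  b <- gen_striated_stack(1.8, noise_sd = 0.1, seed = 5)
  expect_identical(a$channels$actinin, b$channels$actinin)
})

test_that("sarcomere length is recovered across the physiological band", {
  # error below one refined frequency bin at up to 20% intensity noise
  for (p in c(1.0, 1.4, 1.8, 2.2, 3.0)) {
    st <- gen_striated_stack(p, noise_sd = 0.2, seed = 11)
    est <- sarcomere_length(st)
    refined_bin_um <- p^2 / (1024 * 0.1) # df = 1/(nfft*h), dp = p^2 df
    expect_equal(est, p, tolerance = max(refined_bin_um, 0.01) / p)
  }
})

test_that("period estimation is rotation invariant", {
  e0 <- sarcomere_length(gen_striated_stack(2.0, orientation = 0,
                                            noise_sd = 0.05, seed = 2))
  e37 <- sarcomere_length(gen_striated_stack(2.0, orientation = 37,
                                             noise_sd = 0.05, seed = 2))
  expect_equal(e0, e37, tolerance = 0.01)
})

test_that("non-sarcomeric content raises a no-structure error", {
  # periodicity outside the 1/3..1 per-um band
  expect_error(
    sarcomere_length(gen_striated_stack(4.0, noise_sd = 0.1, seed = 5)),
    class = "myoslice_convergence_error")
  # pure noise
  noise <- image_stack(list(actinin = matrix(rnorm(256 * 256, 0.5, 0.1),
                                             256)), c(0.1, 0.1))
  expect_error(sarcomere_length(noise),
               class = "myoslice_convergence_error")
})

test_that("estimators are invariant to global intensity scaling", {
  st <- gen_striated_stack(1.8, noise_sd = 0.1, seed = 7)
  scaled <- image_stack(list(actinin = 3.7 * st$channels$actinin),
                        st$voxel_size)
  expect_equal(sarcomere_length(scaled), sarcomere_length(st),
               tolerance = 1e-9)

  lab <- gen_labelled_stack(0.3, seed = 8)
  lab_scaled <- image_stack(list(membrane = 2.5 * lab$channels$membrane),
                            lab$voxel_size)
  expect_equal(ecm_fraction(lab_scaled), ecm_fraction(lab), tolerance = 1e-9)
})

test_that("ECM volume fraction matches the constructed label fraction", {
  expect_equal(ecm_fraction(gen_labelled_stack(0.2, seed = 1)), 0.2,
               tolerance = 0.01)
  empty <- image_stack(list(membrane = array(0, c(32, 32, 4))))
  expect_equal(ecm_fraction(empty), 0)
  full <- image_stack(list(membrane = array(1, c(32, 32, 4))))
  expect_equal(ecm_fraction(full), 1)
})

test_that("membrane distance matches the d/4 slab closed form", {
  for (d in c(1, 2, 4)) {
    m <- gen_slab_stack(d)
    est <- mean_membrane_distance(m)
    expect_lt(abs(est - d / 4) / (d / 4), 0.02)
  }
  # halving the spacing halves the mean
  expect_equal(mean_membrane_distance(gen_slab_stack(1)),
               mean_membrane_distance(gen_slab_stack(2)) / 2,
               tolerance = 0.01)
  # all-membrane mask
  expect_equal(mean_membrane_distance(array(TRUE, c(10, 10, 4))), 0)
})

test_that("anisotropic voxels are honoured by the distance transform", {
  # planes along z: 0.2 um voxels need half the voxel count for the same gap
  m <- gen_slab_stack(2, n_gaps = 3, cross_dim = c(15, 15),
                      voxel_size = c(0.1, 0.1, 0.2), axis = 3)
  expect_lt(abs(mean_membrane_distance(m) - 0.5) / 0.5, 0.02)
})

test_that("cross-section areas are recovered from the cell-grid phantom", {
  m <- gen_cell_grid_stack(pitch = 20)
  res <- cross_section_area(m)
  expect_equal(res$mean_area, 400, tolerance = 0.05)
  expect_equal(nrow(res$components), 9)
  expect_false(any(res$components$oversized))

  # breaking a wall merges two cells into an oversized component
  broken <- m
  broken[201, 220:380] <- FALSE
  res2 <- cross_section_area(broken, oversize_area = 600)
  expect_true(any(res2$components$oversized))

  # a mask with no enclosed interior regions yields an empty result
  solid <- array(TRUE, c(50, 50))
  solid[25, 25] <- FALSE # single-pixel hole, below min size
  res3 <- cross_section_area(solid)
  expect_true(is.na(res3$mean_area))
  expect_equal(nrow(res3$components), 0)
})

test_that("stacks survive a TIFF round trip", {
  st <- gen_striated_stack(1.8, noise_sd = 0, seed = 1, dim = c(64, 64, 4))
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(st, path)
  back <- read_stack(path, channel = "actinin")
  expect_equal(dim(back$channels$actinin), c(64, 64, 4))
  expect_equal(back$channels$actinin,
               pmin(pmax(st$channels$actinin, 0), 1), tolerance = 1e-6)
})
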