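test_that("phantom generation is deterministic and validates its spec", {
  sp <- small_spec(void_fraction = 0.05, noise_sd = 30, seed = 11L)
  a <- generate_tooth_phantom(sp)
  b <- generate_tooth_phantom(sp)
  expect_identical(a$volume, b$volume)
  expect_identical(a$truth$label, b$truth$label)

  expect_error(phantom_spec(void_fraction = 1), "void_fraction")
  expect_error(phantom_spec(voxel_size_um = 0), "voxel_size_um")
  expect_error(phantom_spec(enamel_thickness_mm = 0.5, dentin_wall_mm = 0.4,
                            crown_radius_mm = 0.8), "crown_radius")
})

test_that("phantom geometry matches its construction parameters", {
  ph <- small_phantom()
  tr <- ph$truth
  lab <- tr$label

  # no voids requested -> none realized
  expect_identical(tr$void_n, 0L)
  expect_identical(tr$void_voxels, 0L)

  # enamel layer thickness checked along a radial ray at mid-crown
  zmid <- tr$cej_slice - 10L
  c0 <- (dim(lab)[1] + 1) / 2
  ray <- lab[c0:dim(lab)[1], c0, zmid]
  n_enamel_ray <- sum(ray == 3L)
  expect_lte(abs(n_enamel_ray - 12L), 1L)  # 0.12 mm at 10 um

  # tissue labels partition the volume and masks are pairwise disjoint
  tissues <- c("background", "pulp", "dentin", "enamel", "cementum", "void")
  counts <- vapply(tissues, function(t) sum(truth_mask(tr, t)), numeric(1))
  expect_equal(sum(counts), length(lab))
  expect_true(all(truth_mask(tr, "dentin") + truth_mask(tr, "enamel") +
                  truth_mask(tr, "pulp") <= 1))
})

test_that("realized void fraction tracks the request and voids are spheres in crown dentin", {
  fr <- c(0.05, 0.1, 0.2)
  vox <- vapply(fr, function(f) {
    ph <- generate_tooth_phantom(small_spec(void_fraction = f, seed = 5L))
    expect_lt(abs(ph$truth$void_fraction_realized - f) / f, 0.10)
    ph$truth$void_voxels
  }, numeric(1))
  expect_true(all(diff(vox) > 0))  # monotone in the request at fixed seed
})

test_that("calibration phantom renders rods through the grey map", {
  dens <- c(100, 400, 800, 1200, 1600)
  # identity map, no noise: rod means equal densities exactly
  p <- generate_calibration_phantom(dens)
  expect_equal(rod_mean_greys(p$volume, p$rod_masks), dens)

  # affine map grey = 2 d + 10
  p2 <- generate_calibration_phantom(dens, grey_slope = 2, grey_intercept = 10)
  expect_equal(rod_mean_greys(p2$volume, p2$rod_masks), 2 * dens + 10)

  # CLT bound: mean of N noisy voxels within 4 sd / sqrt(N)
  p3 <- generate_calibration_phantom(dens, noise_sd = 20, rod_radius = 12L,
                                     rod_length = 30L, seed = 2L)
  n <- sum(p3$rod_masks[[1]])
  expect_gt(n, 1e4)
  means <- rod_mean_greys(p3$volume, p3$rod_masks)
  expect_true(all(abs(means - dens) < 4 * 20 / sqrt(n)))

  expect_error(generate_calibration_phantom(c(500, 500)), "degenerate")
  expect_error(generate_calibration_phantom(700), "at least 2")
})

test_that("histology sections honour requested fractions and band widths", {
  s <- generate_histology_section(1)
  expect_equal(s$truth$realized_fraction_mineralized, 1)

  cb <- generate_histology_section(0.5, mode = "checkerboard")
  expect_equal(cb$truth$realized_fraction_mineralized, 0.5)

  s40 <- generate_histology_section(0.9, predentin_width_um = 40, um_per_px = 1)
  expect_equal(s40$truth$predentin_width_px, 40)
  expect_equal(sum(s40$truth$predentin_mask[, 1]), 40)  # band 40 px wide

  expect_error(generate_histology_section(0.5, predentin_width_um = 1,
                                          um_per_px = 10), "narrower")
  expect_error(generate_histology_section(1.2), "area fraction")
})
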