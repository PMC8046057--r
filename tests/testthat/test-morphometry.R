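test_that("mean density is the arithmetic mean over the mask", {
  v <- array(1200, dim = c(4, 4, 4))
  m <- array(TRUE, dim(v))
  expect_equal(mean_density(calibrated_volume(v, 10), m), 1200)

  v2 <- array(c(1000, 1400), dim = c(2, 1, 1))
  expect_equal(mean_density(calibrated_volume(v2, 10), array(TRUE, dim(v2))),
               1200)
  expect_error(mean_density(calibrated_volume(v, 10), array(FALSE, dim(v))),
               "empty")

  # unbiasedness: noisy phantom dentin, N ~ 1e5+, error << 1 mg/cm^3
  ph <- small_phantom_noisy()
  cv <- as_cv(ph)
  dn <- truth_mask(ph$truth, "dentin")
  expect_gt(sum(dn), 1e5)
  expect_lt(abs(mean_density(cv, dn) - 1200), 1)
})

test_that("local thickness recovers analytic solids within one voxel", {
  for (d in c(9, 15, 21)) {
    lt <- local_thickness(digital_ball(d), 1000)  # 1 mm voxels: mm == voxels
    expect_lt(abs(lt$mean_mm - d), 1)
  }
  tube <- tube_mask(6, 18, height = 24)           # wall 12 voxels
  lt <- local_thickness(tube, 1000)
  expect_lt(abs(lt$mean_mm - 12), 1)
})

test_that("local thickness equals the exhaustive sphere-fitting reference", {
  set.seed(13)
  masks <- list(
    digital_ball(11),
    tube_mask(5, 12, height = 18),
    array(runif(24^3) < 0.4, dim = c(24, 24, 24))
  )
  for (k in 1:2) {  # random blob unions
    d <- c(30L, 28L, 26L)
    fg <- array(FALSE, d)
    co <- arrayInd(seq_len(prod(d)), d)
    for (b in 1:5) {
      c0 <- c(sample(4:27, 1), sample(4:25, 1), sample(4:23, 1))
      r0 <- sample(2:6, 1)
      fg[(co[, 1] - c0[1])^2 + (co[, 2] - c0[2])^2 + (co[, 3] - c0[3])^2 <= r0^2] <- TRUE
    }
    masks[[length(masks) + 1]] <- fg
  }
  for (m in masks) {
    fast <- local_thickness(m, 10)
    ref <- local_thickness(m, 10, reference = TRUE)
    expect_identical(dim(fast$map_mm), dim(m))
    expect_equal(fast$map_mm, ref$map_mm, tolerance = 1e-12)
  }
})

test_that("interglobular volume converts counts to mm^3 and fractions", {
  d <- c(20, 20, 20)
  igd <- array(FALSE, d); igd[1:10, 1:10, 1:10] <- TRUE  # 1000 voxels
  terr <- array(TRUE, d)
  out <- interglobular_volume(igd, terr, 10)
  expect_equal(out$volume_mm3, 0.001)
  expect_equal(out$fraction, 1000 / 8000)
  expect_error(interglobular_volume(igd, array(FALSE, d), 10), "empty")

  ph <- small_phantom()  # zero voids
  cv <- as_cv(ph)
  igd0 <- segment_interglobular(cv, c(ph$truth$crown_slices[1],
                                      ph$truth$cej_slice))
  expect_equal(interglobular_volume(igd0$mask, igd0$territory, 10)$volume_mm3, 0)
})

test_that("crown length is the axial CEJ-to-cusp distance", {
  ph <- small_phantom()
  cv <- as_cv(ph)
  en <- segment_enamel(cv)
  cej <- detect_cej(en)
  cl <- crown_length(en, cej, 10)
  expect_lt(abs(cl - 0.5), 0.02)  # constructed 0.5 mm crown

  # enamel only at the CEJ slice -> length 0
  m <- array(FALSE, c(9, 9, 9)); m[4, 4, 5] <- TRUE
  expect_equal(crown_length(m, 5L, 10), 0)
  expect_error(crown_length(m, 3L, 10), "coronal")

  # halving the resolution leaves the mm value invariant
  m1 <- array(FALSE, c(5, 5, 40)); m1[3, 3, 10:30] <- TRUE
  m2 <- array(FALSE, c(5, 5, 20)); m2[3, 3, 5:15] <- TRUE
  expect_equal(crown_length(m1, 30L, 10), crown_length(m2, 15L, 20))
})

test_that("voids depress mean dentin density and zonal densities localize", {
  # adding voids strictly decreases crown dentin mean density and strictly
  # increases interglobular volume (fixed seed family)
  res <- lapply(c(0, 0.1), function(f) {
    p <- generate_tooth_phantom(small_spec(void_fraction = f, seed = 31L))
    cv <- as_cv(p)
    zr <- c(p$truth$crown_slices[1], p$truth$cej_slice)
    igd <- segment_interglobular(cv, zr)
    terr <- igd$territory
    list(dens = mean(cv$data[terr]),  # territory mean includes voids
         vol = interglobular_volume(igd$mask, terr, 10)$volume_mm3)
  })
  expect_lt(res[[2]]$dens, res[[1]]$dens)
  expect_gt(res[[2]]$vol, res[[1]]$vol)
})
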