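test_that("density windows use the documented boundary semantics", {
  v <- array(c(1601, 1600, 1200, 650, 649.9, 449, 200), dim = c(7, 1, 1))
  cv <- calibrated_volume(v, 10)
  en <- segment_enamel(cv)$mask
  dn <- segment_dentin(cv)$mask
  expect_identical(as.vector(en), c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_identical(as.vector(dn), c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_false(any(en & dn))  # windows are disjoint by construction
})

test_that("noiseless phantom segmentation equals ground truth exactly", {
  ph <- small_phantom()
  cv <- as_cv(ph)
  expect_identical(segment_enamel(cv)$mask, truth_mask(ph$truth, "enamel"))
  # cementum (900) falls inside the dentin window; the window mask equals
  # dentin + cementum truth
  expect_identical(segment_dentin(cv)$mask,
                   truth_mask(ph$truth, "dentin") |
                     truth_mask(ph$truth, "cementum"))

  igd <- segment_interglobular(cv, c(ph$truth$crown_slices[1],
                                     ph$truth$cej_slice))
  expect_equal(sum(igd$mask$mask), 0)  # no voids requested -> empty mask
})

test_that("cementum filter-and-mask-back keeps cementum, drops pulp-adjacent and low-density voxels", {
  # uniform 900 block with no pulp contact: entirely retained
  v <- array(900, dim = c(15, 15, 15))
  cv <- calibrated_volume(v, 10)
  m <- segment_cementum(cv, pulp = array(FALSE, dim(v)))
  expect_true(all(m$mask))

  # a voxel passing the filtered window but <= 650 on the original volume is
  # excluded by the mask-back step
  v2 <- array(900, dim = c(15, 15, 15))
  v2[8, 8, 8] <- 600
  cv2 <- calibrated_volume(v2, 10)
  m2 <- segment_cementum(cv2, pulp = array(FALSE, dim(v2)))
  expect_false(m2$mask[8, 8, 8])
  expect_equal(sum(m2$mask), length(v2) - 1L)

  # the pulp-adjacent highlight is removed: with the component rule alone the
  # whole pulp-contacting slab goes; with the margin rule the band within
  # 50 um of the pulp goes while distant cementum stays
  v3 <- array(0, dim = c(40, 15, 15))
  v3[2:9, , ] <- 900       # cementum-like slab, no pulp contact
  v3[22:30, , ] <- 900     # slab touching the "pulp" (gap wider than kernel)
  v3[31:40, , ] <- 200     # pulp
  pulp3 <- array(FALSE, dim(v3)); pulp3[31:40, , ] <- TRUE
  cv3 <- calibrated_volume(v3, 10)
  m3 <- segment_cementum(cv3, pulp = pulp3, pulp_margin_um = 0)
  expect_true(any(m3$mask[2:9, , ]))
  expect_false(any(m3$mask[22:30, , ]))
  m3b <- segment_cementum(cv3, pulp = pulp3)
  expect_true(any(m3b$mask[2:9, , ]))
  expect_false(any(m3b$mask[26:30, , ]))  # within 50 um of the pulp
  expect_true(any(m3b$mask[22:25, , ]))   # distant part of the slab survives

  # empty result warns (aplastic cementum is a phenotype, not an error)
  v4 <- array(1500, dim = c(12, 12, 12))
  expect_warning(segment_cementum(calibrated_volume(v4, 10),
                                  pulp = array(FALSE, dim(v4))),
                 "aplastic|hypoplastic")
})

test_that("phantom cementum is recovered with high overlap under noise", {
  ph <- small_phantom_noisy()
  cv <- as_cv(ph)
  tr <- truth_mask(ph$truth, "cementum")
  m <- segment_cementum(cv, zrange = c(ph$truth$apical_enamel_slice + 1L,
                                       dim(cv$data)[3]))$mask
  dice <- 2 * sum(m & tr) / (sum(m) + sum(tr))
  expect_gt(dice, 0.9)
})

test_that("interglobular segmentation recovers void voxels and is monotone", {
  ph <- small_phantom_noisy()  # void fraction 0.10, noise sd 50
  cv <- as_cv(ph)
  zr <- c(ph$truth$crown_slices[1], ph$truth$cej_slice)
  igd <- segment_interglobular(cv, zr)
  got <- sum(igd$mask$mask)
  expect_lt(abs(got - ph$truth$void_voxels) / ph$truth$void_voxels, 0.10)

  counts <- vapply(c(0.03, 0.08, 0.15), function(f) {
    p <- generate_tooth_phantom(small_spec(void_fraction = f, noise_sd = 50,
                                           seed = 21L))
    c2 <- as_cv(p)
    sum(segment_interglobular(c2, c(p$truth$crown_slices[1],
                                    p$truth$cej_slice))$mask$mask)
  }, numeric(1))
  expect_true(all(diff(counts) > 0))
})
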