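test_that("CEJ detection finds the most apical complete enamel ring", {
  # rings complete only on slices 3..14, broken (slit) on 15..20:
  # scanning from the root end, the first complete ring is slice 14
  m <- annulus_stack(nz = 25, z_present = 3:20, z_ring = 3:14)
  expect_identical(detect_cej(m), 14L)

  # complete tube everywhere: first ring met from the root end is the last slice
  tube <- annulus_stack(nz = 10, z_present = 1:10, z_ring = 1:10)
  expect_identical(detect_cej(tube), 10L)

  # every slice broken -> error
  broken <- annulus_stack(nz = 10, z_present = 1:10, z_ring = integer(0))
  expect_error(detect_cej(broken), "ring")
  expect_error(detect_cej(array(FALSE, c(5, 5, 5))), "empty")
})

test_that("apical enamel extension is the last enamel-bearing slice", {
  m <- array(FALSE, c(7, 7, 9))
  m[4, 4, 5] <- TRUE
  expect_identical(detect_apical_enamel(m), 5L)
  expect_identical(detect_apical_enamel(array(TRUE, c(3, 3, 6))), 6L)
  expect_error(detect_apical_enamel(array(FALSE, c(3, 3, 3))), "empty")
})

test_that("ROI construction follows the 0.5 mm / 150 um slice arithmetic", {
  r <- build_crown_roi(100L, 10, 300L)
  expect_identical(r$slices, c(51L, 100L))   # 50 slices ending at the CEJ
  expect_identical(r$n_slices, 50L)
  expect_identical(build_crown_roi(100L, 20, 300L)$n_slices, 25L)
  expect_error(build_crown_roi(5L, 10, 30L), "coronal")

  rr <- build_root_roi(200L, 10, 400L)
  expect_identical(rr$slices, c(216L, 265L))  # skip 15, span 50
  expect_error(build_root_roi(200L, 10, 240L), "short")
  rr5 <- build_root_roi(200L, 5, 500L)
  expect_identical(rr5$slices[1] - 200L, 31L)  # skip 30 slices
  expect_identical(rr5$n_slices, 100L)
})

test_that("apical cementum ROI collects 25-50 hollow-cylinder slices", {
  m80 <- annulus_stack(nz = 100, z_present = 11:90, z_ring = 11:90)
  r <- build_cementum_roi(m80, 10)
  expect_identical(r$slices, c(41L, 90L))  # the 50 most apical of 80
  expect_identical(r$n_slices, 50L)

  m30 <- annulus_stack(nz = 50, z_present = 11:40, z_ring = 11:40)
  expect_identical(build_cementum_roi(m30, 10)$n_slices, 30L)

  m10 <- annulus_stack(nz = 30, z_present = 11:20, z_ring = 11:20)
  expect_error(build_cementum_roi(m10, 10), "insufficient")
})

test_that("dentin zones partition the wall into 150 um shells", {
  # annulus wall 45 voxels (450 um at 10 um): zones ~15 voxels each; the tube
  # spans the full z range so shell distances are purely radial
  r_in <- 20; r_out <- 65
  dn <- tube_mask(r_in, r_out, height = 30, pad_z = 0)
  n <- dim(dn)[1]
  c0 <- r_out + 3 + 1
  xs <- seq_len(n) - c0
  r2 <- outer(xs^2, xs^2, "+")
  pulp <- array(FALSE, dim(dn))
  for (z in 1:30) pulp[, , z] <- r2 <= r_in^2
  z <- subdivide_dentin(dn, NULL, pulp, voxel_size_um = 10)

  # partition + disjointness
  expect_identical(z$mantle | z$circumpulpal | z$proximal_pulpal, dn)
  expect_equal(sum(z$mantle) + sum(z$circumpulpal) + sum(z$proximal_pulpal),
               sum(dn))
  expect_false(any(z$mantle & z$circumpulpal))
  expect_false(any(z$mantle & z$proximal_pulpal))

  # analytic annulus volumes (mid-slice, away from tube ends)
  h <- 30
  ana <- function(r0, r1) pi * (r1^2 - r0^2) * h
  expect_lt(abs(sum(z$mantle) - ana(r_out - 15, r_out)) / ana(r_out - 15, r_out), 0.05)
  expect_lt(abs(sum(z$proximal_pulpal) - ana(r_in, r_in + 15)) / ana(r_in, r_in + 15), 0.05)
  expect_lt(abs(sum(z$circumpulpal) - ana(r_in + 15, r_out - 15)) / ana(r_in + 15, r_out - 15), 0.05)
})

test_that("a wall of exactly twice the shell depth leaves no circumpulpal dentin", {
  # flat slab geometry for exact arithmetic: pulp | 30-voxel dentin | background
  d <- c(40L, 12L, 12L)
  dn <- array(FALSE, d); pu <- array(FALSE, d)
  pu[1:5, , ] <- TRUE
  dn[6:35, , ] <- TRUE
  expect_warning(z <- subdivide_dentin(dn, NULL, pu, voxel_size_um = 10),
                 "circumpulpal")
  expect_equal(sum(z$circumpulpal), 0)
  expect_identical(z$mantle | z$proximal_pulpal, dn)
  expect_true(z$degenerate)
})

test_that("orientation aligns the root axis with z and is idempotent", {
  ph <- small_phantom()
  cv <- as_cv(ph)

  # already aligned: identity rotation, volume numerically unchanged
  o1 <- orient_volume(cv)
  expect_lt(attr(o1, "rotation_angle_deg"), 0.5)
  expect_equal(o1$data, cv$data, tolerance = 1e-8)

  # rotate 10 degrees about x, re-orient, recover the axis within 1 degree
  pad <- 25L
  d <- dim(cv$data)
  big <- array(0, d + 2L * pad)
  big[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- cv$data
  th <- 10 * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(th), sin(th), 0, -sin(th), cos(th)), 3, 3)
  ctr <- (dim(big) - 1) / 2
  rot <- array(dentomorph:::cpp_affine_resample(as.numeric(big),
                                                as.integer(dim(big)),
                                                t(Rx), as.numeric(ctr), 0),
               dim = dim(big))
  rcv <- calibrated_volume(rot, 10)
  ax_before <- estimate_tooth_axis(rcv)
  expect_gt(acos(abs(ax_before[3])) * 180 / pi, 8)  # it really was tilted
  o2 <- orient_volume(rcv)
  ax <- estimate_tooth_axis(o2)
  expect_lt(acos(min(1, abs(ax[3]))) * 180 / pi, 1)

  # orienting twice changes little
  o3 <- orient_volume(o2)
  expect_lt(attr(o3, "rotation_angle_deg"), 1)
})

test_that("pulp cavity mask matches the generated pulp and voids", {
  ph <- small_phantom_noisy()
  cv <- as_cv(ph)
  pm <- pulp_cavity_mask(cv)
  tr <- truth_mask(ph$truth, "pulp") | truth_mask(ph$truth, "void")
  agree <- sum(pm & tr) / sum(pm | tr)
  expect_gt(agree, 0.95)
})
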