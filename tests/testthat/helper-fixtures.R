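# Shared fixtures, built lazily and cached for the whole test run.

fx_cache <- new.env(parent = emptyenv())

fixture <- function(key, build) {
  if (!exists(key, envir = fx_cache)) assign(key, build(), envir = fx_cache)
  get(key, envir = fx_cache)
}

# A miniature tooth for fast unit tests (~123 x 123 x 132 voxels).
small_spec <- function(void_fraction = 0, noise_sd = 0, seed = 1L, ...) {
  phantom_spec(crown_height_mm = 0.5, root_length_mm = 0.7,
               crown_radius_mm = 0.55, root_radius_mm = 0.5,
               enamel_thickness_mm = 0.12, dentin_wall_mm = 0.3,
               cementum_thickness_um = 80,
               void_fraction = void_fraction, noise_sd = noise_sd,
               seed = seed, ...)
}

small_phantom <- function() {
  fixture("small_phantom", function() generate_tooth_phantom(small_spec()))
}

small_phantom_noisy <- function() {
  fixture("small_phantom_noisy",
          function() generate_tooth_phantom(small_spec(void_fraction = 0.1,
                                                       noise_sd = 50,
                                                       seed = 7L)))
}

default_phantom_noiseless <- function() {
  fixture("default_phantom_noiseless",
          function() generate_tooth_phantom(phantom_spec(void_fraction = 0.05,
                                                         seed = 3L)))
}

as_cv <- function(phantom) {
  calibrated_volume(phantom$volume, phantom$spec$voxel_size_um)
}

# Digital solid ball of odd diameter d, padded into a cube.
digital_ball <- function(d, pad = 3L) {
  r <- (d - 1) / 2
  n <- as.integer(d + 2 * pad)
  c0 <- (n + 1) / 2
  co <- arrayInd(seq_len(n^3), c(n, n, n))
  array((co[, 1] - c0)^2 + (co[, 2] - c0)^2 + (co[, 3] - c0)^2 <= r^2,
        dim = c(n, n, n))
}

# Hollow cylinder (tube) along z: r_in < r <= r_out. pad_z = 0 makes the tube
# span the full z extent (no end caps).
tube_mask <- function(r_in, r_out, height, pad = 3L, pad_z = pad) {
  n <- as.integer(2 * (r_out + pad) + 1)
  c0 <- r_out + pad + 1
  xs <- seq_len(n) - c0
  r2 <- outer(xs^2, xs^2, "+")
  disc <- r2 <= r_out^2 & r2 > r_in^2
  nz <- as.integer(height + 2 * pad_z)
  m <- array(FALSE, dim = c(n, n, nz))
  for (z in (pad_z + 1):(pad_z + height)) m[, , z] <- disc
  m
}

# Enamel-like annulus stack for landmark tests; `gap_z` slices get a 1-voxel
# notch so the ring is broken there.
annulus_stack <- function(nz, z_present, z_ring, r_in = 8, r_out = 12,
                          n = 31L) {
  c0 <- (n + 1) / 2
  xs <- seq_len(n) - c0
  r2 <- outer(xs^2, xs^2, "+")
  ring <- r2 <= r_out^2 & r2 > r_in^2
  m <- array(FALSE, dim = c(n, n, nz))
  for (z in z_present) {
    sl <- ring
    if (!(z %in% z_ring))  # radial slit connecting the hole to the outside
      sl[c0 + (r_in:(r_out + 1)), c0] <- FALSE
    m[, , z] <- sl
  }
  m
}
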