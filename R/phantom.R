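#' Specify a synthetic tooth phantom
#'
#' Builds the parameter set for [generate_tooth_phantom()]: an axisymmetric,
#' single-rooted primary tooth modelled as a solid of revolution along the
#' axial (z) axis, with an enamel cap, crown and root dentin, a pulp
#' chamber/canal, an acellular cementum sheath on the root surface, and
#' optional hypomineralized interglobular voids in the crown dentin. Slice 1
#' is the most coronal slice; the z index increases apically.
#'
#' Default nominal densities (enamel 2000, dentin 1200, cementum 900, pulp 200,
#' background 0 mg/cm^3 HA) sit centrally inside the segmentation windows used
#' by the analysis (enamel >1600, dentin 650-1600, cementum 450-1050); they are
#' generator conventions, not measured values. The default geometry is a
#' miniature tooth (~1.6 x 1.6 x 2 mm) so that a full phantom stays near 200^3
#' voxels at the nominal 10 um voxel size.
#'
#' @param voxel_size_um Isotropic voxel edge, micrometres.
#' @param crown_height_mm,root_length_mm Axial extents of crown and root.
#' @param crown_radius_mm,root_radius_mm Outer radii of crown cylinder and of
#'   the root at the cementum-enamel junction (the root tapers conically over
#'   its apical 40% to 35% of its starting radius).
#' @param enamel_thickness_mm Radial enamel thickness of the crown cap.
#' @param dentin_wall_mm Radial crown dentin wall between enamel and pulp.
#' @param cementum_thickness_um Radial thickness of the root cementum sheath.
#' @param predentin_width_um Nominal predentin width, carried for the 2-D
#'   histology generator; it has no effect on the mineral-density volume.
#' @param density_enamel,density_dentin,density_cementum,density_pulp,density_background
#'   Nominal tissue densities, mg/cm^3 HA.
#' @param void_fraction Target interglobular void volume fraction of the crown
#'   dentin, in `[0, 1)`.
#' @param void_radius_um Radius of the spherical voids.
#' @param noise_sd Additive Gaussian noise, grey units, applied after the
#'   density-to-grey map.
#' @param seed Integer seed; identical spec + seed gives a bit-identical
#'   phantom.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_tooth_phantom()]
#' @export
phantom_spec <- function(voxel_size_um = 10,
                         crown_height_mm = 0.9,
                         root_length_mm = 1.0,
                         crown_radius_mm = 0.8,
                         root_radius_mm = 0.7,
                         enamel_thickness_mm = 0.2,
                         dentin_wall_mm = 0.45,
                         cementum_thickness_um = 100,
                         predentin_width_um = 20,
                         density_enamel = 2000,
                         density_dentin = 1200,
                         density_cementum = 900,
                         density_pulp = 200,
                         density_background = 0,
                         void_fraction = 0,
                         void_radius_um = 30,
                         noise_sd = 0,
                         seed = 1L) {
  spec <- list(voxel_size_um = voxel_size_um,
               crown_height_mm = crown_height_mm,
               root_length_mm = root_length_mm,
               crown_radius_mm = crown_radius_mm,
               root_radius_mm = root_radius_mm,
               enamel_thickness_mm = enamel_thickness_mm,
               dentin_wall_mm = dentin_wall_mm,
               cementum_thickness_um = cementum_thickness_um,
               predentin_width_um = predentin_width_um,
               density_enamel = density_enamel,
               density_dentin = density_dentin,
               density_cementum = density_cementum,
               density_pulp = density_pulp,
               density_background = density_background,
               void_fraction = void_fraction,
               void_radius_um = void_radius_um,
               noise_sd = noise_sd,
               seed = as.integer(seed))
  for (nm in setdiff(names(spec), "seed")) stopifnot_scalar(spec[[nm]], nm)
  lengths_pos <- c("voxel_size_um", "crown_height_mm", "root_length_mm",
                   "crown_radius_mm", "root_radius_mm", "enamel_thickness_mm",
                   "dentin_wall_mm", "cementum_thickness_um", "void_radius_um")
  for (nm in lengths_pos)
    if (spec[[nm]] <= 0) stop(sprintf("'%s' must be > 0", nm), call. = FALSE)
  if (spec$void_fraction < 0 || spec$void_fraction >= 1)
    stop("'void_fraction' must be in [0, 1)", call. = FALSE)
  if (spec$noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  pulp_r <- crown_radius_mm - enamel_thickness_mm - dentin_wall_mm
  if (pulp_r <= 0)
    stop("enamel_thickness_mm + dentin_wall_mm must be < crown_radius_mm",
         call. = FALSE)
  if (root_radius_mm > crown_radius_mm)
    stop("'root_radius_mm' must not exceed 'crown_radius_mm'", call. = FALSE)
  structure(spec, class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("Tooth phantom specification\n")
  cat(sprintf("  voxel %.3g um; crown %.3g mm (radius %.3g), root %.3g mm (radius %.3g)\n",
              x$voxel_size_um, x$crown_height_mm, x$crown_radius_mm,
              x$root_length_mm, x$root_radius_mm))
  cat(sprintf("  enamel %.3g mm, dentin wall %.3g mm, cementum %.3g um\n",
              x$enamel_thickness_mm, x$dentin_wall_mm, x$cementum_thickness_um))
  cat(sprintf("  densities (E/D/C/P/bg): %g/%g/%g/%g/%g mg/cm^3 HA\n",
              x$density_enamel, x$density_dentin, x$density_cementum,
              x$density_pulp, x$density_background))
  cat(sprintf("  voids: fraction %.3g, radius %.3g um; noise sd %.3g; seed %d\n",
              x$void_fraction, x$void_radius_um, x$noise_sd, x$seed))
  invisible(x)
}

# Tissue codes used in the ground-truth label volume.
TISSUE_CODES <- c(background = 0L, pulp = 1L, dentin = 2L, enamel = 3L,
                  cementum = 4L, void = 5L)

#' Extract a ground-truth tissue mask
#'
#' @param truth The `$truth` element of a [generate_tooth_phantom()] result.
#' @param tissue One of `"background"`, `"pulp"`, `"dentin"`, `"enamel"`,
#'   `"cementum"`, `"void"`.
#' @return A logical array.
#' @export
truth_mask <- function(truth, tissue = names(TISSUE_CODES)) {
  tissue <- match.arg(tissue)
  truth$label == TISSUE_CODES[[tissue]]
}

# Integer ball offsets with |d| <= r (voxel units).
ball_offsets <- function(r) {
  ri <- floor(r)
  g <- expand.grid(dx = -ri:ri, dy = -ri:ri, dz = -ri:ri)
  g[g$dx^2 + g$dy^2 + g$dz^2 <= r^2, , drop = FALSE]
}

#' Generate a synthetic tooth volume with voxel ground truth
#'
#' Renders the axisymmetric tooth described by a [phantom_spec()] into a
#' grey-value voxel volume plus a ground-truth label volume. Interglobular
#' voids are placed as non-overlapping spheres, fully inside crown dentin, by
#' seeded rejection sampling until the target void volume is reached; they are
#' rendered at the pulp density. The grey values are an affine map of the
#' nominal densities (`grey = grey_intercept + grey_slope * density`) plus
#' optional Gaussian noise, so a fitted calibration can be exercised
#' end-to-end.
#'
#' @param spec A [phantom_spec()].
#' @param grey_slope,grey_intercept Affine density-to-grey map; the defaults
#'   make grey values equal densities.
#' @return A list of class `tooth_phantom` with elements `volume` (numeric 3-D
#'   array of grey values), `truth` (label volume, landmark slices, realized
#'   void statistics) and `spec`.
#' @export
generate_tooth_phantom <- function(spec, grey_slope = 1, grey_intercept = 0) {
  stopifnot(inherits(spec, "phantom_spec"))
  vox <- spec$voxel_size_um
  um <- function(mm) mm * 1000

  n_crown <- max(1L, as.integer(round(um(spec$crown_height_mm) / vox)))
  n_root <- max(1L, as.integer(round(um(spec$root_length_mm) / vox)))
  mz <- 6L
  mxy <- 6L

  Rc <- um(spec$crown_radius_mm)
  Te <- um(spec$enamel_thickness_mm)
  wall <- um(spec$dentin_wall_mm)
  Rp <- Rc - Te - wall
  Rr <- um(spec$root_radius_mm)
  Tc <- spec$cementum_thickness_um
  canal0 <- Rp
  canal_apex <- min(Rp, 50)
  apex_R <- 0.6 * Rr     # gentle conical taper over the apical half; steeper
  taper_from <- 0.5      # cones make the sheath obliquely thin and unrealistic

  half <- ceiling(Rc / vox) + mxy
  nx <- 2L * half + 1L
  ny <- nx
  nz <- mz + n_crown + n_root + mz
  cx <- half + 1L

  xs <- ((1:nx) - cx) * vox
  r2 <- outer(xs^2, xs^2, "+")  # squared in-plane radius, um^2

  label <- array(0L, dim = c(nx, ny, nz))
  n_enamel_cap <- ceiling(Te / vox)

  for (zt in seq_len(n_crown)) {
    z <- mz + zt
    sl <- integer(nx * ny)
    if (zt <= n_enamel_cap) {
      sl[r2 <= Rc^2] <- TISSUE_CODES[["enamel"]]
    } else {
      sl[r2 <= Rc^2] <- TISSUE_CODES[["enamel"]]
      sl[r2 <= (Rc - Te)^2] <- TISSUE_CODES[["dentin"]]
      sl[r2 <= Rp^2] <- TISSUE_CODES[["pulp"]]
    }
    label[, , z] <- sl
  }
  for (zr in seq_len(n_root)) {
    z <- mz + n_crown + zr
    f <- max(0, (zr / n_root - taper_from) / (1 - taper_from))
    Rout <- Rr - (Rr - apex_R) * f
    canal <- canal0 - (canal0 - canal_apex) * f
    sl <- integer(nx * ny)
    sl[r2 <= Rout^2] <- TISSUE_CODES[["cementum"]]
    sl[r2 <= (Rout - Tc)^2] <- TISSUE_CODES[["dentin"]]
    sl[r2 <= canal^2] <- TISSUE_CODES[["pulp"]]
    label[, , z] <- sl
  }

  cej_slice <- as.integer(mz + n_crown)  # most apical complete enamel ring
  apical_enamel_slice <- as.integer(mz + n_crown)

  # Interglobular voids: non-overlapping spheres fully inside crown dentin.
  crown_z <- (mz + 1L):(mz + n_crown)
  crown_dentin <- label == TISSUE_CODES[["dentin"]]
  crown_dentin[, , -crown_z] <- FALSE
  n_cd <- sum(crown_dentin)
  rv <- spec$void_radius_um / vox
  offs <- ball_offsets(rv)
  ball_n <- nrow(offs)
  void_n <- 0L

  if (spec$void_fraction > 0 && n_cd > 0L) {
    target_n <- round(spec$void_fraction * n_cd / ball_n)
    if (target_n > 0L) {
      # Centres lie in crown dentin; spheres must fit inside dentin as a whole
      # with a one-voxel dentin shell left around them, so voids never abut
      # pulp or enamel (they may dip just past the CEJ plane, which keeps the
      # crown ROI from being depleted near the CEJ). Rejection sampling over a
      # shuffled candidate list with an occupancy stamp enforcing non-overlap.
      dentin_all <- label == TISSUE_CODES[["dentin"]]
      d2 <- feature_sqedt(!dentin_all, outside_is_feature = TRUE)
      elig <- which(crown_dentin & d2 > (rv + 1)^2)
      if (length(elig) == 0L)
        warning("no eligible void centres; dentin wall too thin for void radius")
      excl <- ball_offsets(2 * rv)     # centre-to-centre exclusion
      blocked <- array(FALSE, dim = dim(label))
      centres <- matrix(0L, nrow = target_n, ncol = 3)
      with_seed(spec$seed, {
        cand <- sample(elig)
        nxy <- nx * ny
        for (i in cand) {
          if (void_n >= target_n) break
          if (blocked[i]) next
          i0 <- i - 1L
          zc <- i0 %/% nxy
          rem <- i0 - zc * nxy
          p <- c(rem %% nx + 1L, rem %/% nx + 1L, zc + 1L)
          void_n <- void_n + 1L
          centres[void_n, ] <- p
          bx <- p[1] + excl$dx; by <- p[2] + excl$dy; bz <- p[3] + excl$dz
          ok <- bx >= 1L & bx <= nx & by >= 1L & by <= ny & bz >= 1L & bz <= nz
          blocked[cbind(bx[ok], by[ok], bz[ok])] <- TRUE
        }
      })
      if (void_n < target_n)
        warning(sprintf(
          "placed %d of %d requested voids; realized fraction %.4f < requested %.4f",
          void_n, target_n, void_n * ball_n / n_cd, spec$void_fraction))
      for (k in seq_len(void_n)) {
        ix <- centres[k, 1] + offs$dx
        iy <- centres[k, 2] + offs$dy
        iz <- centres[k, 3] + offs$dz
        label[cbind(ix, iy, iz)] <- TISSUE_CODES[["void"]]
      }
    }
  }

  dens <- c(spec$density_background, spec$density_pulp, spec$density_dentin,
            spec$density_enamel, spec$density_cementum, spec$density_pulp)
  density <- array(dens[label + 1L], dim = dim(label))
  volume <- grey_intercept + grey_slope * density
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed + 1L,
                       rnorm(length(volume), 0, spec$noise_sd))
    volume <- volume + array(noise, dim = dim(volume))
  }

  vv_mm3 <- (vox / 1000)^3
  truth <- list(label = label,
                densities = dens[-1],
                cej_slice = cej_slice,
                apical_enamel_slice = apical_enamel_slice,
                crown_slices = range(crown_z),
                root_slices = c(mz + n_crown + 1L, mz + n_crown + n_root),
                crown_dentin_voxels = n_cd,
                void_n = void_n,
                void_voxels = void_n * ball_n,
                void_volume_mm3 = void_n * ball_n * vv_mm3,
                void_fraction_requested = spec$void_fraction,
                void_fraction_realized = if (n_cd > 0) void_n * ball_n / n_cd else 0,
                ball_voxels = ball_n,
                voxel_size_um = vox,
                grey_slope = grey_slope,
                grey_intercept = grey_intercept)
  structure(list(volume = volume, truth = truth, spec = spec),
            class = "tooth_phantom")
}

#' @export
print.tooth_phantom <- function(x, ...) {
  d <- dim(x$volume)
  cat(sprintf("Synthetic tooth phantom: %d x %d x %d voxels at %.3g um\n",
              d[1], d[2], d[3], x$truth$voxel_size_um))
  cat(sprintf("  CEJ slice %d, apical enamel slice %d\n",
              x$truth$cej_slice, x$truth$apical_enamel_slice))
  cat(sprintf("  voids: %d spheres, %.4g mm^3 (realized fraction %.4f)\n",
              x$truth$void_n, x$truth$void_volume_mm3,
              x$truth$void_fraction_realized))
  invisible(x)
}

#' Generate a multi-rod hydroxyapatite calibration phantom
#'
#' One homogeneous cylinder per rod density, rendered through an affine
#' density-to-grey map with optional Gaussian noise — the synthetic stand-in
#' for a scanner's 5-density HA standard.
#'
#' @param rod_densities Distinct rod densities, mg/cm^3 HA (at least 2).
#' @param grey_slope,grey_intercept Affine density-to-grey map
#'   (`grey = grey_intercept + grey_slope * density`).
#' @param noise_sd Additive Gaussian grey noise.
#' @param rod_radius,rod_length Rod geometry in voxels.
#' @param seed Seed for the noise stream.
#' @return A list with `volume`, `rod_masks` (list of logical arrays),
#'   `rod_densities`, and the grey map used.
#' @export
generate_calibration_phantom <- function(rod_densities,
                                         grey_slope = 1, grey_intercept = 0,
                                         noise_sd = 0,
                                         rod_radius = 8L, rod_length = 24L,
                                         seed = 1L) {
  if (length(rod_densities) < 2L)
    stop("at least 2 rod densities are required", call. = FALSE)
  if (anyDuplicated(rod_densities))
    stop("duplicate rod densities give a degenerate calibration fit",
         call. = FALSE)
  nr <- length(rod_densities)
  gap <- 4L
  pitch <- 2L * rod_radius + gap
  nx <- nr * pitch + gap
  ny <- 2L * rod_radius + 2L * gap
  nz <- rod_length + 2L * gap
  vol <- array(grey_intercept, dim = c(nx, ny, nz))
  cy <- gap + rod_radius + 0.5
  zr <- (gap + 1L):(gap + rod_length)
  masks <- vector("list", nr)
  xs <- seq_len(nx); ys <- seq_len(ny)
  for (k in seq_len(nr)) {
    cxk <- gap + (k - 1L) * pitch + rod_radius + 0.5
    disc <- outer((xs - cxk)^2, (ys - cy)^2, "+") <= rod_radius^2
    m <- array(FALSE, dim = dim(vol))
    m[, , zr] <- disc
    masks[[k]] <- m
    vol[m] <- grey_intercept + grey_slope * rod_densities[k]
  }
  if (noise_sd > 0) {
    noise <- with_seed(seed, rnorm(length(vol), 0, noise_sd))
    vol <- vol + array(noise, dim = dim(vol))
  }
  list(volume = vol, rod_masks = masks, rod_densities = rod_densities,
       grey_slope = grey_slope, grey_intercept = grey_intercept)
}

#' Generate a synthetic 2-D histology section
#'
#' Emulates a grayscale (16-bit-range) section of crown dentin for
#' histomorphometry: a mineralized dentin field (dark) carrying unmineralized
#' interglobular blobs (bright) at a requested mineralized area fraction,
#' flanked by a cementum band on the outer edge and a predentin band on the
#' pulpal edge. `mode = "checkerboard"` replaces the blob field by an exact
#' single-pixel checkerboard (area fraction exactly 0.5).
#'
#' @param area_fraction_mineralized Target mineralized fraction of the dentin
#'   field, in `[0, 1]`.
#' @param predentin_width_um,cementum_width_um Band widths; must be at least
#'   one pixel when positive.
#' @param um_per_px Pixel pitch.
#' @param field_px Width and height of the dentin field, pixels.
#' @param blob_radius_um Radius of the unmineralized blobs.
#' @param noise_sd Additive Gaussian grey noise (16-bit grey units).
#' @param mode `"blobs"` (random discs) or `"checkerboard"` (exact 0.5).
#' @param seed Integer seed.
#' @return A list with `image` (numeric matrix, x by y) and `truth` (realized
#'   mineralized fraction, band widths in px, and masks for field, predentin
#'   and cementum).
#' @export
generate_histology_section <- function(area_fraction_mineralized,
                                       predentin_width_um = 40,
                                       cementum_width_um = 20,
                                       um_per_px = 1,
                                       field_px = c(300L, 300L),
                                       blob_radius_um = 15,
                                       noise_sd = 0,
                                       mode = c("blobs", "checkerboard"),
                                       seed = 1L) {
  mode <- match.arg(mode)
  af <- area_fraction_mineralized
  if (af < 0 || af > 1) stop("area fraction must be in [0, 1]", call. = FALSE)
  wp <- round(predentin_width_um / um_per_px)
  wc <- round(cementum_width_um / um_per_px)
  if (predentin_width_um > 0 && wp < 1L)
    stop("predentin band narrower than 1 px at this um_per_px", call. = FALSE)
  if (cementum_width_um > 0 && wc < 1L)
    stop("cementum band narrower than 1 px at this um_per_px", call. = FALSE)

  GREY <- c(mineralized = 10000, unmineralized = 52000,
            predentin = 45000, cementum = 25000, slide = 62000)
  border <- 3L  # empty-slide margin so edge layers have two boundaries
  fx <- field_px[1]; fy <- field_px[2]
  nx <- border + wc + fx + wp + border
  ny <- fy

  unmin <- matrix(FALSE, fx, fy)
  if (mode == "checkerboard") {
    unmin <- (outer(seq_len(fx), seq_len(fy), "+") %% 2L) == 0L
  } else if (af < 1) {
    target <- round((1 - af) * fx * fy)
    rb <- max(1, blob_radius_um / um_per_px)
    ri <- floor(rb)
    g <- expand.grid(dx = -ri:ri, dy = -ri:ri)
    g <- g[g$dx^2 + g$dy^2 <= rb^2, , drop = FALSE]
    with_seed(seed, {
      tries <- 0L
      while (sum(unmin) < target && tries < 50000L) {
        tries <- tries + 1L
        cxk <- sample.int(fx, 1L)
        cyk <- sample.int(fy, 1L)
        ix <- cxk + g$dx; iy <- cyk + g$dy
        ok <- ix >= 1L & ix <= fx & iy >= 1L & iy <= fy
        unmin[cbind(ix[ok], iy[ok])] <- TRUE
      }
    })
  }

  img <- matrix(GREY[["mineralized"]], nx, ny)
  img[c(seq_len(border), (nx - border + 1L):nx), ] <- GREY[["slide"]]
  field_cols <- (border + wc + 1L):(border + wc + fx)
  img[field_cols, ][unmin] <- GREY[["unmineralized"]]
  cem_mask <- matrix(FALSE, nx, ny)
  pre_mask <- matrix(FALSE, nx, ny)
  if (wc > 0L) {
    cols <- border + seq_len(wc)
    img[cols, ] <- GREY[["cementum"]]
    cem_mask[cols, ] <- TRUE
  }
  if (wp > 0L) {
    cols <- (nx - border - wp + 1L):(nx - border)
    img[cols, ] <- GREY[["predentin"]]
    pre_mask[cols, ] <- TRUE
  }
  if (noise_sd > 0)
    img <- img + matrix(with_seed(seed + 1L, rnorm(length(img), 0, noise_sd)),
                        nx, ny)

  field_mask <- matrix(FALSE, nx, ny)
  field_mask[field_cols, ] <- TRUE
  truth <- list(realized_fraction_mineralized = 1 - sum(unmin) / (fx * fy),
                requested_fraction_mineralized = af,
                predentin_width_px = wp,
                cementum_width_px = wc,
                um_per_px = um_per_px,
                field_mask = field_mask,
                predentin_mask = pre_mask,
                cementum_mask = cem_mask)
  list(image = img, truth = truth)
}
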