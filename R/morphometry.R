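#' Mean tissue density over a mask
#'
#' Arithmetic mean of ORIGINAL calibrated densities over the mask voxels
#' (quantification always runs on the unfiltered volume).
#'
#' @param vol A [calibrated_volume()].
#' @param mask Logical array or `tissue_mask`.
#' @return Mean density, mg/cm^3 HA.
#' @export
mean_density <- function(vol, mask) {
  v <- vol_data(vol)
  m <- vol_data(mask)
  if (!any(m)) stop("mask is empty", call. = FALSE)
  mean(v[m])
}

#' Model-independent local thickness of a structure
#'
#' Maximal-inscribed-sphere (Hildebrand-Ruegsegger) local thickness, the
#' algorithm behind standard cortical-thickness measures: each foreground
#' voxel is assigned the diameter of the largest sphere that contains it and
#' fits inside the mask, and the ROI thickness is the mean over the z-stack.
#' Sphere radii are the Euclidean distance-transform values (distance to the
#' nearest background voxel centre), the classic convention; the up-to-one-
#' voxel discretization bias this carries on thin structures is accepted and
#' documented, not corrected.
#'
#' @param mask Logical array or `tissue_mask`.
#' @param voxel_size_um Voxel size.
#' @param reference If `TRUE`, use the exhaustive brute-force reference
#'   implementation (for validation on tiny masks only).
#' @return A list of class `local_thickness`: `map_mm` (per-voxel thickness,
#'   mm), `mean_mm`, `n_voxels`.
#' @export
local_thickness <- function(mask, voxel_size_um, reference = FALSE) {
  m <- vol_data(mask)
  if (!any(m)) stop("mask is empty", call. = FALSE)
  d <- dim3(m)
  fn <- if (reference) cpp_localthick_brute else cpp_localthick
  th <- array(fn(as.logical(m), d), dim = dim(m))
  map_mm <- th * voxel_size_um / 1000
  structure(list(map_mm = map_mm,
                 mean_mm = mean(map_mm[m]),
                 n_voxels = sum(m),
                 voxel_size_um = voxel_size_um),
            class = "local_thickness")
}

#' @export
print.local_thickness <- function(x, ...) {
  cat(sprintf("Local thickness: mean %.3f mm over %d voxels\n",
              x$mean_mm, x$n_voxels))
  invisible(x)
}

#' Interglobular dentin volume and fraction
#'
#' @param igd Interglobular mask (from [segment_interglobular()]).
#' @param territory Crown dentin territory mask.
#' @param voxel_size_um Voxel size.
#' @return List with `volume_mm3`, `fraction` (of the territory) and voxel
#'   counts.
#' @export
interglobular_volume <- function(igd, territory, voxel_size_um) {
  mi <- vol_data(igd)
  mt <- vol_data(territory)
  nt <- sum(mt)
  if (nt == 0L) stop("dentin territory is empty", call. = FALSE)
  ni <- sum(mi)
  vv <- (voxel_size_um / 1000)^3
  list(volume_mm3 = ni * vv, fraction = ni / nt,
       igd_voxels = ni, territory_voxels = nt)
}

#' Crown length along the tooth axis
#'
#' Axial distance from the CEJ plane to the most coronal enamel-containing
#' slice. The source software's operational rule is unrecorded; this axial
#' CEJ-to-cusp definition is the package's documented choice.
#'
#' @param enamel Enamel mask.
#' @param cej_slice CEJ slice index.
#' @param voxel_size_um Voxel size.
#' @return Crown length, mm.
#' @export
crown_length <- function(enamel, cej_slice, voxel_size_um) {
  m <- vol_data(enamel)
  sl <- slices_with(m)
  sl <- sl[sl <= cej_slice]
  if (length(sl) == 0L)
    stop("no enamel at or coronal to the CEJ slice", call. = FALSE)
  (cej_slice - min(sl)) * voxel_size_um / 1000
}

#' Full per-tooth morphometric analysis
#'
#' Runs the standard pipeline on a calibrated, oriented tooth volume: enamel /
#' dentin segmentation, CEJ and apical-enamel landmarks, crown and root ROIs,
#' interglobular dentin within the crown territory, filter-and-mask-back
#' cementum with its apical hollow-cylinder ROI, dentin zone subdivision, and
#' density / local-thickness / volume metrics.
#'
#' @param vol A [calibrated_volume()], already oriented (use [orient_volume()]
#'   first if not).
#' @param tooth_id Identifier copied into the output.
#' @param cementum_kernel Median kernel for cementum segmentation.
#' @param measure_root_dentin_thickness Include root dentin local thickness
#'   (the most expensive metric).
#' @return A long-format `data.frame` with columns `tooth`, `metric`, `value`.
#'   Metrics: `enamel_density`, `enamel_thickness_mm`, `crown_length_mm`,
#'   `crown_dentin_density`, `igd_volume_mm3`, `igd_fraction`,
#'   `mantle_density`, `circumpulpal_density`, `proximal_pulpal_density`,
#'   `root_dentin_thickness_mm` (optional), `cementum_density`,
#'   `cementum_thickness_mm`.
#' @export
analyze_tooth <- function(vol, tooth_id = "tooth", cementum_kernel = 11L,
                          measure_root_dentin_thickness = TRUE) {
  stopifnot(inherits(vol, "calibrated_volume"))
  vox <- vol$voxel_size_um
  d <- dim(vol$data)
  nz <- d[3]

  enamel <- segment_enamel(vol)
  dentin <- segment_dentin(vol)
  pulp <- pulp_cavity_mask(vol)
  # landmarks come from the despeckled enamel cap: at realistic noise a few
  # dentin voxels clear the enamel threshold and would fake an apical extension
  enamel_lm <- largest_component(enamel$mask)
  cej <- detect_cej(enamel_lm)
  ae <- detect_apical_enamel(enamel_lm)
  croi <- build_crown_roi(cej, vox, nz)
  rroi <- build_root_roi(ae, vox, nz)

  crown_z <- roi_slices(croi)
  igd <- segment_interglobular(vol, croi, dentin = dentin)
  igv <- interglobular_volume(igd$mask, igd$territory, vox)

  dentin_crown <- dentin$mask
  dentin_crown[, , -crown_z] <- FALSE
  enamel_crown <- enamel$mask
  enamel_crown[, , -crown_z] <- FALSE

  cem <- suppressWarnings(segment_cementum(vol, pulp = pulp,
                                           kernel = cementum_kernel,
                                           zrange = c(ae + 1L, nz)))
  cemroi <- tryCatch(build_cementum_roi(cem, vox), error = function(e) {
    warning("apical cementum not measurable: ", conditionMessage(e))
    NULL
  })
  cem_apical <- cem$mask
  if (is.null(cemroi)) cem_apical[] <- FALSE
  else cem_apical[, , -roi_slices(cemroi)] <- FALSE

  root_z <- roi_slices(rroi)
  # the density windows alone place cementum inside the dentin window, so the
  # zone subdivision works on dentin with the segmented cementum excluded
  dentin_root <- (dentin$mask & !cem$mask)[, , root_z, drop = FALSE]
  zones <- subdivide_dentin(dentin_root,
                            cem$mask[, , root_z, drop = FALSE],
                            pulp[, , root_z, drop = FALSE], vox)

  metrics <- c(
    enamel_density = mean_density(vol, enamel),
    enamel_thickness_mm = local_thickness(enamel_crown, vox)$mean_mm,
    crown_length_mm = crown_length(enamel_lm, cej, vox),
    crown_dentin_density = mean_density(vol, dentin_crown),
    igd_volume_mm3 = igv$volume_mm3,
    igd_fraction = igv$fraction,
    mantle_density = mean_density_sub(vol, zones$mantle, root_z),
    circumpulpal_density = mean_density_sub(vol, zones$circumpulpal, root_z),
    proximal_pulpal_density = mean_density_sub(vol, zones$proximal_pulpal, root_z),
    cementum_density = if (any(cem_apical)) mean_density(vol, cem_apical) else NA_real_,
    cementum_thickness_mm = if (any(cem_apical))
      local_thickness(crop_z(cem_apical, roi_slices(cemroi)), vox)$mean_mm
      else NA_real_)
  if (measure_root_dentin_thickness) {
    metrics <- c(metrics, root_dentin_thickness_mm =
      local_thickness(dentin_root, vox)$mean_mm)
  }
  data.frame(tooth = tooth_id, metric = names(metrics),
             value = unname(metrics), row.names = NULL)
}

# mean density over a zone mask given in ROI-cropped coordinates
mean_density_sub <- function(vol, zone_mask, zsel) {
  if (!any(zone_mask)) return(NA_real_)
  v <- vol_data(vol)[, , zsel, drop = FALSE]
  mean(v[zone_mask])
}

crop_z <- function(mask, zsel) vol_data(mask)[, , zsel, drop = FALSE]
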