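#' Estimate the tooth's long axis
#'
#' Principal axis (largest-variance eigenvector) of the mineralized voxel
#' cloud, taken as the root axis of a single-rooted tooth. The sign is chosen
#' so the axis points apically: the enamel centroid lies on the negative side.
#'
#' @param vol A [calibrated_volume()] or density array.
#' @param threshold Mineralized-tissue density threshold (mg/cm^3 HA).
#' @param enamel_threshold Enamel threshold used for the sign convention.
#' @param max_points Optional subsample cap for the eigen-decomposition;
#'   the default uses every mineralized voxel (subsampling breaks the exact
#'   symmetry of symmetric inputs).
#' @return Unit 3-vector in voxel coordinates.
#' @export
estimate_tooth_axis <- function(vol, threshold = 450, enamel_threshold = 1600,
                                max_points = Inf) {
  v <- vol_data(vol)
  idx <- which(v > threshold)
  if (length(idx) < 10L)
    stop("too few mineralized voxels to estimate an axis", call. = FALSE)
  if (length(idx) > max_points)
    idx <- idx[seq(1L, length(idx), length.out = max_points)]
  xyz <- arrayInd(idx, dim(v))
  cv <- stats::cov(xyz)
  ax <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  ax <- ax / sqrt(sum(ax^2))
  eidx <- which(v > enamel_threshold)
  ref <- if (length(eidx) >= 10L) {
    if (length(eidx) > max_points)
      eidx <- eidx[seq(1L, length(eidx), length.out = max_points)]
    colMeans(arrayInd(eidx, dim(v)))
  } else NULL
  ctr <- colMeans(xyz)
  if (!is.null(ref)) {
    if (sum((ref - ctr) * ax) > 0) ax <- -ax   # enamel (crown) on the -z side
  } else if (ax[3] < 0) ax <- -ax
  ax
}

# Minimal rotation taking unit vector a onto unit vector b (Rodrigues).
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (c_ < -1 + 1e-12) {  # antiparallel: rotate pi about any orthogonal axis
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- p - sum(p * a) * a
    v <- v / sqrt(sum(v^2))
    K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K / (1 + c_)
}

#' Orient a tooth volume along the axial convention
#'
#' Rigid rotation (about the volume centre, trilinear resampling, voxel size
#' unchanged) so that the root axis aligns with +z (slice index increasing
#' apically). With explicit landmarks, the mesial-distal CEJ chord is
#' additionally brought into an axial plane and aligned with the x axis; with
#' `landmarks = NULL` the axis is estimated by [estimate_tooth_axis()], which
#' is the automated surrogate for the manual midsagittal-slice orientation
#' step.
#'
#' @param vol A [calibrated_volume()].
#' @param landmarks Optional list with `mesial_cej_point` and
#'   `distal_cej_point` (voxel coordinates, length-3) and optionally
#'   `root_axis`.
#' @param threshold,enamel_threshold Passed to [estimate_tooth_axis()].
#' @param fill Grey value for samples falling outside the volume.
#' @return A `calibrated_volume` with attributes `rotation` (matrix applied)
#'   and `rotation_angle_deg`.
#' @export
orient_volume <- function(vol, landmarks = NULL, threshold = 450,
                          enamel_threshold = 1600, fill = 0) {
  stopifnot(inherits(vol, "calibrated_volume"))
  axis <- if (!is.null(landmarks) && !is.null(landmarks$root_axis)) {
    a <- landmarks$root_axis
    a / sqrt(sum(a^2))
  } else {
    estimate_tooth_axis(vol, threshold, enamel_threshold)
  }
  R <- rotation_between(axis, c(0, 0, 1))
  if (!is.null(landmarks) && !is.null(landmarks$mesial_cej_point) &&
      !is.null(landmarks$distal_cej_point)) {
    chord <- as.numeric(landmarks$distal_cej_point) -
             as.numeric(landmarks$mesial_cej_point)
    if (sqrt(sum(chord^2)) < .Machine$double.eps^0.5)
      stop("degenerate CEJ landmarks: mesial and distal points coincide",
           call. = FALSE)
    ch <- as.numeric(R %*% chord)
    if (sqrt(ch[1]^2 + ch[2]^2) < .Machine$double.eps^0.5)
      stop("degenerate CEJ landmarks: chord parallel to the root axis",
           call. = FALSE)
    th <- atan2(ch[2], ch[1])   # rotate about z so the chord lies along x
    Rz <- matrix(c(cos(-th), sin(-th), 0, -sin(-th), cos(-th), 0, 0, 0, 1), 3, 3)
    R <- Rz %*% R
  }
  d <- dim(vol$data)
  ctr <- (d - 1) / 2
  out <- if (max(abs(R - diag(3))) < 1e-9) {
    as.numeric(vol$data)  # identity rotation: skip the resampling exactly
  } else {
    cpp_affine_resample(as.numeric(vol$data), as.integer(d),
                        t(R), as.numeric(ctr), fill)
  }
  ang <- acos(min(1, max(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
  res <- calibrated_volume(array(out, dim = d), vol$voxel_size_um,
                           provenance = paste(vol$provenance, "[oriented]"))
  attr(res, "rotation") <- R
  attr(res, "rotation_angle_deg") <- ang
  res
}

#' Detect the cementum-enamel junction slice
#'
#' Scans axial slices from the root end toward the crown and returns the first
#' slice on which enamel forms a topologically complete ring. Ring
#' completeness is operationalized as the in-plane (4-connectivity) complement
#' of the enamel splitting into an enclosed interior plus the outside.
#'
#' @param enamel Enamel mask (logical array or `tissue_mask`).
#' @return The 1-based axial slice index of the CEJ.
#' @export
detect_cej <- function(enamel) {
  m <- vol_data(enamel)
  if (!any(m)) stop("enamel mask is empty", call. = FALSE)
  rings <- cpp_ring_slices(as.logical(m), dim3(m))
  hit <- which(rings)
  if (length(hit) == 0L)
    stop("no axial slice forms a complete enamel ring (crown missing or severely worn)",
         call. = FALSE)
  max(hit)
}

#' Detect the most apical extension of enamel
#'
#' @param enamel Enamel mask.
#' @return The last (most apical) axial slice index containing enamel.
#' @export
detect_apical_enamel <- function(enamel) {
  m <- vol_data(enamel)
  sl <- slices_with(m)
  if (length(sl) == 0L) stop("enamel mask is empty", call. = FALSE)
  max(sl)
}

new_roi <- function(label, from, to, voxel_size_um) {
  structure(list(label = label, slices = c(from, to),
                 n_slices = to - from + 1L, voxel_size_um = voxel_size_um),
            class = "tooth_roi")
}

#' @export
print.tooth_roi <- function(x, ...) {
  cat(sprintf("ROI '%s': axial slices %d..%d (%d slices, %.3g um voxels)\n",
              x$label, x$slices[1], x$slices[2], x$n_slices, x$voxel_size_um))
  invisible(x)
}

roi_slices <- function(roi) seq.int(roi$slices[1], roi$slices[2])

#' Crown dentin/enamel region of interest
#'
#' The `ceiling(500 / voxel)` axial slices (0.5 mm, i.e. 50 slices at 10 um)
#' extending coronally from (and including) the CEJ slice.
#'
#' @param cej_slice CEJ slice from [detect_cej()].
#' @param voxel_size_um Voxel size.
#' @param n_slices Total number of axial slices in the volume.
#' @param extent_um Coronal extent of the ROI (default 500 um).
#' @return A `tooth_roi` (1-based inclusive slice range).
#' @export
build_crown_roi <- function(cej_slice, voxel_size_um, n_slices,
                            extent_um = 500) {
  n <- ceiling(extent_um / voxel_size_um)
  from <- cej_slice - n + 1L
  if (from < 1L)
    stop(sprintf("insufficient coronal extent: ROI needs %d slices coronal of the CEJ but only %d exist (short by %d)",
                 n, cej_slice, 1L - from), call. = FALSE)
  if (cej_slice > n_slices)
    stop("cej_slice lies outside the volume", call. = FALSE)
  new_roi("crown_dentin", as.integer(from), as.integer(cej_slice),
          voxel_size_um)
}

#' Root dentin region of interest
#'
#' Skips `ceiling(150 / voxel)` slices apically from the most apical enamel
#' slice, then spans `ceiling(500 / voxel)` slices (150 um offset + 0.5 mm
#' extent).
#'
#' @param apical_enamel_slice Slice from [detect_apical_enamel()].
#' @param voxel_size_um Voxel size.
#' @param n_slices Total number of axial slices.
#' @param skip_um,extent_um Apical offset and ROI extent.
#' @return A `tooth_roi`.
#' @export
build_root_roi <- function(apical_enamel_slice, voxel_size_um, n_slices,
                           skip_um = 150, extent_um = 500) {
  skip <- ceiling(skip_um / voxel_size_um)
  n <- ceiling(extent_um / voxel_size_um)
  from <- apical_enamel_slice + skip + 1L
  to <- from + n - 1L
  if (to > n_slices)
    stop(sprintf("root too short (resorbed?): ROI needs slices %d..%d but the volume ends at %d",
                 from, to, n_slices), call. = FALSE)
  new_roi("root_dentin", as.integer(from), as.integer(to), voxel_size_um)
}

#' Apical acellular-cementum region of interest
#'
#' Starting from the most apical slice on which cementum forms a complete
#' (hollow-cylinder) ring and moving coronally, collects the consecutive run
#' of ring slices, clamped to at most `max_slices`; fewer than `min_slices`
#' qualifying slices is an error (insufficient root structure).
#'
#' @param cementum Cementum mask.
#' @param voxel_size_um Voxel size.
#' @param min_slices,max_slices Bounds on the ROI (default 25-50 slices).
#' @return A `tooth_roi` labelled `cementum_apical`.
#' @export
build_cementum_roi <- function(cementum, voxel_size_um,
                               min_slices = 25L, max_slices = 50L) {
  m <- vol_data(cementum)
  if (!any(m)) stop("cementum mask is empty", call. = FALSE)
  rings <- cpp_ring_slices(as.logical(m), dim3(m))
  hit <- which(rings)
  if (length(hit) == 0L)
    stop("no slice forms a complete cementum ring", call. = FALSE)
  last <- max(hit)
  run <- 1L
  while (last - run >= 1L && rings[last - run]) run <- run + 1L
  if (run < min_slices)
    stop(sprintf("only %d consecutive hollow-cylinder cementum slices (need >= %d): insufficient root structure",
                 run, min_slices), call. = FALSE)
  take <- min(run, max_slices)
  new_roi("cementum_apical", as.integer(last - take + 1L), as.integer(last),
          voxel_size_um)
}

#' Subdivide root dentin into mantle, circumpulpal and proximal pulpal zones
#'
#' Within a root ROI, mantle dentin is the outermost shell within `shell_um`
#' (default 150 um) Euclidean distance of the outer dentin surface (cementum
#' excluded, i.e. the surface toward cementum/background), proximal pulpal
#' dentin the innermost shell within `shell_um` of the pulp surface, and
#' circumpulpal dentin the remainder. Where a thin wall makes the shells
#' overlap, the mantle assignment wins and the overlap is flagged.
#'
#' Input masks are expected already cropped to the ROI slices; crop faces are
#' not treated as surfaces.
#'
#' @param dentin,cementum,pulp Logical arrays over the ROI (cementum may be
#'   `NULL` if absent).
#' @param voxel_size_um Voxel size.
#' @param shell_um Shell depth.
#' @return Object of class `dentin_zones`: masks `mantle`, `circumpulpal`,
#'   `proximal_pulpal`, plus `overlap` and `degenerate` flags.
#' @export
subdivide_dentin <- function(dentin, cementum = NULL, pulp,
                             voxel_size_um, shell_um = 150) {
  dn <- vol_data(dentin)
  if (!any(dn)) stop("dentin mask is empty in the ROI", call. = FALSE)
  pu <- if (is.null(pulp)) array(FALSE, dim(dn)) else vol_data(pulp)
  outer_surface <- !dn & !pu
  shell <- shell_um / voxel_size_um

  d_out2 <- feature_sqedt(outer_surface, outside_is_feature = FALSE)
  d_pulp2 <- if (any(pu)) feature_sqedt(pu, outside_is_feature = FALSE)
             else array(Inf, dim(dn))

  near_out <- d_out2 <= shell^2
  near_pulp <- d_pulp2 <= shell^2
  mantle <- dn & near_out
  proximal <- dn & near_pulp & !mantle
  circum <- dn & !mantle & !proximal
  overlap <- any(dn & near_out & near_pulp)
  degenerate <- !any(circum)
  if (degenerate)
    warning("dentin wall thinner than twice the shell depth: circumpulpal zone is empty")
  structure(list(mantle = mantle, circumpulpal = circum,
                 proximal_pulpal = proximal,
                 overlap = overlap, degenerate = degenerate,
                 shell_um = shell_um, voxel_size_um = voxel_size_um),
            class = "dentin_zones")
}

#' @export
print.dentin_zones <- function(x, ...) {
  cat(sprintf("Dentin zones (%g um shells): mantle %d, circumpulpal %d, proximal pulpal %d voxels\n",
              x$shell_um, sum(x$mantle), sum(x$circumpulpal),
              sum(x$proximal_pulpal)))
  if (x$overlap) cat("  note: shells overlapped (thin wall); mantle took precedence\n")
  invisible(x)
}

#' Pulp cavity mask
#'
#' Voxels below the soft-tissue threshold that are enclosed in-plane: on each
#' axial slice, sub-threshold components not reaching the slice border. This
#' captures the pulp chamber and canal (plus any enclosed hypomineralized
#' voids) while excluding the surrounding background air, and is robust to the
#' canal opening into the background at the apical foramen, which would fuse
#' pulp and background in a 3-D connectivity test.
#'
#' @param vol A [calibrated_volume()] or density array.
#' @param threshold Soft-tissue density threshold, mg/cm^3 HA.
#' @return Logical array.
#' @export
pulp_cavity_mask <- function(vol, threshold = 450) {
  v <- vol_data(vol)
  d <- dim3(v)
  cand <- v < threshold
  out <- array(FALSE, dim(v))
  for (z in seq_len(d[3])) {
    sl <- cand[, , z]
    if (!any(sl)) next
    comp <- label_components(sl)
    open_ <- boundary_labels(comp, "xy")
    out[, , z] <- sl & !(comp %in% open_)
  }
  out
}
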