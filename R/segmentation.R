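new_tissue_mask <- function(mask, tissue, lo, hi, filter = "none") {
  structure(list(mask = mask, tissue = tissue, lo = lo, hi = hi,
                 filter = filter),
            class = "tissue_mask")
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf("Tissue mask '%s': %d voxels; window (%s, %s] semantics: %s; filter: %s\n",
              x$tissue, sum(x$mask), format(x$lo), format(x$hi),
              attr(x, "semantics") %||% "", x$filter))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Segment enamel by density window
#'
#' Enamel is every voxel strictly above `threshold` mg/cm^3 HA (default 1600).
#'
#' @param vol A [calibrated_volume()].
#' @param threshold Lower bound, exclusive.
#' @return A `tissue_mask`.
#' @export
segment_enamel <- function(vol, threshold = 1600) {
  v <- vol_data(vol)
  m <- new_tissue_mask(v > threshold, "enamel", lo = threshold, hi = Inf)
  attr(m, "semantics") <- "density > lo (strict)"
  m
}

#' Segment dentin by density window
#'
#' Dentin is the closed window `[lo, hi]` mg/cm^3 HA (default 650-1600),
#' complementing the strict enamel bound so the two masks are disjoint.
#'
#' @param vol A [calibrated_volume()].
#' @param lo,hi Window bounds, inclusive.
#' @return A `tissue_mask`.
#' @export
segment_dentin <- function(vol, lo = 650, hi = 1600) {
  v <- vol_data(vol)
  m <- new_tissue_mask(v >= lo & v <= hi, "dentin", lo = lo, hi = hi)
  attr(m, "semantics") <- "lo <= density <= hi (closed)"
  m
}

#' Segment acellular cementum (filter-and-mask-back)
#'
#' The four-step procedure used for thin root cementum: (1) median-filter the
#' calibrated volume (kernel 11, volumetric by default); (2) threshold the
#' filtered volume at the closed cementum window (450-1050 mg/cm^3 HA);
#' (3) remove the pulp-adjacent highlight — the automated surrogate for
#' manually excluding softer dentin highlighted next to the pulp: candidate
#' voxels within `pulp_margin_um` of the pulp cavity are erased, and any
#' remaining candidate component still contacting the pulp is dropped (a
#' component-only rule fails at the apical foramen, where the filtered halo
#' around the canal touches the outer sheath and would drag it along);
#' (4) keep, of the surviving candidates, only voxels that are cementum with a
#' density over the mask-back threshold on the ORIGINAL unfiltered volume —
#' i.e. original density in `(650, 1050]`; the upper bound is the cementum
#' window's, without which the filtered transition band drags 1-2 voxels of
#' adjacent dentin (~1200) into thin sheaths. Downstream quantification uses
#' original-volume densities.
#'
#' @param vol A [calibrated_volume()].
#' @param pulp Optional pulp mask; computed by [pulp_cavity_mask()] if `NULL`.
#' @param kernel Median kernel size (voxels; odd).
#' @param filter_mode `"3d"` (11x11x11) or `"2d"` (11x11 per axial slice).
#' @param window Closed density window on the filtered volume.
#' @param maskback_threshold Strict lower bound on the original volume.
#' @param pulp_margin_um Width of the pulp-adjacent exclusion band.
#' @param zrange Optional axial slice range `c(from, to)` to restrict the
#'   (expensive) filtering to; the filter window is padded internally and the
#'   returned mask is empty outside the range.
#' @return A `tissue_mask` (full volume shape).
#' @export
segment_cementum <- function(vol, pulp = NULL, kernel = 11L,
                             filter_mode = c("3d", "2d"),
                             window = c(450, 1050), maskback_threshold = 650,
                             pulp_margin_um = 50, zrange = NULL) {
  filter_mode <- match.arg(filter_mode)
  if (kernel %% 2L != 1L) stop("median kernel must be odd", call. = FALSE)
  v <- vol_data(vol)
  d <- dim3(v)
  if (is.null(pulp)) pulp <- pulp_cavity_mask(vol)
  r <- (kernel - 1L) %/% 2L

  zr <- if (is.null(zrange)) c(1L, d[3]) else as.integer(zrange)
  zlo <- max(1L, zr[1] - r)
  zhi <- min(d[3], zr[2] + r)
  crop <- v[, , zlo:zhi, drop = FALSE]
  pulp_c <- pulp[, , zlo:zhi, drop = FALSE]

  rz <- if (filter_mode == "3d") r else 0L
  filt <- array(cpp_median_filter(as.numeric(crop), dim3(crop), r, r, rz),
                dim = dim(crop))
  cand <- filt >= window[1] & filt <= window[2]

  if (any(pulp_c) && pulp_margin_um > 0) {
    vox <- if (inherits(vol, "calibrated_volume")) vol$voxel_size_um else 1
    margin <- pulp_margin_um / vox
    pd2 <- feature_sqedt(pulp_c, outside_is_feature = FALSE)
    cand <- cand & pd2 > margin^2
  }
  comp <- label_components(cand)
  touching <- unique(comp[dilate6(pulp_c) & cand])
  touching <- setdiff(touching, 0L)
  if (length(touching)) cand <- cand & !(comp %in% touching)

  keep <- cand & (crop > maskback_threshold) & (crop <= window[2])

  full <- array(FALSE, dim = d)
  zsel <- zr[1]:zr[2]
  full[, , zsel] <- keep[, , (zsel - zlo + 1L), drop = FALSE]
  if (!any(full))
    warning("no cementum segmented: aplastic or hypoplastic cementum, or ROI mismatch")
  m <- new_tissue_mask(full, "cementum", lo = window[1], hi = window[2],
                       filter = sprintf("median-%d-%s + mask-back > %g",
                                        kernel, filter_mode,
                                        maskback_threshold))
  attr(m, "semantics") <- "closed window on filtered volume, mask-back strict on original"
  m
}

#' Crown dentin territory
#'
#' The filled dentin region within an axial slice range: internal cavities
#' (interglobular voids) are closed by 3-D hole filling of the full-volume
#' dentin mask before cropping, so voids bisected by the ROI faces still count.
#' The pulp cavity is never filled because it always communicates with the
#' exterior — through the apical foramen or through the volume boundary —
#' whereas interglobular voids are fully enclosed in dentin. The territory is
#' the denominator for interglobular dentin fractions.
#'
#' @param dentin Dentin mask (full volume).
#' @param zrange Axial slice range `c(from, to)`, e.g. from
#'   [build_crown_roi()].
#' @return Logical array over the full volume, nonzero only inside `zrange`.
#' @export
dentin_territory <- function(dentin, zrange) {
  dm <- vol_data(dentin)
  d <- dim3(dm)
  zsel <- zrange[1]:zrange[2]
  if (!any(dm[, , zsel])) stop("no dentin inside the ROI", call. = FALSE)
  filled <- fill_holes(dm)
  out <- array(FALSE, dim = d)
  out[, , zsel] <- filled[, , zsel]
  out
}

#' Segment interglobular dentin within a crown ROI
#'
#' Interglobular dentin is the hypomineralized volume inside the crown dentin
#' territory with density strictly below `threshold` (default 650 mg/cm^3 HA);
#' the pulp cavity is excluded by the territory construction.
#'
#' @param vol A [calibrated_volume()].
#' @param roi A `tooth_roi` from [build_crown_roi()] (or a length-2 slice
#'   range).
#' @param threshold Strict upper density bound.
#' @param dentin Optional precomputed dentin `tissue_mask`.
#' @return A list with `mask` (a `tissue_mask`) and `territory` (logical
#'   array).
#' @export
segment_interglobular <- function(vol, roi, threshold = 650, dentin = NULL) {
  v <- vol_data(vol)
  zr <- if (inherits(roi, "tooth_roi")) roi$slices else as.integer(roi)
  if (is.null(dentin)) dentin <- segment_dentin(vol)
  terr <- dentin_territory(dentin, zr)
  igd <- terr & (v < threshold)
  m <- new_tissue_mask(igd, "interglobular_dentin", lo = -Inf, hi = threshold)
  attr(m, "semantics") <- "density < hi (strict), within filled dentin territory"
  list(mask = m, territory = terr, zrange = zr)
}
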