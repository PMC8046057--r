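#' Construct a calibrated density volume
#'
#' A light container for a 3-D voxel array of mineral densities (mg/cm^3 HA)
#' with its voxel size and provenance. Slice 1 is the most coronal axial slice
#' once the volume is oriented; the z index increases apically.
#'
#' @param data Numeric 3-D array, mg/cm^3 HA.
#' @param voxel_size_um Isotropic voxel edge, micrometres.
#' @param provenance Free-text provenance (source file, calibration used).
#' @return An object of class `calibrated_volume`.
#' @export
calibrated_volume <- function(data, voxel_size_um, provenance = "") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3-D array", call. = FALSE)
  stopifnot_scalar(voxel_size_um, "voxel_size_um")
  if (voxel_size_um <= 0) stop("'voxel_size_um' must be > 0", call. = FALSE)
  if (!all(is.finite(data))) stop("density values must be finite", call. = FALSE)
  structure(list(data = data, voxel_size_um = voxel_size_um,
                 provenance = provenance),
            class = "calibrated_volume")
}

#' @export
print.calibrated_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Calibrated volume: %d x %d x %d voxels at %.3g um\n",
              d[1], d[2], d[3], x$voxel_size_um))
  cat(sprintf("  density range %.1f .. %.1f mg/cm^3 HA\n",
              min(x$data), max(x$data)))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
dim.calibrated_volume <- function(x) dim(x$data)

#' Fit a grey-value to mineral-density calibration
#'
#' Ordinary least-squares fit of the affine standard curve
#' `density = slope * grey + intercept` from the mean grey values of rods of
#' known hydroxyapatite density, as done against a scanner's multi-density HA
#' standard.
#'
#' @param rod_mean_greys Mean grey value per rod.
#' @param rod_densities Known rod densities, mg/cm^3 HA.
#' @return An object of class `calibration_curve` with `slope`, `intercept`,
#'   `r_squared` and the rod table.
#' @examples
#' fit_calibration(c(0, 1), c(0, 1))  # identity curve
#' @export
fit_calibration <- function(rod_mean_greys, rod_densities) {
  g <- as.numeric(rod_mean_greys)
  d <- as.numeric(rod_densities)
  if (length(g) != length(d))
    stop("rod grey and density vectors must have equal length", call. = FALSE)
  if (length(g) < 2L) stop("at least 2 rods are required", call. = FALSE)
  if (anyDuplicated(g) || sd(g) == 0)
    stop("degenerate fit: rod grey values are not distinct", call. = FALSE)
  fit <- lm(d ~ g)
  cf <- coef(fit)
  ss_tot <- sum((d - mean(d))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else 1
  structure(list(slope = unname(cf[2]), intercept = unname(cf[1]),
                 r_squared = r2,
                 rod_densities = d, rod_mean_greys = g),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("HA calibration curve: density = %.6g * grey + %.6g (r^2 = %.6f, %d rods)\n",
              x$slope, x$intercept, x$r_squared, length(x$rod_densities)))
  invisible(x)
}

#' Mean grey value per calibration rod
#'
#' @param volume Grey-value array (or `calibrated_volume`).
#' @param rod_masks List of logical arrays, one per rod.
#' @return Numeric vector of rod means.
#' @export
rod_mean_greys <- function(volume, rod_masks) {
  v <- vol_data(volume)
  vapply(rod_masks, function(m) mean(v[m]), numeric(1))
}

#' Apply a calibration curve to a raw grey-value volume
#'
#' Voxelwise affine transform to mg/cm^3 HA; shape is preserved.
#'
#' @param raw Numeric 3-D array of grey values.
#' @param curve A [fit_calibration()] result.
#' @param voxel_size_um Voxel size of the raw volume.
#' @param provenance Optional provenance string.
#' @return A [calibrated_volume()].
#' @export
apply_calibration <- function(raw, curve, voxel_size_um, provenance = "") {
  stopifnot(inherits(curve, "calibration_curve"))
  v <- vol_data(raw)
  calibrated_volume(curve$slope * v + curve$intercept, voxel_size_um,
                    provenance = paste0(provenance,
                                        sprintf(" [curve slope=%.6g intercept=%.6g]",
                                                curve$slope, curve$intercept)))
}

#' Write / read a calibration curve as JSON
#'
#' @param curve A `calibration_curve`.
#' @param path File path.
#' @return `read_calibration()` returns a `calibration_curve`;
#'   `write_calibration()` returns `path` invisibly.
#' @export
write_calibration <- function(curve, path) {
  stopifnot(inherits(curve, "calibration_curve"))
  jsonlite::write_json(unclass(curve), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared,
                 rod_densities = x$rod_densities,
                 rod_mean_greys = x$rod_mean_greys),
            class = "calibration_curve")
}
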