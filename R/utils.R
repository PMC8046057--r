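# Internal helpers shared across modules.

# Accept a calibrated_volume, tissue_mask or plain array and return the array.
vol_data <- function(x) {
  if (inherits(x, "calibrated_volume")) return(x$data)
  if (inherits(x, "tissue_mask")) return(x$mask)
  if (is.array(x)) return(x)
  stop("expected a calibrated_volume, tissue_mask or array", call. = FALSE)
}

vol_voxel_size <- function(x, voxel_size_um = NULL) {
  if (!is.null(voxel_size_um)) return(voxel_size_um)
  if (inherits(x, "calibrated_volume")) return(x$voxel_size_um)
  stop("voxel_size_um must be supplied when the input is a plain array",
       call. = FALSE)
}

dim3 <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("input has no dim attribute", call. = FALSE)
  if (length(d) == 2L) d <- c(d, 1L)
  if (length(d) != 3L) stop("expected a 2-D or 3-D array", call. = FALSE)
  as.integer(d)
}

# Run code with a private RNG stream, restoring the caller's .Random.seed.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Squared Euclidean distance (in voxels) to the nearest feature voxel.
feature_sqedt <- function(feature, outside_is_feature = FALSE) {
  d <- dim3(feature)
  out <- cpp_feature_sqedt(as.logical(feature), d, outside_is_feature)
  array(out, dim = dim(feature))
}

# Connected-component labels, 6-connectivity in 3-D / 4-connectivity in 2-D.
label_components <- function(mask) {
  d <- dim3(mask)
  array(cpp_label(as.logical(mask), d), dim = dim(mask))
}

# Labels of components touching the x/y side faces or any face of the array.
boundary_labels <- function(lab, faces = c("all", "xy")) {
  faces <- match.arg(faces)
  d <- dim3(lab)
  if (length(dim(lab)) == 2L) dim(lab) <- c(dim(lab), 1L)
  sel <- c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ])
  if (faces == "all" && d[3] > 1L) sel <- c(sel, lab[, , 1], lab[, , d[3]])
  if (faces == "all" && d[3] == 1L) sel <- c(sel, lab[, , 1])
  setdiff(unique(sel), 0L)
}

#' Largest connected component of a mask
#'
#' Keeps the largest 6-connected (4-connected in 2-D) component; the standard
#' despeckling step before landmark detection on noisy masks, where isolated
#' misclassified voxels would otherwise masquerade as anatomy.
#'
#' @param mask Logical array.
#' @return Logical array of the same shape.
#' @export
largest_component <- function(mask) {
  m <- vol_data(mask)
  comp <- label_components(m)
  if (max(comp) <= 1L) return(m)
  sizes <- tabulate(comp[comp > 0L])
  comp == which.max(sizes)
}

# Fill interior cavities: complement components not touching any array face.
fill_holes <- function(mask) {
  comp <- label_components(!mask)
  outside <- boundary_labels(comp, "all")
  mask | (comp != 0L & !(comp %in% outside))
}

# One-voxel 6-connected dilation, done with array shifts.
dilate6 <- function(mask) {
  d <- dim3(mask)
  if (length(dim(mask)) == 2L) dim(mask) <- c(dim(mask), 1L)
  out <- mask
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  out[-nx, , ] <- out[-nx, , ] | mask[-1, , ]
  out[-1, , ]  <- out[-1, , ]  | mask[-nx, , ]
  out[, -ny, ] <- out[, -ny, ] | mask[, -1, ]
  out[, -1, ]  <- out[, -1, ]  | mask[, -ny, ]
  if (nz > 1L) {
    out[, , -nz] <- out[, , -nz] | mask[, , -1]
    out[, , -1]  <- out[, , -1]  | mask[, , -nz]
  }
  if (d[3] == 1L) dim(out) <- d[1:2]
  out
}

slices_with <- function(mask) {
  d <- dim3(mask)
  if (length(dim(mask)) == 2L) dim(mask) <- c(dim(mask), 1L)
  which(apply(mask, 3, any))
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
}
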