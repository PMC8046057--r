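# Minimal uncompressed NIfTI-1 (.nii) reader/writer. No R package in this
# toolchain provides NIfTI I/O, so the single-file format is written directly:
# 348-byte header + 4-byte extension flag, little-endian, data at offset 352.
# Orientation metadata (qform/sform) is left unset; the axial-slice convention
# is documented in the package vignette.

#' Write a voxel volume as NIfTI-1
#'
#' @param x A 3-D numeric array or a [calibrated_volume()].
#' @param path Output path (conventionally `.nii`).
#' @param voxel_size_um Voxel size; taken from a `calibrated_volume` input when
#'   omitted.
#' @param datatype `"float32"`, `"float64"`, `"int16"` or `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, voxel_size_um = NULL,
                        datatype = c("float32", "float64", "int16", "uint8")) {
  datatype <- match.arg(datatype)
  vox <- vol_voxel_size(x, voxel_size_um)
  v <- vol_data(x)
  if (is.logical(v)) v <- array(as.integer(v), dim = dim(v))
  d <- dim3(v)
  dt <- switch(datatype,
               uint8 = list(code = 2L, bitpix = 8L, size = 1L, what = "integer"),
               int16 = list(code = 4L, bitpix = 16L, size = 2L, what = "integer"),
               float32 = list(code = 16L, bitpix = 32L, size = 4L, what = "double"),
               float64 = list(code = 64L, bitpix = 64L, size = 8L, what = "double"))
  con <- file(path, "wb")
  on.exit(close(con))
  w_i <- function(x, size = 4L) writeBin(as.integer(x), con, size = size,
                                         endian = "little")
  w_f <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i(348L)                                   # sizeof_hdr
  w_raw(36L)                                  # data_type, db_name, extents, ...
  w_i(c(3L, d, 1L, 1L, 1L, 1L), size = 2L)    # dim[8]
  w_f(c(0, 0, 0))                             # intent_p1..p3
  w_i(0L, size = 2L)                          # intent_code
  w_i(dt$code, size = 2L)                     # datatype
  w_i(dt$bitpix, size = 2L)                   # bitpix
  w_i(0L, size = 2L)                          # slice_start
  w_f(c(1, rep(vox / 1000, 3), 1, 1, 1, 1))   # pixdim[8], mm
  w_f(352)                                    # vox_offset
  w_f(c(1, 0))                                # scl_slope, scl_inter
  w_i(0L, size = 2L)                          # slice_end
  w_raw(2L)                                   # slice_code, xyzt_units
  w_f(c(0, 0, 0, 0))                          # cal_max, cal_min, slice_duration, toffset
  w_i(c(0L, 0L))                              # glmax, glmin
  desc <- charToRaw(substr("dentomorph volume", 1, 79))
  w_raw_pad <- function(r, n) writeBin(c(r, raw(n - length(r))), con)
  w_raw_pad(desc, 80L)                        # descrip
  w_raw(24L)                                  # aux_file
  w_i(c(0L, 0L), size = 2L)                   # qform_code, sform_code
  w_f(rep(0, 6))                              # quatern b,c,d + offset x,y,z
  w_f(rep(0, 12))                             # srow_x/y/z
  w_raw(16L)                                  # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  w_raw(4L)                                   # extension flag

  vals <- as.vector(v)
  if (dt$what == "integer")
    writeBin(as.integer(round(vals)), con, size = dt$size, endian = "little")
  else
    writeBin(as.numeric(vals), con, size = dt$size, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Supports uncompressed single-file `.nii` with datatypes uint8, int16,
#' int32, float32 or float64.
#'
#' @param path File path.
#' @return A list with `data` (3-D array), `voxel_size_um`, and `datatype`.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  r_i <- function(n, size = 4L) readBin(con, "integer", n = n, size = size,
                                        endian = "little")
  r_f <- function(n, size = 4L) readBin(con, "double", n = n, size = size,
                                        endian = "little")
  sizeof <- r_i(1)
  if (!identical(sizeof, 348L))
    stop("not a little-endian NIfTI-1 file: ", path, call. = FALSE)
  invisible(readBin(con, "raw", n = 36))
  dims <- r_i(8, size = 2L)
  nd <- dims[1]
  d <- dims[2:(1 + max(nd, 3))]
  d <- d[d > 0]
  if (length(d) < 3L) d <- c(d, rep(1L, 3L - length(d)))
  r_f(3)                     # intent params
  r_i(1, size = 2L)          # intent_code
  datatype <- r_i(1, size = 2L)
  r_i(1, size = 2L)          # bitpix
  r_i(1, size = 2L)          # slice_start
  pixdim <- r_f(8)
  vox_offset <- r_f(1)
  scl <- r_f(2)
  n <- prod(d[1:3])
  seek(con, where = vox_offset, origin = "start")
  vals <- switch(as.character(datatype),
                 "2" = as.numeric(readBin(con, "integer", n = n, size = 1L,
                                          signed = FALSE, endian = "little")),
                 "4" = as.numeric(readBin(con, "integer", n = n, size = 2L,
                                          endian = "little")),
                 "8" = as.numeric(readBin(con, "integer", n = n, size = 4L,
                                          endian = "little")),
                 "16" = readBin(con, "double", n = n, size = 4L,
                                endian = "little"),
                 "64" = readBin(con, "double", n = n, size = 8L,
                                endian = "little"),
                 stop("unsupported NIfTI datatype code: ", datatype,
                      call. = FALSE))
  if (scl[1] != 0 && !(scl[1] == 1 && scl[2] == 0))
    vals <- scl[1] * vals + scl[2]
  list(data = array(vals, dim = d[1:3]),
       voxel_size_um = pixdim[2] * 1000,
       datatype = datatype)
}

#' Export a tooth phantom to disk
#'
#' Writes the grey-value volume and the ground-truth label volume as NIfTI-1,
#' plus a JSON sidecar with the scalar ground truth and the generating
#' specification.
#'
#' @param phantom A [generate_tooth_phantom()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_tooth_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "tooth_phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vox <- phantom$truth$voxel_size_um
  write_nifti(phantom$volume, file.path(dir, "volume.nii"), vox, "float32")
  write_nifti(phantom$truth$label, file.path(dir, "labels.nii"), vox, "uint8")
  side <- phantom$truth[setdiff(names(phantom$truth), "label")]
  side$spec <- unclass(phantom$spec)
  jsonlite::write_json(side, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
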