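#' Minimal NIfTI-1 volume writer
#'
#' Writes a 3D or 4D numeric array as an uncompressed single-file NIfTI-1
#' (.nii) volume, float32, with a diagonal sform carrying the voxel size.
#' This is a deliberately small implementation covering exactly what the
#' dosimetry pipeline emits (parametric, TIA, dose and BED maps and dynamic
#' studies); it is not a general NIfTI library.
#'
#' @param arr 3D or 4D numeric array.
#' @param path output path ending in `.nii`.
#' @param voxel_mm voxel size, mm (length 3).
#' @param t_step time step for the 4th dimension (seconds), default 1.
#' @return invisibly, `path`.
#' @export
write_nifti <- function(arr, path, voxel_mm = c(1, 1, 1), t_step = 1) {
  dims <- dim(arr)
  if (is.null(dims) || !length(dims) %in% c(3, 4))
    stop("expected a 3D or 4D array")
  con <- file(path, "wb")
  on.exit(close(con))
  ndim <- length(dims)
  dim_field <- rep(1L, 8); dim_field[1] <- ndim
  dim_field[2:(1 + ndim)] <- as.integer(dims)
  pixdim <- rep(0, 8)
  pixdim[1] <- 1                       # qfac
  pixdim[2:4] <- voxel_mm
  if (ndim == 4) pixdim[5] <- t_step

  writeBin(348L, con, size = 4)                       # sizeof_hdr
  writeBin(raw(36), con)                              # unused legacy fields
  writeBin(dim_field, con, size = 2)                  # dim[8]
  writeBin(raw(14), con)                              # intent_p1..intent_code
  writeBin(16L, con, size = 2)                        # datatype = float32
  writeBin(32L, con, size = 2)                        # bitpix
  writeBin(0L, con, size = 2)                         # slice_start
  writeBin(pixdim, con, size = 4)                     # pixdim[8]
  writeBin(352, con, size = 4)                        # vox_offset (float!)
  writeBin(c(1, 0), con, size = 4)                    # scl_slope, scl_inter
  writeBin(0L, con, size = 2)                         # slice_end
  writeBin(as.integer(c(0, 10)), con, size = 1)       # slice_code; units mm|sec
  writeBin(rep(0, 4), con, size = 4)                  # cal_max..toffset
  writeBin(c(0L, 0L), con, size = 4)                  # glmax, glmin
  desc <- charToRaw("trtdose minimal NIfTI-1 writer")
  writeBin(c(desc, raw(80 - length(desc))), con)      # descrip[80]
  writeBin(raw(24), con)                              # aux_file[24]
  writeBin(c(0L, 1L), con, size = 2)                  # qform=0, sform=1
  writeBin(rep(0, 6), con, size = 4)                  # quaternions
  writeBin(c(voxel_mm[1], 0, 0, 0), con, size = 4)    # srow_x
  writeBin(c(0, voxel_mm[2], 0, 0), con, size = 4)    # srow_y
  writeBin(c(0, 0, voxel_mm[3], 0), con, size = 4)    # srow_z
  writeBin(raw(16), con)                              # intent_name[16]
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)       # magic
  writeBin(raw(4), con)                               # extension flag
  vals <- as.numeric(arr)
  vals[!is.finite(vals)] <- NaN
  writeBin(vals, con, size = 4)
  invisible(path)
}

#' Minimal NIfTI-1 volume reader
#'
#' Reads volumes written by [write_nifti()] (single-file, float32 or a few
#' other common scalar types, no compression, native endianness).
#'
#' @param path a `.nii` file.
#' @return list with `data` (array) and `voxel_mm`.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_size <- readBin(con, "integer", 1, size = 4)
  if (hdr_size != 348) stop("not a native-endian NIfTI-1 file")
  invisible(readBin(con, "raw", 36))
  dim_field <- readBin(con, "integer", 8, size = 2)
  invisible(readBin(con, "raw", 14))
  datatype <- readBin(con, "integer", 1, size = 2)
  invisible(readBin(con, "integer", 1, size = 2))      # bitpix
  invisible(readBin(con, "integer", 1, size = 2))      # slice_start
  pixdim <- readBin(con, "numeric", 8, size = 4)
  vox_offset <- readBin(con, "numeric", 1, size = 4)
  ndim <- dim_field[1]
  dims <- dim_field[2:(1 + ndim)]
  n <- prod(dims)
  seek(con, where = vox_offset, origin = "start")
  data <- switch(as.character(datatype),
    "16" = readBin(con, "numeric", n, size = 4),
    "64" = readBin(con, "numeric", n, size = 8),
    "8"  = readBin(con, "integer", n, size = 4),
    "4"  = readBin(con, "integer", n, size = 2),
    stop("unsupported NIfTI datatype ", datatype))
  list(data = array(data, dim = dims), voxel_mm = pixdim[2:4])
}
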