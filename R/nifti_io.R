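# Minimal NIfTI-1 I/O.
#
# No NIfTI package is available in the target environment, so this implements
# the single-file (.nii / .nii.gz) NIfTI-1 layout directly: 348-byte header,
# data at vox_offset. The writer emits float64 little-endian with an sform
# affine (code 1); the reader handles the common datatypes, either endianness,
# scl_slope/scl_inter scaling, and 3D or 4D images. Round-trips are checked
# against nibabel in the test suite.

NIFTI_DT <- list(`2` = list(what = "integer", size = 1, signed = FALSE),
                 `4` = list(what = "integer", size = 2, signed = TRUE),
                 `8` = list(what = "integer", size = 4, signed = TRUE),
                 `16` = list(what = "numeric", size = 4, signed = TRUE),
                 `64` = list(what = "numeric", size = 8, signed = TRUE),
                 `256` = list(what = "integer", size = 1, signed = TRUE),
                 `512` = list(what = "integer", size = 2, signed = FALSE))

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read a NIfTI-1 volume
#'
#' Reads a 3D map or a 4D subject stack together with its grid geometry.
#'
#' @param path Path to a `.nii` or `.nii.gz` NIfTI-1 file.
#' @param mask Optional logical array to attach as the grid mask (default:
#'   all voxels).
#' @return A list with `data` (3D or 4D numeric array) and `grid`
#'   (a [volume_grid()] built from the header; for 4D input the grid describes
#'   one 3D frame).
#' @export
read_volume <- function(path, mask = NULL) {
  if (!file.exists(path)) {
    stop_invalid("cannot read NIfTI file '%s': no such file", path)
  }
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) {
    stop_invalid("'%s' is not a NIfTI-1 file (truncated header)", path)
  }
  endian <- "little"
  sizeof_hdr <- readBin(hdr[1:4], "integer", size = 4, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr[1:4], "integer", size = 4, endian = endian)
    if (sizeof_hdr != 348L) {
      stop_invalid("'%s' is not a NIfTI-1 file (bad sizeof_hdr)", path)
    }
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) {
    stop_invalid("'%s' is not a NIfTI-1 file (bad magic '%s')", path, magic)
  }
  int16 <- function(off, n) {
    readBin(hdr[(off + 1):(off + 2 * n)], "integer", n = n, size = 2,
            endian = endian)
  }
  flt32 <- function(off, n) {
    readBin(hdr[(off + 1):(off + 4 * n)], "numeric", n = n, size = 4,
            endian = endian)
  }
  dims <- int16(40, 8)
  ndim <- dims[1]
  if (!ndim %in% c(3L, 4L)) {
    stop_invalid("'%s': only 3D/4D images supported (dim[0] = %d)", path, ndim)
  }
  shape <- dims[2:(1 + ndim)]
  datatype <- int16(70, 1)
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) {
    stop_invalid("'%s': unsupported NIfTI datatype %d", path, datatype)
  }
  pixdim <- flt32(76, 8)
  vox_offset <- flt32(108, 1)
  scl_slope <- flt32(112, 1)
  scl_inter <- flt32(116, 1)
  sform_code <- int16(254, 1)
  srow <- rbind(flt32(280, 4), flt32(296, 4), flt32(312, 4))

  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  n_values <- prod(shape)
  data <- readBin(con, dt$what, n = n_values, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(data) < n_values) {
    stop_invalid("'%s': truncated data section", path)
  }
  data <- as.numeric(data)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    data <- data * scl_slope + scl_inter
  }
  data <- array(data, dim = shape)

  voxel_size <- abs(pixdim[2:4])
  if (sform_code > 0) {
    affine <- rbind(srow, c(0, 0, 0, 1))
  } else {
    affine <- diag(c(voxel_size, 1))
  }
  grid <- volume_grid(shape[1:3], voxel_size = voxel_size, affine = affine,
                      mask = mask)
  list(data = data, grid = grid)
}

#' Write a NIfTI-1 volume
#'
#' Writes a 3D map or 4D subject stack as float64 NIfTI-1 with the grid's
#' affine stored as the sform.
#'
#' @param data 3D numeric array matching `grid$shape`, or 4D array whose
#'   first three dimensions match.
#' @param grid A [volume_grid()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, grid, path) {
  data <- as.array(data)
  nd <- length(dim(data))
  if (!nd %in% c(3L, 4L)) {
    stop_invalid("`data` must be a 3D or 4D array")
  }
  if (!identical(dim(data)[1:3], grid$shape)) {
    stop_invalid("data shape %s does not match grid shape %s for '%s'",
                 paste(dim(data)[1:3], collapse = "x"),
                 paste(grid$shape, collapse = "x"), path)
  }
  dims <- integer(8)
  dims[1] <- nd
  dims[2:(1 + nd)] <- dim(data)
  dims[(2 + nd):8] <- 1L
  pixdim <- numeric(8)
  pixdim[1] <- 1
  pixdim[2:4] <- grid$voxel_size
  pixdim[5:8] <- c(1, 0, 0, 0)

  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(348L, 4)                                  # sizeof_hdr
  writeBin(raw(36), con)                       # data_type..dim_info
  wi(dims, 2)                                  # dim[8]
  writeBin(raw(14), con)                       # intent_p1..intent_code
  wi(64L, 2)                                   # datatype = float64
  wi(64L, 2)                                   # bitpix
  wi(0L, 2)                                    # slice_start
  wf(pixdim)                                   # pixdim[8]
  wf(352)                                      # vox_offset
  wf(1)                                        # scl_slope
  wf(0)                                        # scl_inter
  writeBin(raw(8), con)                        # slice_end..cal_max (start)
  wf(0)                                        # cal_min
  wf(0)                                        # slice_duration
  wf(0)                                        # toffset
  wi(c(0L, 0L), 4)                             # glmax, glmin
  writeBin(raw(104), con)                      # descrip + aux_file
  wi(0L, 2)                                    # qform_code
  wi(1L, 2)                                    # sform_code
  wf(numeric(6))                               # quatern b,c,d + qoffset x,y,z
  wf(grid$affine[1, ])                         # srow_x
  wf(grid$affine[2, ])                         # srow_y
  wf(grid$affine[3, ])                         # srow_z
  writeBin(raw(16), con)                       # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)   # magic
  writeBin(raw(4), con)                        # extension flag
  writeBin(as.numeric(data), con, size = 8, endian = "little")
  invisible(path)
}
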