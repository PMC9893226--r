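# Minimal NIfTI-1 single-file (.nii) reader/writer for volume_grid objects.
# Only the subset the lesion module needs is supported: 3-D volumes,
# float32 or uint8 data, sform affine, little-endian, no compression.
# (No NIfTI package ships with the analysis environment, so the package
# carries its own narrow implementation of the container format.)

#' Write a volume grid to a NIfTI-1 file
#'
#' Binary grids are stored as uint8, probability grids as float32. The affine
#' is stored in the sform rows (`sform_code = 1`).
#'
#' @param grid a [volume_grid()].
#' @param path output path (`.nii`, uncompressed).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(grid, path) {
  stopifnot(inherits(grid, "volume_grid"))
  uint8 <- grid$kind == "binary"
  dims <- dim(grid$data)

  hdr <- raw(348)
  put <- function(at, values, what, size) {
    bytes <- writeBin(values, raw(), size = size, endian = "little")
    hdr[(at + 1):(at + length(bytes))] <<- bytes
  }
  put(0, 348L, "integer", 4)                                   # sizeof_hdr
  put(40, as.integer(c(3L, dims, 1L, 1L, 1L, 1L)), "integer", 2) # dim[8]
  put(70, if (uint8) 2L else 16L, "integer", 2)                # datatype
  put(72, if (uint8) 8L else 32L, "integer", 2)                # bitpix
  put(76, c(1, grid$voxel_dims, 1, 1, 1, 1), "numeric", 4)     # pixdim[8]
  put(108, 352, "numeric", 4)                                  # vox_offset
  put(112, 1, "numeric", 4)                                    # scl_slope
  desc <- charToRaw(sprintf("speechlesion %s grid", grid$kind))
  hdr[149:(148 + length(desc))] <- desc                        # descrip
  put(254, 1L, "integer", 2)                                   # sform_code
  put(280, as.numeric(t(grid$affine[1:3, ])), "numeric", 4)    # srow_x/y/z
  hdr[345:348] <- c(charToRaw("n+1"), as.raw(0))               # magic

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4), con)                                        # extensions
  if (uint8) {
    writeBin(as.integer(grid$data), con, size = 1)
  } else {
    writeBin(as.numeric(grid$data), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 file written by [write_nifti()]
#'
#' Supports little-endian, uncompressed, 3-D uint8/float32 single-file NIfTI
#' with an sform affine.
#'
#' @param path file path.
#' @param kind grid kind to assign (`"probability"` or `"binary"`); defaults
#'   to binary for uint8 data, probability otherwise.
#' @return a [volume_grid()].
#' @export
read_nifti <- function(path, kind = NULL) {
  bytes <- readBin(path, "raw", file.size(path))
  take <- function(at, n, what, size, signed = TRUE) {
    readBin(bytes[(at + 1):(at + n * size)], what, n, size = size,
            signed = signed, endian = "little")
  }
  if (!identical(take(0, 1, "integer", 4), 348L)) {
    stop("not a little-endian NIfTI-1 file: ", path, call. = FALSE)
  }
  dims <- take(40, 8, "integer", 2)
  if (dims[1] != 3L) stop("only 3-D NIfTI volumes are supported", call. = FALSE)
  shape <- dims[2:4]
  datatype <- take(70, 1, "integer", 2)
  pixdim <- take(76, 8, "numeric", 4)
  vox_offset <- take(108, 1, "numeric", 4)
  srow <- matrix(take(280, 12, "numeric", 4), nrow = 3, byrow = TRUE)
  affine <- rbind(srow, c(0, 0, 0, 1))
  n <- prod(shape)
  vals <- switch(as.character(datatype),
    "2" = as.numeric(take(vox_offset, n, "integer", 1, signed = FALSE)),
    "16" = take(vox_offset, n, "numeric", 4),
    stop("unsupported NIfTI datatype: ", datatype, call. = FALSE)
  )
  if (is.null(kind)) kind <- if (datatype == 2L) "binary" else "probability"
  volume_grid(array(vals, dim = shape), pixdim[2:4], affine, kind = kind)
}
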