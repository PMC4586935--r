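# Minimal single-file NIfTI-1 support. Only what the pipeline needs: 3D/4D
# volumes, float/int datatypes, sform affine. Written little-endian; reads
# either endianness.

nifti_datatypes <- list(`2` = list(what = "integer", size = 1, signed = FALSE),
                        `4` = list(what = "integer", size = 2, signed = TRUE),
                        `8` = list(what = "integer", size = 4, signed = TRUE),
                        `16` = list(what = "numeric", size = 4, signed = TRUE),
                        `64` = list(what = "numeric", size = 8, signed = TRUE))

#' Write a volume as NIfTI-1
#'
#' Writes a 3D or 4D array as a single-file little-endian NIfTI-1 image
#' (float32 by default, uint8 for logical input) with the affine stored in
#' the sform (code 2).
#'
#' @param data 3D or 4D numeric/logical array. NA values are written as 0.
#' @param path Output path (conventionally `.nii`).
#' @param affine 4x4 voxel-to-world matrix (0-based voxel indices).
#' @param datatype NIfTI datatype code: 16 (float32, default), 64
#'   (float64), 2 (uint8), 4 (int16), 8 (int32).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, affine = diag(4), datatype = NULL) {
  dims <- dim(data)
  if (is.null(dims) || !(length(dims) %in% c(3L, 4L)))
    stop("data must be a 3D or 4D array")
  if (is.logical(data)) {
    data <- array(as.integer(data), dims)
    if (is.null(datatype)) datatype <- 2L
  }
  if (is.null(datatype)) datatype <- 16L
  dt <- nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported datatype code: ", datatype)
  stopifnot(all(dim(affine) == c(4, 4)))
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wc <- function(n) writeBin(raw(n), con)
  wi(348L, 4)                                   # sizeof_hdr
  wc(36)                                        # data_type..regular, dim_info
  wi(c(length(dims), dims, rep(1L, 7 - length(dims))), 2)   # dim[8]
  wf(c(0, 0, 0))                                # intent_p1..p3
  wi(0L, 2)                                     # intent_code
  wi(datatype, 2)                               # datatype
  wi(dt$size * 8L, 2)                           # bitpix
  wi(0L, 2)                                     # slice_start
  wf(c(1, vs, rep(1, 4 - length(vs)), 0, 0, 0, 0)[1:8])     # pixdim[8]
  wf(352)                                       # vox_offset
  wf(1); wf(0)                                  # scl_slope, scl_inter
  wi(0L, 2); wc(2)                              # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0))                             # cal_max/min, slice_duration, toffset
  wi(c(0L, 0L), 4)                              # glmax, glmin
  wc(104)                                       # descrip, aux_file
  wi(0L, 2); wi(2L, 2)                          # qform_code, sform_code
  wf(rep(0, 6))                                 # quaternions, qoffsets
  wf(affine[1, ]); wf(affine[2, ]); wf(affine[3, ])         # srow_x/y/z
  wc(16)                                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con) # magic
  wc(4)                                         # extension flag
  vals <- as.vector(data)
  vals[is.na(vals)] <- 0
  if (dt$what == "integer")
    writeBin(as.integer(round(vals)), con, size = dt$size, endian = "little")
  else writeBin(as.numeric(vals), con, size = dt$size, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path Path to a single-file (`.nii`) NIfTI-1 image.
#' @return List with `data` (array), `affine` (4x4; sform if present, else
#'   diagonal from pixdim), `dims`, `datatype`.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sz <- readBin(con, "integer", 1, size = 4, endian = "little")
  endian <- "little"
  if (sz != 348L) {                      # try the other byte order
    seek(con, 0)
    sz <- readBin(con, "integer", 1, size = 4, endian = "big")
    endian <- "big"
  }
  seek(con, 0)
  rd_i <- function(n, size) readBin(con, "integer", n, size = size, endian = endian)
  rd_f <- function(n, size = 4) readBin(con, "numeric", n, size = size, endian = endian)
  sz <- rd_i(1, 4)
  if (sz != 348L) stop("malformed NIfTI header in ", path, " (sizeof_hdr != 348)")
  invisible(readBin(con, "raw", 36))
  dim8 <- rd_i(8, 2)
  ndim <- dim8[1]
  if (ndim < 3 || ndim > 4) stop("only 3D/4D images are supported: ", path)
  dims <- dim8[2:(1 + ndim)]
  rd_f(3)                                       # intent_p
  rd_i(1, 2)                                    # intent_code
  datatype <- rd_i(1, 2)
  dt <- nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported datatype code ", datatype, " in ", path)
  rd_i(1, 2); rd_i(1, 2)                        # bitpix, slice_start
  pixdim <- rd_f(8)
  vox_offset <- rd_f(1)
  scl_slope <- rd_f(1); scl_inter <- rd_f(1)
  rd_i(1, 2); invisible(readBin(con, "raw", 2)) # slice_end/code/units
  rd_f(4); rd_i(2, 4)                           # cal/slice_duration/toffset, glmax/min
  invisible(readBin(con, "raw", 104))           # descrip, aux_file
  rd_i(1, 2)                                    # qform_code
  sform_code <- rd_i(1, 2)
  rd_f(6)                                       # quaternions/qoffsets
  srow <- rbind(rd_f(4), rd_f(4), rd_f(4))
  invisible(readBin(con, "raw", 16))            # intent_name
  magic <- rawToChar(readBin(con, "raw", 4)[1:3])
  if (magic != "n+1") stop("malformed NIfTI magic in ", path)
  seek(con, vox_offset)
  n <- prod(dims)
  vals <- readBin(con, dt$what, n, size = dt$size, endian = endian,
                  signed = dt$signed)
  if (length(vals) != n) stop("truncated NIfTI data in ", path)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  affine <- if (sform_code > 0) rbind(srow, c(0, 0, 0, 1))
            else diag(c(pixdim[2:4], 1))
  list(data = array(vals, dims), affine = affine, dims = dims,
       datatype = datatype)
}

#' Read multiple volumes, enforcing a common grid and affine
#'
#' @param paths Character vector of NIfTI paths.
#' @return List of [read_nifti()] results.
#' @export
read_volumes <- function(paths) {
  vols <- lapply(paths, read_nifti)
  for (i in seq_along(vols)[-1]) {
    if (!isTRUE(all.equal(vols[[1]]$affine, vols[[i]]$affine,
                          tolerance = 1e-5)) ||
        !identical(vols[[1]]$dims[1:3], vols[[i]]$dims[1:3]))
      stop("affine/grid mismatch between ", paths[1], " and ", paths[i])
  }
  vols
}

#' Write a JSON sidecar
#'
#' @param x List of metadata.
#' @param path Path of the data file (`.json` is substituted/appended).
#' @return Sidecar path, invisibly.
#' @export
write_sidecar <- function(x, path) {
  sidecar <- sub("\\.nii$", ".json", path)
  if (!grepl("\\.json$", sidecar)) sidecar <- paste0(sidecar, ".json")
  jsonlite::write_json(x, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(sidecar)
}
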