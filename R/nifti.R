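#' Minimal NIfTI-1 volume I/O
#'
#' A small single-file NIfTI-1 reader/writer (uncompressed `.nii`,
#' little-endian, datatypes uint8 / int16 / int32 / float32 / float64)
#' sufficient for round-tripping phantoms and masks with correct spacing
#' metadata. Arrays are handled in this package's (slice, row, col) layout
#' and stored on disk in conventional (row, col, slice) axis order with
#' pixdim = (in-plane, in-plane, slice spacing).
#'
#' @param img 3-D array (slice, row, col)
#' @param path output path (`.nii`)
#' @param in_plane_spacing,slice_spacing voxel geometry, mm
#' @param datatype one of `"uint8"`, `"int16"`, `"int32"`, `"float32"`,
#'   `"float64"`
#' @return `write_nifti` returns `path` invisibly; `read_nifti` returns a
#'   list with `img` (slice, row, col), `in_plane_spacing`, `slice_spacing`
#' @export
write_nifti <- function(img, path, in_plane_spacing = 1, slice_spacing = 1,
                        datatype = "int16") {
  stopifnot(is.array(img), length(dim(img)) == 3L)
  dt <- switch(datatype,
               uint8 = list(code = 2L, bits = 8L, what = "integer", size = 1L),
               int16 = list(code = 4L, bits = 16L, what = "integer", size = 2L),
               int32 = list(code = 8L, bits = 32L, what = "integer", size = 4L),
               float32 = list(code = 16L, bits = 32L, what = "double", size = 4L),
               float64 = list(code = 64L, bits = 64L, what = "double", size = 8L),
               stopf("unsupported datatype '%s'", datatype))
  arr <- aperm(img, c(2, 3, 1)) # (row, col, slice)
  d <- dim(arr)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(348L, 4)                                    # sizeof_hdr
  writeBin(raw(35), con)                         # data_type, db_name, extents, session_error, regular
  writeBin(as.raw(0L), con)                      # dim_info
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2)                # dim[8]
  wf(c(0, 0, 0))                                 # intent_p1..p3
  wi(0L, 2)                                      # intent_code
  wi(dt$code, 2)                                 # datatype
  wi(dt$bits, 2)                                 # bitpix
  wi(0L, 2)                                      # slice_start
  wf(c(1, in_plane_spacing, in_plane_spacing, slice_spacing, 0, 0, 0, 0)) # pixdim[8]
  wf(352)                                        # vox_offset
  wf(c(1, 0))                                    # scl_slope, scl_inter
  wi(0L, 2); writeBin(raw(1), con); writeBin(raw(1), con) # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0))                                 # cal_max, cal_min, slice_duration
  wf(0)                                          # toffset
  wi(c(0L, 0L), 4)                               # glmax, glmin
  writeBin(raw(80 + 24), con)                    # descrip, aux_file
  wi(c(0L, 0L), 2)                               # qform_code, sform_code
  wf(rep(0, 18))                                 # quatern/qoffset + srow
  writeBin(raw(16), con)                         # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con) # magic
  writeBin(raw(4), con)                          # extender
  if (dt$what == "integer") {
    writeBin(as.integer(round(as.vector(arr))), con, size = dt$size,
             endian = "little")
  } else {
    writeBin(as.numeric(as.vector(arr)), con, size = dt$size,
             endian = "little")
  }
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n, size) readBin(con, "integer", n = n, size = size,
                                  endian = "little")
  rf <- function(n) readBin(con, "double", n = n, size = 4, endian = "little")
  if (ri(1, 4) != 348L) stopf("'%s' is not an uncompressed NIfTI-1 file", path)
  readBin(con, "raw", 36)
  dims <- ri(8, 2)
  if (dims[1] != 3L) stopf("only 3-D NIfTI volumes are supported")
  d <- dims[2:4]
  rf(3); ri(1, 2)
  dtcode <- ri(1, 2)
  ri(1, 2); ri(1, 2)
  pixdim <- rf(8)
  vox_offset <- rf(1)
  scl <- rf(2)
  seek(con, vox_offset)
  n <- prod(d)
  vec <- switch(as.character(dtcode),
                "2" = readBin(con, "integer", n, size = 1, signed = FALSE,
                              endian = "little"),
                "4" = readBin(con, "integer", n, size = 2, endian = "little"),
                "8" = readBin(con, "integer", n, size = 4, endian = "little"),
                "16" = readBin(con, "double", n, size = 4, endian = "little"),
                "64" = readBin(con, "double", n, size = 8, endian = "little"),
                stopf("unsupported NIfTI datatype code %d", dtcode))
  if (scl[1] != 0 && !(scl[1] == 1 && scl[2] == 0))
    vec <- vec * scl[1] + scl[2]
  arr <- array(vec, dim = d)                    # (row, col, slice)
  list(img = aperm(arr, c(3, 1, 2)),            # back to (slice, row, col)
       in_plane_spacing = pixdim[2],
       slice_spacing = pixdim[4])
}

#' CT volume and truth-mask NIfTI round trip
#'
#' `write_ct_volume`/`read_ct_volume` store a [ct_volume()] as int16 NIfTI
#' (slice thickness is not representable in the header and must be re-supplied
#' on read). `write_mask_labels`/`read_mask_labels` store a `phantom_truth`
#' as an integer label volume with the convention 0 background, 1 adipose,
#' 2-5 classes A-D, 6 table.
#'
#' @param volume a [ct_volume()]
#' @param path file path (`.nii`)
#' @param slice_thickness slice thickness metadata to attach on read, mm
#' @return read functions return a [ct_volume()] / `phantom_truth`-like list
#' @export
write_ct_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  write_nifti(volume$hu, path, volume$in_plane_spacing, volume$slice_spacing,
              "int16")
}

#' @rdname write_ct_volume
#' @export
read_ct_volume <- function(path, slice_thickness = NULL) {
  nii <- read_nifti(path)
  if (nii$in_plane_spacing <= 0 || nii$slice_spacing <= 0)
    stopf("'%s' lacks valid spacing metadata", path)
  ct_volume(nii$img, nii$in_plane_spacing, nii$slice_spacing,
            if (is.null(slice_thickness)) nii$slice_spacing else slice_thickness)
}

mask_label_codes <- c(adipose = 1L, A = 2L, B = 3L, C = 4L, D = 5L, table = 6L)

#' @rdname write_ct_volume
#' @param truth a `phantom_truth`
#' @export
write_mask_labels <- function(truth, path) {
  dims <- dim(truth$body_mask)
  lab <- array(0L, dims)
  lab[truth$adipose_mask] <- mask_label_codes[["adipose"]]
  for (cls in names(truth$class_masks))
    lab[truth$class_masks[[cls]]] <- mask_label_codes[[cls]]
  write_nifti(lab, path, 1, 1, "uint8")
}

#' @rdname write_ct_volume
#' @export
read_mask_labels <- function(path) {
  nii <- read_nifti(path)
  lab <- nii$img
  cls <- setdiff(names(mask_label_codes), "adipose")
  masks <- lapply(cls, function(k) lab == mask_label_codes[[k]])
  names(masks) <- cls
  list(adipose_mask = lab == 1L,
       class_masks = masks[vapply(masks, any, TRUE)],
       labels = lab)
}
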