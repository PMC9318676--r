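# Minimal NIfTI-1 volume I/O (little-endian, single-file .nii / .nii.gz).
# Hand-rolled because no NIfTI-capable R package is available in the
# target environment.  The writer emits uint8 label volumes laid out like
# the ACDC dataset: one 3D volume per cardiac frame with short-axis
# slices stacked along the third axis, index 1 = basal.

write_raw_buffer <- function(writer) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writer(con)
  rawConnectionValue(con)
}

nifti1_header <- function(dims, datatype, bitpix) {
  write_raw_buffer(function(con) {
    wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                     endian = "little")
    wf <- function(x) writeBin(as.numeric(x), con, size = 4,
                               endian = "little")
    wz <- function(n) writeBin(raw(n), con)
    wi(348, 4)                       # sizeof_hdr
    wz(36)                           # data_type..dim_info
    wi(c(3, dims, rep(1, 7 - length(dims))), 2) # dim[8]
    wf(rep(0, 3)); wi(0, 2)          # intent_p1-3, intent_code
    wi(datatype, 2); wi(bitpix, 2); wi(0, 2) # datatype, bitpix, slice_start
    wf(c(1, 1, 1, 1, 0, 0, 0, 0))    # pixdim[8]
    wf(352)                          # vox_offset
    wf(1); wf(0)                     # scl_slope, scl_inter
    wi(0, 2); wz(2)                  # slice_end, slice_code, xyzt_units
    wf(c(0, 0, 0, 0))                # cal_max, cal_min, slice_dur, toffset
    wi(c(0, 0), 4)                   # glmax, glmin
    wz(104)                          # descrip[80], aux_file[24]
    wi(c(0, 1), 2)                   # qform_code, sform_code
    wf(rep(0, 6))                    # quatern_b/c/d, qoffset_x/y/z
    wf(c(1, 0, 0, 0)); wf(c(0, 1, 0, 0)); wf(c(0, 0, 1, 0)) # srow
    wz(16)                           # intent_name
    writeBin(c(charToRaw("n+1"), raw(1)), con) # magic
    wz(4)                            # extension flag
  })
}

#' Write a 3D volume as NIfTI-1 (.nii or .nii.gz)
#'
#' Integer volumes in `[0, 255]` are stored as uint8, other integer data
#' as int32, numeric data as float32.
#'
#' @param volume 3D array; the third axis is the slice axis.
#' @param path Output path; compressed iff it ends in `.gz`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(volume, path) {
  d <- dim(volume)
  stopifnot(length(d) == 3)
  v <- as.vector(volume)
  int_like <- is.integer(volume) || all(v == round(v))
  if (int_like && all(v >= 0) && all(v <= 255)) {
    hdr <- nifti1_header(d, datatype = 2, bitpix = 8)
    body <- as.raw(as.integer(v))
  } else if (int_like) {
    hdr <- nifti1_header(d, datatype = 8, bitpix = 32)
    body <- write_raw_buffer(function(con)
      writeBin(as.integer(v), con, size = 4, endian = "little"))
  } else {
    hdr <- nifti1_header(d, datatype = 16, bitpix = 32)
    body <- write_raw_buffer(function(con)
      writeBin(as.numeric(v), con, size = 4, endian = "little"))
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(c(hdr, body), con)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Little-endian single-file NIfTI-1 with datatype uint8, int16, int32,
#' float32 or float64; `scl_slope`/`scl_inter` are applied when set.
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return 3D array.
#' @export
read_nifti <- function(path) {
  con <- gzfile(path, "rb") # reads plain files transparently too
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  if (length(hdr) < 348) stop("truncated NIfTI header: ", path)
  rd <- function(off, n, size, what = "integer", signed = TRUE) {
    rcon <- rawConnection(hdr[(off + 1):(off + n * size)])
    on.exit(close(rcon), add = TRUE)
    readBin(rcon, what, n = n, size = size, endian = "little",
            signed = signed)
  }
  if (rd(0, 1, 4) != 348)
    stop("unsupported NIfTI file (not little-endian NIfTI-1): ", path)
  dim8 <- rd(40, 8, 2)
  ndim <- dim8[1]
  if (ndim < 3) stop("expected a 3D volume: ", path)
  dims <- dim8[2:(ndim + 1)]
  if (ndim > 3) {
    if (any(dims[4:length(dims)] != 1))
      stop("expected a single-frame 3D volume: ", path)
    dims <- dims[1:3]
  }
  datatype <- rd(70, 1, 2)
  vox_offset <- rd(108, 1, 4, "numeric")
  slope <- rd(112, 1, 4, "numeric")
  inter <- rd(116, 1, 4, "numeric")
  n <- prod(dims)
  readBin(con, "raw", vox_offset - 348) # skip extensions
  v <- switch(as.character(datatype),
    "2"  = as.integer(readBin(con, "integer", n, 1, signed = FALSE)),
    "4"  = readBin(con, "integer", n, 2, endian = "little"),
    "8"  = readBin(con, "integer", n, 4, endian = "little"),
    "16" = readBin(con, "numeric", n, 4, endian = "little"),
    "64" = readBin(con, "numeric", n, 8, endian = "little"),
    stop("unsupported NIfTI datatype ", datatype, ": ", path))
  if (length(v) < n) stop("truncated NIfTI data: ", path)
  if (slope != 0 && !(slope == 1 && inter == 0)) v <- v * slope + inter
  array(v, dims)
}

frame_file <- function(directory, patient_id, frame) {
  cands <- file.path(directory, paste0(patient_id, "_", frame,
                                       c(".nii.gz", ".nii")))
  hit <- cands[file.exists(cands)]
  if (length(hit) == 0)
    stop("missing ", frame, " frame for patient ", patient_id, " in ",
         directory, " (expected ", basename(cands[1]), ")")
  hit[1]
}

#' Write a patient's frames as ACDC-style NIfTI pairs
#'
#' One uint8 label volume per frame, `<patient_id>_ED.nii.gz` and
#' `<patient_id>_ES.nii.gz`, slices stacked basal-first along the third
#' axis.
#'
#' @param patient A [patient_frames()].
#' @param directory Output directory (created if needed).
#' @return Character vector of the two file paths, invisibly.
#' @export
write_patient_niftis <- function(patient, directory) {
  stopifnot(inherits(patient, "patient_frames"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  stack <- function(slices) {
    d <- dim(slices[[1]])
    array(unlist(slices), c(d, length(slices)))
  }
  paths <- c(file.path(directory, paste0(patient$patient_id, "_ED.nii.gz")),
             file.path(directory, paste0(patient$patient_id, "_ES.nii.gz")))
  write_nifti(stack(patient$ed_slices), paths[1])
  write_nifti(stack(patient$es_slices), paths[2])
  invisible(paths)
}

#' Read a patient's label volumes from NIfTI files
#'
#' Expects `<patient_id>_ED.nii[.gz]` and `<patient_id>_ES.nii[.gz]` in
#' `directory`; slices along the third axis are interpreted basal-first.
#' Labels are validated to be integers in `{0,1,2,3}`.
#'
#' @param directory Directory containing the frame volumes.
#' @param patient_id Patient identifier.
#' @param condition Optional class label to attach.
#' @return A [patient_frames()].
#' @export
read_patient_niftis <- function(directory, patient_id,
                                condition = NA_character_) {
  read_frame <- function(frame) {
    vol <- read_nifti(frame_file(directory, patient_id, frame))
    lapply(seq_len(dim(vol)[3]), function(k) {
      m <- vol[, , k]
      bad <- unique(m[!(m %in% 0:3 & m == round(m))])
      if (length(bad) > 0)
        stop("invalid label value ", paste(bad, collapse = ", "),
             " in ", frame, " slice ", k, " of patient ", patient_id)
      storage.mode(m) <- "integer"
      m
    })
  }
  patient_frames(patient_id, read_frame("ED"), read_frame("ES"),
                 condition = condition)
}
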