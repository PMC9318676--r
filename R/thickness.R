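# 2D thickness encoding: collapse a patient's multi-slice ED/ES label
# maps into one 128 x 64 x 3 image.  Per slice k of an N-slice frame,
# every pixel carrying a structure label contributes the k-th entry of the
# N-slice intensity table to that structure's channel (RV -> R, MYO -> G,
# LV -> B); the entries of each table sum to exactly 255, so a pixel
# labeled in all N slices saturates at 255 and brightness encodes how many
# slices a structure spans.

# The per-N intensity tables.  No generating formula exists; the tables
# are fixed constants of the encoding (N > 6 is unsupported).
SLICE_INTENSITY_TABLES <- list(
  `1` = c(255L),
  `2` = c(85L, 170L),
  `3` = c(21L, 87L, 147L),
  `4` = c(16L, 51L, 85L, 103L),
  `5` = c(15L, 29L, 51L, 67L, 93L),
  `6` = c(14L, 26L, 38L, 49L, 59L, 69L)
)

#' Slice intensity table
#'
#' The ordered per-slice intensities used by the thickness encoding for an
#' `n`-slice frame (basal slice first).  Each table sums to exactly 255.
#'
#' @param n Number of slices, 1 to 6.
#' @return Integer vector of length `n`.
#' @export
slice_intensities <- function(n) {
  key <- as.character(n)
  if (!key %in% names(SLICE_INTENSITY_TABLES))
    stop("no intensity table for N = ", n, " slices (supported: 1-6)")
  SLICE_INTENSITY_TABLES[[key]]
}

#' Select the basal slices of a frame
#'
#' Returns the first `n` slices in basal-to-apical order.
#'
#' @param frame_slices Ordered list of label maps, basal first.
#' @param n Number of slices to keep (`1 <= n <= length(frame_slices)`).
#' @param patient_id Optional id used in the error message.
#' @return List of `n` label maps.
#' @export
select_slices <- function(frame_slices, n, patient_id = NULL) {
  stopifnot(n >= 1)
  if (length(frame_slices) < n)
    stop("patient ", if (is.null(patient_id)) "<unknown>" else patient_id,
         " has only ", length(frame_slices), " slices; ", n, " requested")
  frame_slices[seq_len(n)]
}

#' Encode one frame into an accumulated-intensity image
#'
#' For slice `k`, every pixel labeled RV/MYO/LV contributes
#' `intensities[k]` to the R/G/B channel respectively; contributions are
#' summed over slices.  Valid label maps can never exceed 255 per channel
#' because each table sums to 255.
#'
#' @param slices List of integer label maps, all the same shape, basal
#'   slice first; the number of slices must have an intensity table.
#' @param intensities Optional intensity vector overriding
#'   [slice_intensities()] for `length(slices)`.
#' @return Numeric `H x W x 3` array of accumulated intensities.
#' @export
encode_frame <- function(slices, intensities = NULL) {
  stopifnot(is.list(slices), length(slices) >= 1)
  n <- length(slices)
  if (is.null(intensities)) intensities <- slice_intensities(n)
  stopifnot(length(intensities) == n)
  d <- dim(slices[[1]])
  out <- array(0, c(d, 3))
  for (k in seq_len(n)) {
    m <- slices[[k]]
    if (!identical(dim(m), d)) stop("slices differ in shape")
    out[, , 1] <- out[, , 1] + intensities[k] * (m == LABEL_RV)
    out[, , 2] <- out[, , 2] + intensities[k] * (m == LABEL_MYO)
    out[, , 3] <- out[, , 3] + intensities[k] * (m == LABEL_LV)
  }
  out
}

#' Crop window specification
#'
#' @param size Side of the square crop window in pixels (default 128).
#' @param mode `"center"` crops around the image center; `"content"`
#'   around the centroid of nonzero pixels (falling back to the image
#'   center for an all-zero image).
#' @return An object of class `crop_spec`.
#' @export
crop_spec <- function(size = 128L, mode = c("center", "content")) {
  mode <- match.arg(mode)
  size <- as.integer(size)
  if (is.na(size) || size < 1) stop("degenerate crop window: size must be >= 1")
  structure(list(size = size, mode = mode), class = "crop_spec")
}

#' Crop and resize an encoded frame
#'
#' Crops a square window per [crop_spec()] (clamped inside the image) and
#' resizes it to `64 x 64` with antialiased bilinear interpolation;
#' intensities are rounded half-up to integers and clipped to `[0, 255]`.
#'
#' @param image `H x W x 3` numeric array.
#' @param spec A [crop_spec()].
#' @param target Output `(rows, cols)`, default `c(64, 64)`.
#' @return Integer-valued `target[1] x target[2] x 3` array.
#' @export
crop_and_resize <- function(image, spec = crop_spec(), target = c(64L, 64L)) {
  d <- dim(image)
  stopifnot(length(d) == 3, inherits(spec, "crop_spec"))
  size <- spec$size
  if (size > min(d[1:2]))
    stop("crop window (", size, ") larger than image (",
         d[1], "x", d[2], ")")
  if (spec$mode == "content") {
    nz <- which(apply(image != 0, c(1, 2), any), arr.ind = TRUE)
    ctr <- if (nrow(nz) == 0) (d[1:2] + 1) / 2 else colMeans(nz)
  } else {
    ctr <- (d[1:2] + 1) / 2
  }
  r0 <- min(max(round_half_up(ctr[1] - size / 2 + 0.5), 1), d[1] - size + 1)
  c0 <- min(max(round_half_up(ctr[2] - size / 2 + 0.5), 1), d[2] - size + 1)
  win <- image[r0:(r0 + size - 1), c0:(c0 + size - 1), , drop = FALSE]
  out <- resize_image(win, target, mode = "bilinear")
  out <- round_half_up(out)
  out[out < 0] <- 0; out[out > 255] <- 255
  storage.mode(out) <- "integer"
  out
}

#' Thickness image container
#'
#' @param patient_id Character scalar.
#' @param pixels Integer `128 x 64 x 3` array, intensities in `[0, 255]`;
#'   rows 1-64 are the ED half, rows 65-128 the ES half; channels are
#'   (RV, MYO, LV) = (R, G, B).
#' @param condition Class label or `NA`.
#' @return Object of class `thickness_image`.
#' @export
thickness_image <- function(patient_id, pixels, condition = NA_character_) {
  d <- dim(pixels)
  stopifnot(length(d) == 3, d[3] == 3,
            all(pixels >= 0), all(pixels <= 255))
  structure(list(patient_id = patient_id, condition = condition,
                 pixels = pixels), class = "thickness_image")
}

#' @export
print.thickness_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat("<thickness_image>", x$patient_id,
      if (!is.na(x$condition)) paste0("(", x$condition, ")") else "(unlabeled)",
      "-", paste(d, collapse = "x"), "\n")
  invisible(x)
}

#' Encode a patient into a thickness image
#'
#' Selects the first `n_slices` basal slices of each frame, encodes ED and
#' ES with the `n_slices` intensity table, crops and resizes each to
#' `64 x 64 x 3`, and joins them vertically (ED on top).
#'
#' @param patient A [patient_frames()] object.
#' @param n_slices Slices per frame to encode (1-6).
#' @param spec A [crop_spec()].
#' @param intensities Optional intensity override for [encode_frame()].
#' @return A [thickness_image()] of shape `128 x 64 x 3`.
#' @export
encode_patient <- function(patient, n_slices = 6L, spec = crop_spec(),
                           intensities = NULL) {
  stopifnot(inherits(patient, "patient_frames"))
  ed <- select_slices(patient$ed_slices, n_slices, patient$patient_id)
  es <- select_slices(patient$es_slices, n_slices, patient$patient_id)
  top <- crop_and_resize(encode_frame(ed, intensities), spec)
  bot <- crop_and_resize(encode_frame(es, intensities), spec)
  px <- array(0L, c(2 * dim(top)[1], dim(top)[2], 3))
  px[seq_len(dim(top)[1]), , ] <- top
  px[dim(top)[1] + seq_len(dim(bot)[1]), , ] <- bot
  thickness_image(patient$patient_id, px, patient$condition)
}

#' Dataset-level default slice count
#'
#' The minimum slice count over all patients and frames, capped at 6 (the
#' largest N with an intensity table).
#'
#' @param patients List of [patient_frames()].
#' @return Integer.
#' @export
default_n_slices <- function(patients) {
  m <- min(vapply(patients, function(p)
    min(length(p$ed_slices), length(p$es_slices)), 1L))
  min(m, 6L)
}

#' Encode every patient of a dataset
#'
#' @param patients List of [patient_frames()].
#' @param n_slices Slices per frame; default [default_n_slices()].
#' @param spec A [crop_spec()].
#' @return List of [thickness_image()] objects.
#' @export
encode_dataset <- function(patients, n_slices = NULL, spec = crop_spec()) {
  if (is.null(n_slices)) n_slices <- default_n_slices(patients)
  lapply(patients, encode_patient, n_slices = n_slices, spec = spec)
}
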