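# Pre/post-processing operators around segmentation: padding, resizing,
# channel triplication, probability ensembling, mask cleanup, Jaccard loss.

#' Auto zero padding to a square
#'
#' Pads the shorter side of a 2D (or 2D + channels) image with zeros to
#' make it square, splitting the padding as evenly as possible with the
#' extra pixel on the trailing side.  The original content is unchanged.
#'
#' @param image Matrix or `H x W x C` array.
#' @return Square image of side `max(nrow, ncol)`, same type.
#' @export
auto_zero_pad <- function(image) {
  d <- dim(image)
  stopifnot(length(d) %in% c(2, 3))
  h <- d[1]; w <- d[2]
  side <- max(h, w)
  if (h == w) return(image)
  out_dim <- d; out_dim[1:2] <- side
  out <- array(if (is.integer(image)) 0L else 0, out_dim)
  lead_r <- (side - h) %/% 2
  lead_c <- (side - w) %/% 2
  if (length(d) == 2) {
    out[lead_r + seq_len(h), lead_c + seq_len(w)] <- image
    if (is.matrix(image)) out <- matrix(out, side, side)
  } else {
    out[lead_r + seq_len(h), lead_c + seq_len(w), ] <- image
  }
  out
}

# Interpolation weight matrix mapping n_in samples to n_out.
# mode "bilinear": antialiased — area-overlap (box) weights when
# downscaling, linear-interpolation sampling when upscaling.  Rows are
# non-negative and sum to 1, so interpolation is convex.
interp_matrix <- function(n_in, n_out) {
  w <- matrix(0, n_out, n_in)
  if (n_out < n_in) {
    r <- n_in / n_out
    for (j in seq_len(n_out)) {
      lo <- (j - 1) * r; hi <- j * r
      i <- (floor(lo) + 1):ceiling(hi)
      ov <- pmin(hi, i) - pmax(lo, i - 1)
      w[j, i] <- ov / sum(ov) # exact row-stochastic weights
    }
  } else {
    r <- n_in / n_out
    pos <- (seq_len(n_out) - 0.5) * r + 0.5
    i0 <- pmin(pmax(floor(pos), 1), n_in)
    i1 <- pmin(i0 + 1, n_in)
    t <- pmin(pmax(pos - floor(pos), 0), 1)
    t[pos < 1] <- 0; t[pos > n_in] <- 1
    for (j in seq_len(n_out)) {
      w[j, i0[j]] <- w[j, i0[j]] + (1 - t[j])
      w[j, i1[j]] <- w[j, i1[j]] + t[j]
    }
  }
  w
}

#' Resize an image
#'
#' `mode = "nearest"` samples by index and therefore preserves the set of
#' values (use for label maps).  `mode = "bilinear"` uses convex
#' interpolation weights (area averaging when downscaling), preserving the
#' value range.  An identity target returns the input unchanged.
#'
#' @param image Matrix or `H x W x C` array.
#' @param target Integer `(rows, cols)`.
#' @param mode `"nearest"` or `"bilinear"`.
#' @return Resized image.
#' @export
resize_image <- function(image, target, mode = c("nearest", "bilinear")) {
  mode <- match.arg(mode)
  d <- dim(image)
  stopifnot(length(d) %in% c(2, 3), length(target) == 2, all(target >= 1))
  target <- as.integer(target)
  if (all(d[1:2] == target)) return(image)
  if (mode == "nearest") {
    ri <- pmin(pmax(floor((seq_len(target[1]) - 0.5) * d[1] / target[1]) + 1,
                    1), d[1])
    ci <- pmin(pmax(floor((seq_len(target[2]) - 0.5) * d[2] / target[2]) + 1,
                    1), d[2])
    if (length(d) == 2) image[ri, ci, drop = FALSE]
    else image[ri, ci, , drop = FALSE]
  } else {
    wr <- interp_matrix(d[1], target[1])
    wc <- interp_matrix(d[2], target[2])
    if (length(d) == 2) {
      wr %*% image %*% t(wc)
    } else {
      out <- array(0, c(target, d[3]))
      for (k in seq_len(d[3])) out[, , k] <- wr %*% image[, , k] %*% t(wc)
      out
    }
  }
}

#' Triplicate a grayscale image into three channels
#'
#' @param gray Single-channel matrix (or `H x W x 1` array).
#' @return `H x W x 3` array with three identical channels.
#' @export
triplicate_channels <- function(gray) {
  if (is.array(gray) && length(dim(gray)) == 3) {
    if (dim(gray)[3] != 1) stop("input already has ", dim(gray)[3],
                                " channels; expected a single channel")
    gray <- array(gray, dim(gray)[1:2])
  }
  stopifnot(is.matrix(gray))
  array(gray, c(dim(gray), 3))
}

#' Ensemble-average probability stacks into a label map
#'
#' Averages per-pixel class probabilities over stacks and takes the
#' per-pixel argmax (ties broken toward the lowest class index).  Applying
#' a softmax to the averaged probabilities before the argmax would give
#' the identical labels since softmax is monotone.
#'
#' @param prob_stacks List of `H x W x C` probability arrays, same shape.
#' @return Integer label matrix with values in `0:(C-1)`.
#' @export
ensemble_average <- function(prob_stacks) {
  stopifnot(is.list(prob_stacks), length(prob_stacks) >= 1)
  d <- dim(prob_stacks[[1]])
  stopifnot(length(d) == 3)
  for (s in prob_stacks)
    if (!identical(dim(s), d)) stop("probability stacks differ in shape")
  avg <- Reduce(`+`, prob_stacks) / length(prob_stacks)
  flat <- matrix(avg, d[1] * d[2], d[3])
  lab <- max.col(flat, ties.method = "first") - 1L
  matrix(as.integer(lab), d[1], d[2])
}

# Connected components of a logical mask (4-connectivity) by iterative
# max-id propagation; returns a numeric matrix of component ids (0 = off).
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  ids <- matrix(0, h, w)
  ids[mask] <- which(mask)
  zr <- rep(0, w); zc <- rep(0, h)
  repeat {
    up    <- rbind(ids[-1, , drop = FALSE], zr)
    down  <- rbind(zr, ids[-h, , drop = FALSE])
    left  <- cbind(ids[, -1, drop = FALSE], zc)
    right <- cbind(zc, ids[, -w, drop = FALSE])
    new <- pmax(ids, up, down, left, right)
    new[!mask] <- 0
    if (identical(new, ids)) break
    ids <- new
  }
  ids
}

# Pixels not in `mask` and not 4-connected to the image border through
# the complement of `mask` (i.e. interior holes of mask).
interior_holes <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  open <- !mask
  reach <- matrix(FALSE, h, w)
  reach[1, ] <- open[1, ]; reach[h, ] <- open[h, ]
  reach[, 1] <- reach[, 1] | open[, 1]
  reach[, w] <- reach[, w] | open[, w]
  zr <- rep(FALSE, w); zc <- rep(FALSE, h)
  repeat {
    grown <- reach |
      rbind(reach[-1, , drop = FALSE], zr) |
      rbind(zr, reach[-h, , drop = FALSE]) |
      cbind(reach[, -1, drop = FALSE], zc) |
      cbind(zc, reach[, -w, drop = FALSE])
    grown <- grown & open
    if (identical(grown, reach)) break
    reach <- grown
  }
  open & !reach
}

#' Clean up a predicted label map
#'
#' Per non-background class: keeps only the largest 4-connected component
#' (for the RV this is what removes a spurious double contour) and fills
#' interior background holes with the class label.  Idempotent.  Holes
#' occupied by another class (e.g. the LV cavity inside the myocardial
#' annulus) are left alone; only background-labeled enclosed pixels are
#' filled.
#'
#' @param label_map Integer matrix with values in `{0,1,2,3}`.
#' @return Cleaned integer label map.
#' @export
postprocess_mask <- function(label_map) {
  stopifnot(is.matrix(label_map), all(label_map %in% 0:3))
  map <- label_map
  # first pass: largest component per class (all classes before any hole
  # filling, so that removed debris is visible as background to the fill)
  for (cls in 1:3) {
    mask <- map == cls
    if (!any(mask)) next
    comp <- label_components(mask)
    sizes <- table(comp[comp > 0])
    keep <- as.numeric(names(sizes)[which.max(sizes)])
    map[mask & comp != keep] <- 0L
  }
  # second pass: fill enclosed background per class
  for (cls in 1:3) {
    kept <- map == cls
    if (!any(kept)) next
    holes <- interior_holes(kept)
    map[holes & map == 0L] <- cls
  }
  storage.mode(map) <- "integer"
  map
}

#' Jaccard loss
#'
#' `1 - |G intersect P| / (|G| + |P| - |G intersect P|)` for binary masks;
#' with a probability-valued prediction the soft variant uses elementwise
#' products and sums.  Two empty masks are in perfect agreement, so the
#' loss is defined as 0 (background-only apical slices must not yield an
#' undefined loss).
#'
#' @param ground_truth Binary array.
#' @param prediction Binary or probability-valued array, same shape.
#' @return Scalar loss in `[0, 1]`.
#' @export
jaccard_loss <- function(ground_truth, prediction) {
  g <- as.numeric(ground_truth); p <- as.numeric(prediction)
  if (length(g) != length(p)) stop("mask shapes differ")
  if (any(g < 0 | g > 1) || any(p < 0 | p > 1))
    stop("masks must be binary or probability-valued in [0, 1]")
  inter <- sum(g * p)
  union <- sum(g) + sum(p) - inter
  if (union == 0) return(0)
  1 - inter / union
}
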