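# Synthetic short-axis cardiac label-map generator.
#
# Minimal shape family expressing what distinguishes the five morphology
# groups on segmentation maps: the left-ventricular blood pool is a disc
# (label 3), the myocardium a concentric annulus (label 2), and the right
# ventricle a crescent-shaped annular sector hugging the epicardium
# (label 1).  End-systole is derived from end-diastole by scaling the
# cavity radii, so ejection-fraction-like contrast between groups is
# directly controllable.

#' Slice geometry
#'
#' Parameterizes the anatomy rendered on one short-axis slice.
#'
#' @param center Numeric length-2 `(row, col)` center in pixels.
#' @param lv_radius Radius of the LV blood pool disc, pixels (`>= 0`;
#'   0 renders an empty slice).
#' @param myo_thickness Thickness of the myocardial annulus, pixels.
#' @param rv_extent Radial depth of the RV crescent, pixels (`>= 0`).
#' @param rv_angular_span Angular width of the RV crescent, radians.
#' @param rv_direction Direction (radians) of the crescent's center;
#'   `pi` points toward decreasing column index.
#' @return An object of class `slice_geometry`.
#' @export
slice_geometry <- function(center, lv_radius, myo_thickness, rv_extent,
                           rv_angular_span = 2.4, rv_direction = pi) {
  stopifnot(length(center) == 2, is.finite(center),
            length(lv_radius) == 1, lv_radius >= 0,
            length(myo_thickness) == 1, myo_thickness >= 0,
            length(rv_extent) == 1, rv_extent >= 0,
            rv_angular_span > 0, rv_angular_span <= 2 * pi)
  structure(list(center = as.numeric(center),
                 lv_radius = as.numeric(lv_radius),
                 myo_thickness = as.numeric(myo_thickness),
                 rv_extent = as.numeric(rv_extent),
                 rv_angular_span = as.numeric(rv_angular_span),
                 rv_direction = as.numeric(rv_direction)),
            class = "slice_geometry")
}

#' Rasterize one short-axis slice
#'
#' Renders a [slice_geometry()] into an integer label map with labels
#' 0 = background, 1 = RV, 2 = myocardium, 3 = LV.  Labels are mutually
#' exclusive by construction.
#'
#' @param geometry A [slice_geometry()].
#' @param shape Integer `(rows, cols)` of the output map.
#' @return Integer matrix of dimension `shape` with values in `{0,1,2,3}`.
#' @export
make_slice_label_map <- function(geometry, shape = c(256L, 256L)) {
  stopifnot(inherits(geometry, "slice_geometry"),
            length(shape) == 2, shape >= 1)
  g <- geometry
  r_out <- g$lv_radius + g$myo_thickness + g$rv_extent
  if (g$center[1] - r_out < 1 || g$center[1] + r_out > shape[1] ||
      g$center[2] - r_out < 1 || g$center[2] + r_out > shape[2]) {
    stop("geometry exceeds image bounds: outer radius ", round(r_out, 2),
         " around center (", g$center[1], ", ", g$center[2],
         ") does not fit in a ", shape[1], "x", shape[2], " image")
  }
  rows <- matrix(seq_len(shape[1]) - g$center[1], shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]) - g$center[2], shape[1], shape[2],
                 byrow = TRUE)
  dist <- sqrt(rows^2 + cols^2)
  map <- matrix(LABEL_BG, shape[1], shape[2])
  if (g$lv_radius > 0) {
    map[dist <= g$lv_radius] <- LABEL_LV
    if (g$myo_thickness > 0) {
      r_epi <- g$lv_radius + g$myo_thickness
      map[dist > g$lv_radius & dist <= r_epi] <- LABEL_MYO
      if (g$rv_extent > 0) {
        # angular distance from the crescent's direction, in (-pi, pi]
        ang <- atan2(rows, cols) # row offset ~ y, col offset ~ x
        dang <- (ang - g$rv_direction + pi) %% (2 * pi) - pi
        rv <- dist > r_epi & dist <= r_epi + g$rv_extent &
          abs(dang) <= g$rv_angular_span / 2
        map[rv] <- LABEL_RV
      }
    }
  }
  storage.mode(map) <- "integer"
  map
}

#' Condition profile
#'
#' Distribution of slice-geometry parameters for one morphology group.
#' Parameter entries are `(mean, sd)` pairs in pixels (for a 256 x 256
#' grid); `es_contraction_factor` is the fraction of the end-diastolic
#' cavity radii (LV radius and RV extent) remaining at end-systole, and
#' `apical_taper` the per-slice fractional shrink of the radii from the
#' base toward the apex.
#'
#' @param condition One of `"DCM"`, `"HCM"`, `"MINF"`, `"NOR"`, `"ARV"`.
#' @param lv_radius,myo_thickness,rv_extent Numeric `(mean, sd)` pairs.
#' @param es_contraction_factor Numeric `(mean, sd)`, mean in `(0, 1]`.
#' @param apical_taper Per-slice shrink fraction in `[0, 1)`.
#' @return An object of class `condition_profile`.
#' @export
condition_profile <- function(condition, lv_radius, myo_thickness, rv_extent,
                              es_contraction_factor, apical_taper) {
  stopifnot(condition %in% condition_classes(),
            length(lv_radius) == 2, length(myo_thickness) == 2,
            length(rv_extent) == 2, length(es_contraction_factor) == 2,
            es_contraction_factor[1] > 0, es_contraction_factor[1] <= 1,
            apical_taper >= 0, apical_taper < 1)
  structure(list(condition = condition,
                 lv_radius = as.numeric(lv_radius),
                 myo_thickness = as.numeric(myo_thickness),
                 rv_extent = as.numeric(rv_extent),
                 es_contraction_factor = as.numeric(es_contraction_factor),
                 apical_taper = as.numeric(apical_taper)),
            class = "condition_profile")
}

#' Default condition profiles
#'
#' The default generator parameters for the five morphology groups,
#' chosen so that on segmentation maps the groups differ the way the
#' clinical groups do: DCM has the largest ED cavity and a contraction
#' factor near 1 (enlarged heart, ineffective ES pumping); HCM the
#' thickest myocardium with a small cavity; MINF a normal-sized ED cavity
#' but a reduced ejection fraction (< 40%); ARV the largest RV; NOR is
#' the reference.  Values are pixels on a 256 x 256 grid.
#'
#' @return Named list of [condition_profile()] objects.
#' @export
condition_profiles <- function() {
  list(
    ARV  = condition_profile("ARV",  lv_radius = c(26, 2),
                             myo_thickness = c(9, 1),  rv_extent = c(30, 3),
                             es_contraction_factor = c(0.80, 0.03),
                             apical_taper = 0.10),
    DCM  = condition_profile("DCM",  lv_radius = c(44, 2.5),
                             myo_thickness = c(7, 1),  rv_extent = c(14, 2),
                             es_contraction_factor = c(0.95, 0.02),
                             apical_taper = 0.06),
    HCM  = condition_profile("HCM",  lv_radius = c(18, 1.5),
                             myo_thickness = c(20, 1.5), rv_extent = c(13, 2),
                             es_contraction_factor = c(0.55, 0.03),
                             apical_taper = 0.10),
    MINF = condition_profile("MINF", lv_radius = c(27, 2),
                             myo_thickness = c(9, 1),  rv_extent = c(15, 2),
                             es_contraction_factor = c(0.85, 0.02),
                             apical_taper = 0.10),
    NOR  = condition_profile("NOR",  lv_radius = c(26, 2),
                             myo_thickness = c(9, 1),  rv_extent = c(14, 2),
                             es_contraction_factor = c(0.65, 0.03),
                             apical_taper = 0.11)
  )
}

# truncated-normal draw: normal clipped to [lo, hi]
rnorm_clip <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Patient frames container
#'
#' Ordered basal-to-apical slice lists for the ED and ES frames of one
#' patient.
#'
#' @param patient_id Character scalar.
#' @param ed_slices,es_slices Lists of integer label-map matrices (basal
#'   slice first); all slices must share one shape and take values in
#'   `{0,1,2,3}`.
#' @param condition Class label, or `NA` for unlabeled data.
#' @return An object of class `patient_frames`.
#' @export
patient_frames <- function(patient_id, ed_slices, es_slices,
                           condition = NA_character_) {
  stopifnot(is.character(patient_id), length(patient_id) == 1,
            length(ed_slices) >= 1, length(es_slices) >= 1)
  slices <- c(ed_slices, es_slices)
  shp <- dim(slices[[1]])
  for (s in slices) {
    if (!is.matrix(s) || !identical(dim(s), shp))
      stop("all slices of patient ", patient_id, " must share one shape")
    v <- unique(as.vector(s))
    if (!all(v %in% 0:3))
      stop("label map of patient ", patient_id,
           " contains values outside {0,1,2,3}: ",
           paste(setdiff(v, 0:3), collapse = ", "))
  }
  structure(list(patient_id = patient_id,
                 condition = condition,
                 ed_slices = ed_slices,
                 es_slices = es_slices),
            class = "patient_frames")
}

#' @export
print.patient_frames <- function(x, ...) {
  cat("<patient_frames>", x$patient_id,
      if (!is.na(x$condition)) paste0("(", x$condition, ")") else "(unlabeled)",
      "-", length(x$ed_slices), "ED +", length(x$es_slices), "ES slices of",
      paste(dim(x$ed_slices[[1]]), collapse = "x"), "\n")
  invisible(x)
}

#' Generate one synthetic patient
#'
#' Draws per-patient geometry from a [condition_profile()], renders
#' `n_slices` ED slices with radii shrinking from base to apex by the
#' profile's `apical_taper`, and derives the ES slices from the ED
#' geometry by scaling the cavity radii (LV radius and RV extent) with
#' the drawn contraction factor.
#'
#' @param profile A [condition_profile()].
#' @param n_slices Slices per frame (`>= 1`).
#' @param shape Image shape `(rows, cols)`.
#' @param seed Optional integer seed; with a seed the result is
#'   deterministic and the global RNG stream is left untouched.
#' @param patient_id Identifier stored in the result.
#' @return A [patient_frames()] object.
#' @export
make_patient <- function(profile, n_slices = 8, shape = c(256L, 256L),
                         seed = NULL, patient_id = profile$condition) {
  stopifnot(inherits(profile, "condition_profile"), n_slices >= 1)
  with_seed(seed, {
    lv  <- rnorm_clip(1, profile$lv_radius[1], profile$lv_radius[2], lo = 4)
    myo <- rnorm_clip(1, profile$myo_thickness[1], profile$myo_thickness[2],
                      lo = 1)
    rv  <- rnorm_clip(1, profile$rv_extent[1], profile$rv_extent[2], lo = 0)
    esf <- rnorm_clip(1, profile$es_contraction_factor[1],
                      profile$es_contraction_factor[2], lo = 0.05, hi = 1)
    center <- (c(shape[1], shape[2]) + 1) / 2 + stats::runif(2, -8, 8)
    ed <- vector("list", n_slices)
    es <- vector("list", n_slices)
    for (i in seq_len(n_slices)) {
      sc <- (1 - profile$apical_taper)^(i - 1)
      ed[[i]] <- make_slice_label_map(
        slice_geometry(center, lv * sc, myo, rv * sc), shape)
      es[[i]] <- make_slice_label_map(
        slice_geometry(center, lv * sc * esf, myo, rv * sc * esf), shape)
    }
    patient_frames(patient_id, ed, es, condition = profile$condition)
  })
}

#' Generate a balanced labeled dataset
#'
#' @param n_per_class Patients per morphology group (`>= 1`).
#' @param n_slices Slices per frame; `NULL` draws 6-10 per patient.
#' @param shape Image shape.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @param profiles Named list of [condition_profile()]s (defaults to
#'   [condition_profiles()]).
#' @return List of [patient_frames()] with unique patient IDs, balanced
#'   over classes, of class `patient_dataset`.
#' @export
make_dataset <- function(n_per_class, n_slices = NULL, shape = c(256L, 256L),
                         seed = 1L, profiles = condition_profiles()) {
  stopifnot(n_per_class >= 1)
  with_seed(seed, {
    out <- list()
    for (cond in names(profiles)) {
      for (i in seq_len(n_per_class)) {
        ns <- if (is.null(n_slices)) sample(6:10, 1) else n_slices
        out[[length(out) + 1L]] <- make_patient(
          profiles[[cond]], n_slices = ns, shape = shape, seed = NULL,
          patient_id = sprintf("%s%03d", cond, i))
      }
    }
    structure(out, class = "patient_dataset")
  })
}

#' Labels table of a dataset
#'
#' @param patients A list of [patient_frames()].
#' @return `data.frame` with columns `patient_id`, `condition`.
#' @export
dataset_labels <- function(patients) {
  data.frame(patient_id = vapply(patients, `[[`, "", "patient_id"),
             condition = vapply(patients, `[[`, "", "condition"),
             stringsAsFactors = FALSE)
}

#' Simulate per-class segmentation probability maps
#'
#' Emulates the per-pixel class-probability output of a segmentation
#' model: per pixel, a unit logit margin is put on the true label and
#' Gaussian noise with standard deviation `2 * noise_level` is added to
#' every class logit before a softmax.  At `noise_level = 0` the argmax
#' reproduces the label map exactly; at higher levels individual pixels
#' flip, so averaging independent stacks measurably improves agreement.
#'
#' @param label_map Integer label matrix with values in `{0,1,2,3}`.
#' @param noise_level Noise fraction in `[0, 1)`.
#' @param seed Optional seed.
#' @return `H x W x 4` array; each pixel's 4-vector is non-negative and
#'   sums to 1 (class order background, RV, MYO, LV).
#' @export
make_probability_maps <- function(label_map, noise_level = 0, seed = NULL) {
  stopifnot(is.matrix(label_map), noise_level >= 0, noise_level < 1)
  with_seed(seed, {
    h <- nrow(label_map); w <- ncol(label_map)
    scores <- array(0, c(h, w, 4))
    for (k in 0:3) scores[, , k + 1][label_map == k] <- 1
    if (noise_level > 0)
      scores <- scores + array(stats::rnorm(h * w * 4, sd = 2 * noise_level),
                               c(h, w, 4))
    scores <- exp(scores - as.vector(apply(scores, c(1, 2), max)))
    scores / as.vector(apply(scores, c(1, 2), sum))
  })
}
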