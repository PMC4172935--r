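#' Specify a synthetic coronal brain-slice phantom
#'
#' Defines the geometry and intensity model of a skull-stripped, spatially
#' normalized coronal slice with three tissue classes (CSF < GM < WM): a
#' circular brain with a CSF rim, a GM annulus and a WM interior, plus two
#' elliptical GM-intensity hippocampal bodies sitting in CSF-filled pools
#' inside the standard hippocampal ROI rectangles (see [default_masks()]).
#' Atrophy shrinks the hippocampal semi-axes and the GM annulus by
#' `(1 - atrophy)`; the GM lost from the annulus is replaced by CSF at the
#' brain edge, so GM falls and CSF rises with disease severity.
#'
#' All geometric defaults are stated for the 498x498 reference frame and are
#' rescaled proportionally for other image sizes, so
#' `phantom_spec(width = 166, height = 166)` "just works".
#'
#' @param width,height Image size in pixels. Default 498x498, the normalized
#'   coronal frame the hippocampal ROI coordinates refer to.
#' @param intensity_csf,intensity_gm,intensity_wm Mean gray levels of the
#'   three tissue classes (arbitrary units on a nominal 0-255 scale); must be
#'   strictly increasing.
#' @param noise_sd Standard deviation of additive Gaussian noise applied
#'   inside the brain, in gray levels. `0` gives a noiseless slice.
#' @param bias_amplitude Amplitude in `[0, 1)` of a smooth low-frequency
#'   multiplicative shading field (`1 + a * cos * cos`), emulating MRI
#'   intensity inhomogeneity. `0` disables it.
#' @param hippo_left_center,hippo_right_center Hippocampal ellipse centers as
#'   `c(x, y)` pixel coordinates (column, row; 0-based). Must lie inside the
#'   respective ROI rectangle. Defaults to the ROI centers.
#' @param hippo_semi_axes Ellipse semi-axes `c(a, b)` in pixels before
#'   atrophy scaling.
#' @param atrophy Shrink factor in `[0, 1)` applied to the hippocampal
#'   semi-axes and GM annulus thickness. `0` = healthy anatomy.
#' @param brain_radius Radius of the brain disc in pixels.
#' @param csf_rim Baseline thickness in pixels of the outer CSF rim.
#' @param gm_band Baseline thickness in pixels of the GM annulus.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_slice()], [generate_cohort()], [default_masks()]
#' @export
phantom_spec <- function(width = 498L, height = 498L,
                         intensity_csf = 60, intensity_gm = 110,
                         intensity_wm = 170,
                         noise_sd = 0, bias_amplitude = 0,
                         hippo_left_center = NULL, hippo_right_center = NULL,
                         hippo_semi_axes = NULL,
                         atrophy = 0,
                         brain_radius = NULL, csf_rim = NULL, gm_band = NULL) {
  width <- as.integer(width); height <- as.integer(height)
  if (width < 8L || height < 8L) {
    stop("phantom_spec: width and height must be at least 8 pixels")
  }
  s <- min(width, height) / 498
  masks <- default_masks(width, height)
  if (is.null(hippo_left_center))  hippo_left_center  <- roi_center(masks$left)
  if (is.null(hippo_right_center)) hippo_right_center <- roi_center(masks$right)
  if (is.null(hippo_semi_axes)) hippo_semi_axes <- c(20, 12) * s
  if (is.null(brain_radius)) brain_radius <- 230 * s
  if (is.null(csf_rim)) csf_rim <- 12 * s
  if (is.null(gm_band)) gm_band <- 30 * s

  spec <- structure(
    list(width = width, height = height,
         intensity_csf = intensity_csf, intensity_gm = intensity_gm,
         intensity_wm = intensity_wm,
         noise_sd = noise_sd, bias_amplitude = bias_amplitude,
         hippo_left_center = as.numeric(hippo_left_center),
         hippo_right_center = as.numeric(hippo_right_center),
         hippo_semi_axes = as.numeric(hippo_semi_axes),
         atrophy = atrophy, brain_radius = brain_radius,
         csf_rim = csf_rim, gm_band = gm_band,
         masks = masks),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

roi_center <- function(rect) c((rect$x1 + rect$x2 - 1) / 2,
                               (rect$y1 + rect$y2 - 1) / 2)

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (!(intensity_csf < intensity_gm && intensity_gm < intensity_wm)) {
      stop("phantom_spec: tissue intensities must satisfy CSF < GM < WM")
    }
    if (noise_sd < 0) stop("phantom_spec: noise_sd must be >= 0")
    if (bias_amplitude < 0 || bias_amplitude >= 1) {
      stop("phantom_spec: bias_amplitude must lie in [0, 1)")
    }
    if (atrophy < 0 || atrophy >= 1) {
      stop("phantom_spec: atrophy must lie in [0, 1)")
    }
    if (any(hippo_semi_axes <= 0)) {
      stop("phantom_spec: hippo_semi_axes must be positive")
    }
    check_inside <- function(center, rect, side) {
      a <- hippo_semi_axes[1]; b <- hippo_semi_axes[2]
      ok <- center[1] - a > rect$x1 && center[1] + a < rect$x2 - 1 &&
        center[2] - b > rect$y1 && center[2] + b < rect$y2 - 1
      if (!ok) {
        stop(sprintf(
          "phantom_spec: %s hippocampal ellipse does not lie strictly inside its ROI rectangle",
          side))
      }
    }
    check_inside(hippo_left_center, masks$left, "left")
    check_inside(hippo_right_center, masks$right, "right")
    invisible(NULL)
  })
}

# Tissue label codes shared across the package.
#' Tissue label codes
#'
#' Integer codes used in label maps: background 0, CSF 1, GM 2, WM 3.
#' @return Named integer vector.
#' @export
tissue_levels <- function() {
  c(background = 0L, csf = 1L, gm = 2L, wm = 3L)
}

#' Generate one synthetic brain slice with ground truth
#'
#' Renders the phantom described by `spec`: background 0 outside the brain
#' disc; concentric CSF rim / GM annulus / WM interior; within each
#' hippocampal ROI rectangle a CSF pool containing a GM-intensity elliptical
#' hippocampal body. Gaussian noise (`spec$noise_sd`) and an optional smooth
#' multiplicative bias field (`spec$bias_amplitude`) are applied inside the
#' brain only. The ground truth records the noiseless label map and the exact
#' painted pixel count of each hippocampal ellipse.
#'
#' The generator is a pure function of `(spec, seed)`: identical arguments
#' give bit-identical output.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed controlling the noise realization.
#' @param class_label Optional class label (+1 AD, -1 control) recorded in
#'   the ground truth; `NA` when the slice has no cohort context.
#' @return A list of class `phantom_slice` with elements `image` (numeric
#'   matrix, rows = y, columns = x, with a `brain_mask` attribute) and
#'   `truth` (list: `label_map`, `hippo_left_area`, `hippo_right_area`,
#'   `class_label`, `atrophy`).
#' @examples
#' sl <- generate_slice(phantom_spec(width = 166, height = 166), seed = 1)
#' sl$truth$hippo_left_area
#' @export
generate_slice <- function(spec, seed, class_label = NA_integer_) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  lv <- tissue_levels()
  w <- spec$width; h <- spec$height
  # pixel-center coordinates, 0-based: x = column, y = row
  x <- matrix(rep(0:(w - 1L), each = h), nrow = h)
  y <- matrix(rep(0:(h - 1L), times = w), nrow = h)
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  r <- sqrt((x - cx)^2 + (y - cy)^2)

  shrink <- 1 - spec$atrophy
  gm_thick <- spec$gm_band * shrink
  csf_thick <- spec$csf_rim + spec$gm_band * spec$atrophy
  r_gm_outer <- spec$brain_radius - csf_thick
  r_wm_outer <- r_gm_outer - gm_thick

  labels <- matrix(lv[["background"]], h, w)
  labels[r <= spec$brain_radius] <- lv[["csf"]]
  labels[r <= r_gm_outer] <- lv[["gm"]]
  labels[r <= r_wm_outer] <- lv[["wm"]]

  paint_roi_pool <- function(labels, rect) {
    labels[(rect$y1 + 1L):rect$y2, (rect$x1 + 1L):rect$x2] <- lv[["csf"]]
    labels
  }
  paint_ellipse <- function(labels, center, axes) {
    inside <- ((x - center[1]) / axes[1])^2 + ((y - center[2]) / axes[2])^2 <= 1
    labels[inside] <- lv[["gm"]]
    list(labels = labels, area = sum(inside))
  }
  axes <- spec$hippo_semi_axes * shrink
  labels <- paint_roi_pool(labels, spec$masks$left)
  labels <- paint_roi_pool(labels, spec$masks$right)
  left <- paint_ellipse(labels, spec$hippo_left_center, axes)
  right <- paint_ellipse(left$labels, spec$hippo_right_center, axes)
  labels <- right$labels

  means <- c(0, spec$intensity_csf, spec$intensity_gm, spec$intensity_wm)
  image <- matrix(means[labels + 1L], h, w)
  brain <- r <= spec$brain_radius

  if (spec$bias_amplitude > 0) {
    field <- 1 + spec$bias_amplitude *
      cos(2 * pi * x / w) * cos(2 * pi * y / h)
    image[brain] <- image[brain] * field[brain]
  }
  if (spec$noise_sd > 0) {
    noise <- withr::with_seed(seed, stats::rnorm(sum(brain), 0, spec$noise_sd))
    image[brain] <- image[brain] + noise
    # keep in-brain pixels positive so intensity-0 background detection holds
    image[brain] <- pmax(image[brain], 1e-3)
  }
  attr(image, "brain_mask") <- brain

  structure(
    list(image = image,
         truth = list(label_map = new_tissue_label_map(labels, thresh = NULL),
                      hippo_left_area = left$area,
                      hippo_right_area = right$area,
                      class_label = class_label,
                      atrophy = spec$atrophy)),
    class = "phantom_slice")
}

#' Generate repeated scans of the same anatomy
#'
#' Emulates taking several scans of one subject in a single session for
#' motion-correction-by-averaging: all repeats share identical noiseless
#' anatomy (and bias field) but carry independent noise realizations. Repeat
#' `i` uses seed `seed + i - 1`, so a stack of one reproduces
#' [generate_slice()] for the same seed exactly.
#'
#' @inheritParams generate_slice
#' @param n_repeats Number of repeat scans, `>= 1`.
#' @return A list of image matrices with a shared `truth` attribute.
#' @seealso [average_scans()]
#' @export
generate_repeat_stack <- function(spec, n_repeats, seed) {
  n_repeats <- as.integer(n_repeats)
  if (is.na(n_repeats) || n_repeats < 1L) {
    stop("generate_repeat_stack: n_repeats must be >= 1")
  }
  slices <- lapply(seq_len(n_repeats) - 1L,
                   function(i) generate_slice(spec, seed + i))
  stack <- lapply(slices, `[[`, "image")
  attr(stack, "truth") <- slices[[1L]]$truth
  stack
}

#' Specify a synthetic two-group cohort
#'
#' Defines an AD / control cohort in which each subject's atrophy factor is
#' drawn from a truncated normal distribution (truncated to `[0, 1)`) with a
#' group-specific mean, mirroring the structure of a case-control MRI study.
#'
#' @param n_ad,n_control Subject counts (>= 0).
#' @param atrophy_ad_mean,atrophy_control_mean Group means of the atrophy
#'   factor (unitless).
#' @param atrophy_sd Common within-group standard deviation of atrophy.
#' @param seed Integer seed from which all per-subject randomness is derived.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_ad = 37L, n_control = 48L,
                        atrophy_ad_mean = 0.3, atrophy_control_mean = 0.05,
                        atrophy_sd = 0.05, seed = 1L) {
  n_ad <- as.integer(n_ad); n_control <- as.integer(n_control)
  if (n_ad < 0L || n_control < 0L) {
    stop("cohort_spec: subject counts must be >= 0")
  }
  if (atrophy_sd < 0) stop("cohort_spec: atrophy_sd must be >= 0")
  structure(list(n_ad = n_ad, n_control = n_control,
                 atrophy_ad_mean = atrophy_ad_mean,
                 atrophy_control_mean = atrophy_control_mean,
                 atrophy_sd = atrophy_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

# normal truncated to [0, 1) by rejection; sd = 0 degenerates to the mean
rtruncnorm01 <- function(n, mean, sd) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) {
    if (mean < 0 || mean >= 1) stop("atrophy mean outside [0, 1) with sd = 0")
    return(rep(mean, n))
  }
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    draw <- stats::rnorm(length(todo), mean, sd)
    ok <- draw >= 0 & draw < 1
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

#' Generate a synthetic cohort of brain slices
#'
#' Draws per-subject atrophy factors from the group distributions in `cspec`,
#' renders one slice per subject from `base` (all other phantom parameters
#' shared), and labels AD subjects +1 and controls -1. Deterministic in
#' `cspec$seed`.
#'
#' @param cspec A [cohort_spec()].
#' @param base A [phantom_spec()] providing the shared anatomy and noise
#'   settings; its `atrophy` field is overridden per subject.
#' @return A list of class `phantom_cohort`; each element is a
#'   `phantom_slice` with `subject_id` and per-subject atrophy recorded in
#'   its truth. `tidy()` turns it into a subject-level tibble.
#' @export
generate_cohort <- function(cspec, base = phantom_spec()) {
  stopifnot(inherits(cspec, "cohort_spec"), inherits(base, "phantom_spec"))
  n <- cspec$n_ad + cspec$n_control
  draws <- withr::with_seed(cspec$seed, {
    list(atrophy = c(rtruncnorm01(cspec$n_ad, cspec$atrophy_ad_mean,
                                  cspec$atrophy_sd),
                     rtruncnorm01(cspec$n_control, cspec$atrophy_control_mean,
                                  cspec$atrophy_sd)),
         seeds = sample.int(.Machine$integer.max - 1L, n))
  })
  labels <- c(rep(1L, cspec$n_ad), rep(-1L, cspec$n_control))
  cohort <- vector("list", n)
  for (i in seq_len(n)) {
    spec_i <- base
    spec_i$atrophy <- draws$atrophy[i]
    validate_phantom_spec(spec_i)
    sl <- generate_slice(spec_i, seed = draws$seeds[i],
                         class_label = labels[i])
    sl$subject_id <- sprintf("S%03d", i)
    cohort[[i]] <- sl
  }
  structure(cohort, class = "phantom_cohort")
}

#' @method tidy phantom_cohort
#' @export
tidy.phantom_cohort <- function(x, ...) {
  purrr::map_dfr(x, function(sl) {
    tibble::tibble(subject_id = sl$subject_id,
                   class_label = sl$truth$class_label,
                   atrophy = sl$truth$atrophy,
                   hippo_left_area = sl$truth$hippo_left_area,
                   hippo_right_area = sl$truth$hippo_right_area)
  })
}

#' Generate a bare Gaussian feature table
#'
#' Draws the five pipeline features (GM/WM/CSF volumes, left/right
#' hippocampal areas) directly from class-conditional Gaussians, bypassing
#' the imaging stages. Useful for isolating the classification layer: with
#' identical class means any classifier should sit at chance, and with
#' well-separated means it should approach perfect accuracy.
#'
#' @param n_per_class Subjects per class (>= 1).
#' @param mean_ad,mean_control Numeric length-5 class mean vectors in the
#'   feature order `vol_gm, vol_wm, vol_csf, left_area, right_area`.
#' @param sds Numeric length-5 vector of common within-class standard
#'   deviations; all must be positive.
#' @param seed Integer seed.
#' @return A tibble with columns `subject_id`, the five features and `label`
#'   (+1 AD, -1 control).
#' @export
generate_feature_table <- function(n_per_class,
                                   mean_ad, mean_control,
                                   sds = rep(1, 5), seed = 1L) {
  n_per_class <- as.integer(n_per_class)
  if (n_per_class < 1L) stop("generate_feature_table: n_per_class must be >= 1")
  stopifnot(length(mean_ad) == 5L, length(mean_control) == 5L,
            length(sds) == 5L)
  if (any(sds <= 0)) stop("generate_feature_table: all sds must be positive")
  feat <- c("vol_gm", "vol_wm", "vol_csf", "left_area", "right_area")
  draw <- function(mu) {
    vapply(seq_along(feat),
           function(j) stats::rnorm(n_per_class, mu[j], sds[j]),
           numeric(n_per_class))
  }
  mats <- withr::with_seed(seed, list(ad = draw(mean_ad),
                                      ctrl = draw(mean_control)))
  tab <- rbind(mats$ad, mats$ctrl)
  colnames(tab) <- feat
  tibble::as_tibble(tab) |>
    dplyr::mutate(
      subject_id = sprintf("S%03d", dplyr::row_number()),
      label = rep(c(1L, -1L), each = n_per_class),
      .before = 1)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %dx%d, CSF/GM/WM = %g/%g/%g, noise_sd = %g, atrophy = %g\n",
              x$width, x$height, x$intensity_csf, x$intensity_gm,
              x$intensity_wm, x$noise_sd, x$atrophy))
  invisible(x)
}

#' @export
print.phantom_slice <- function(x, ...) {
  cat(sprintf("<phantom_slice> %dx%d, hippo areas L/R = %d/%d px, label = %s\n",
              nrow(x$image), ncol(x$image),
              x$truth$hippo_left_area, x$truth$hippo_right_area,
              as.character(x$truth$class_label)))
  invisible(x)
}
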