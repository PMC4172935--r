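#' Read a 2D slice from NIfTI/Analyze, PNG or TIFF
#'
#' NIfTI and Analyze volumes are read with RNifti; for 3D volumes a single
#' slice is taken along `slice_axis` (default 2, the coronal axis of an
#' x/y/z volume) at `slice_index` (default the middle slice). PNG and TIFF
#' images are read as grayscale and rescaled to the nominal 0-255 gray-level
#' scale used throughout the package.
#'
#' @param path Input file (`.nii`, `.nii.gz`, `.hdr`, `.img`, `.png`,
#'   `.tif`, `.tiff`).
#' @param slice_axis Axis (1-3) along which to slice a 3D volume.
#' @param slice_index 1-based slice index; `NULL` takes the middle slice.
#' @return A numeric image matrix.
#' @export
read_slice <- function(path, slice_axis = 2L, slice_index = NULL) {
  if (!file.exists(path)) stop("read_slice: file not found: ", path)
  ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
  if (ext %in% c("nii", "hdr", "img")) {
    vol <- as.array(RNifti::readNifti(path))
    vol <- array(as.numeric(vol), dim = dim(vol)) # drop NIfTI attributes
    nd <- length(dim(vol))
    if (nd == 2L) return(vol)
    if (nd >= 4L) vol <- array(vol, dim = dim(vol)[1:3])
    slice_axis <- as.integer(slice_axis)
    if (!slice_axis %in% 1:3) stop("read_slice: slice_axis must be 1, 2 or 3")
    n <- dim(vol)[slice_axis]
    if (is.null(slice_index)) slice_index <- (n + 1L) %/% 2L
    if (slice_index < 1L || slice_index > n) {
      stop("read_slice: slice_index out of range")
    }
    return(switch(slice_axis,
                  vol[slice_index, , ],
                  vol[, slice_index, ],
                  vol[, , slice_index]))
  }
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    return(img * 255)
  }
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    return(img * 255)
  }
  stop("read_slice: unsupported file type: ", path)
}

#' Write a slice as NIfTI or 16-bit TIFF
#'
#' NIfTI output stores the raw intensities losslessly as a single-slice
#' volume. TIFF output is written at 16 bits per sample with intensities
#' scaled from the nominal `[0, max_intensity]` gray-level range.
#'
#' @param image Image matrix.
#' @param path Output path ending in `.nii`, `.nii.gz`, `.tif` or `.tiff`.
#' @param max_intensity Full-scale gray level for TIFF quantization
#'   (default 255).
#' @return `path`, invisibly.
#' @export
write_slice <- function(image, path, max_intensity = 255) {
  ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
  if (ext == "nii") {
    vol <- array(as.numeric(image), dim = c(dim(image), 1L))
    RNifti::writeNifti(RNifti::asNifti(vol), path)
  } else if (ext %in% c("tif", "tiff")) {
    scaled <- pmin(pmax(image / max_intensity, 0), 1)
    tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
  } else {
    stop("write_slice: unsupported file type: ", path)
  }
  invisible(path)
}

#' Write a tissue label map as an indexed grayscale PNG
#'
#' Background, CSF, GM and WM are written as evenly spaced gray levels
#' (0, 1/3, 2/3, 1).
#'
#' @param label_map A `tissue_label_map`.
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_label_png <- function(label_map, path) {
  stopifnot(inherits(label_map, "tissue_label_map"))
  png::writePNG(label_map$labels / 3, path)
  invisible(path)
}

#' Write a synthetic cohort to disk
#'
#' Writes one NIfTI slice (and optionally a 16-bit TIFF copy) per subject, a
#' label-map PNG per subject, and `truth.csv` with the ground-truth areas and
#' class labels.
#'
#' @param cohort A `phantom_cohort`.
#' @param dir Output directory (created if needed).
#' @param tiff Also write 16-bit TIFF copies (default `FALSE`).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, tiff = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sl in cohort) {
    write_slice(sl$image, file.path(dir, paste0(sl$subject_id, ".nii")))
    if (tiff) {
      write_slice(sl$image, file.path(dir, paste0(sl$subject_id, ".tif")))
    }
    write_label_png(sl$truth$label_map,
                    file.path(dir, paste0(sl$subject_id, "_labels.png")))
  }
  readr::write_csv(tidy.phantom_cohort(cohort), file.path(dir, "truth.csv"))
  invisible(dir)
}

#' Pipeline configuration
#'
#' Collects every setting of an end-to-end run: either a directory of
#' preprocessed input slices with a `labels.csv` (columns `subject_id`,
#' `label` in +1/-1), or the parameters of a simulated cohort; the threshold
#' mode; the hippocampus-stage parameters; and the cross-validation settings.
#'
#' @param out_dir Output directory for features, report and log.
#' @param input_dir Optional directory of input slices (`.nii`, `.png`,
#'   `.tif`) plus `labels.csv`; when `NULL` a cohort is simulated.
#' @param n_ad,n_control,atrophy_ad,atrophy_control,atrophy_sd,noise_sd,bias
#'   Simulation settings (see [cohort_spec()] and [phantom_spec()]).
#' @param width,height Simulated slice size.
#' @param thresh `"auto"` (per-slice), `"global"` (estimated once) or a
#'   numeric `c(lo, hi)`.
#' @param opening_radius,margin Hippocampus-stage parameters.
#' @param k,subset Cross-validation folds and feature subset.
#' @param seed Integer master seed.
#' @param save_images Also write the simulated slices to `out_dir`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, input_dir = NULL,
                            n_ad = 37L, n_control = 48L,
                            atrophy_ad = 0.3, atrophy_control = 0.05,
                            atrophy_sd = 0.05, noise_sd = 8, bias = 0,
                            width = 498L, height = 498L,
                            thresh = "auto", opening_radius = 1L, margin = 2L,
                            k = 10L, subset = "all", seed = 1L,
                            save_images = FALSE) {
  structure(list(out_dir = out_dir, input_dir = input_dir,
                 n_ad = n_ad, n_control = n_control,
                 atrophy_ad = atrophy_ad, atrophy_control = atrophy_control,
                 atrophy_sd = atrophy_sd, noise_sd = noise_sd, bias = bias,
                 width = width, height = height, thresh = thresh,
                 opening_radius = opening_radius, margin = margin,
                 k = k, subset = subset, seed = as.integer(seed),
                 save_images = isTRUE(save_images)),
            class = "pipeline_config")
}

read_input_cohort <- function(input_dir) {
  if (!dir.exists(input_dir)) {
    stop("run_pipeline: input directory does not exist: ", input_dir)
  }
  labels_path <- file.path(input_dir, "labels.csv")
  if (!file.exists(labels_path)) {
    stop("run_pipeline: missing labels.csv in ", input_dir)
  }
  labels <- readr::read_csv(labels_path, show_col_types = FALSE)
  purrr::pmap(labels, function(subject_id, label, ...) {
    candidates <- file.path(input_dir,
                            paste0(subject_id, c(".nii", ".nii.gz",
                                                 ".png", ".tif", ".tiff")))
    hit <- candidates[file.exists(candidates)]
    if (length(hit) == 0L) {
      stop("run_pipeline: no image found for subject ", subject_id)
    }
    list(image = read_slice(hit[1L]), subject_id = subject_id,
         truth = list(class_label = as.integer(label)))
  })
}

#' Run the full pipeline
#'
#' Executes simulation (or ingestion) -> tissue segmentation -> volumetry ->
#' hippocampus extraction -> feature assembly -> stratified k-fold
#' cross-validation, writing `features.csv`, `report.json` and `log.json`
#' into the output directory. Fully deterministic under a fixed
#' configuration and seed.
#'
#' @param config A [pipeline_config()].
#' @return The [crossvalidate()] `evaluation_report`, with the feature table
#'   attached as attribute `features`, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- if (!is.null(config$input_dir)) {
    read_input_cohort(config$input_dir)
  } else {
    base <- phantom_spec(width = config$width, height = config$height,
                         noise_sd = config$noise_sd,
                         bias_amplitude = config$bias)
    generate_cohort(cohort_spec(n_ad = config$n_ad,
                                n_control = config$n_control,
                                atrophy_ad_mean = config$atrophy_ad,
                                atrophy_control_mean = config$atrophy_control,
                                atrophy_sd = config$atrophy_sd,
                                seed = config$seed),
                    base)
  }
  if (config$save_images && inherits(cohort, "phantom_cohort")) {
    write_cohort(cohort, file.path(config$out_dir, "slices"))
  }

  th <- config$thresh
  th_arg <- if (is.numeric(th) && length(th) == 2L) {
    thresh_range(th[1L], th[2L])
  } else if (identical(th, "global")) "global" else NULL

  features <- extract_features(cohort, thresh = th_arg,
                               opening_radius = config$opening_radius,
                               margin = config$margin)
  readr::write_csv(features, file.path(config$out_dir, "features.csv"))

  report <- crossvalidate(features, k = config$k, seed = config$seed,
                          subset = config$subset)
  jsonlite::write_json(
    list(metrics = report$metrics, predictions = report$predictions,
         k = report$k, seed = report$seed, subset = report$subset),
    file.path(config$out_dir, "report.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(config)[!vapply(unclass(config), is.null,
                                               logical(1))],
                       file.path(config$out_dir, "log.json"),
                       auto_unbox = TRUE, digits = NA)
  attr(report, "features") <- features
  invisible(report)
}
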