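#' Extract the five pipeline features from a cohort of slices
#'
#' For each subject: estimate (or apply) the GM threshold range, segment the
#' slice into CSF/GM/WM, count tissue pixels, run the hippocampus chain on
#' both ROIs and measure the two areas. Produces the feature table consumed
#' by [crossvalidate()].
#'
#' @param cohort A `phantom_cohort` (see [generate_cohort()]) or a list of
#'   elements with fields `image`, `subject_id` and optionally
#'   `truth$class_label`.
#' @param thresh `NULL` (per-slice estimation via [estimate_thresh()]), a
#'   single [thresh_range()] applied globally, or `"global"` to estimate one
#'   range from the first subject and reuse it.
#' @param opening_radius,margin Hippocampus-stage parameters.
#' @return A tibble with columns `subject_id`, `vol_gm`, `vol_wm`,
#'   `vol_csf`, `left_area`, `right_area` and `label` (when labels are
#'   available).
#' @export
extract_features <- function(cohort, thresh = NULL,
                             opening_radius = 1L, margin = 2L) {
  if (!is.list(cohort) || length(cohort) == 0L) {
    stop("extract_features: cohort must be a non-empty list of slices")
  }
  global <- NULL
  if (is.character(thresh) && identical(thresh, "global")) {
    global <- estimate_thresh(cohort[[1L]]$image)
  } else if (inherits(thresh, "thresh_range")) {
    global <- thresh
  } else if (!is.null(thresh)) {
    stop("extract_features: thresh must be NULL, \"global\" or a thresh_range")
  }
  purrr::imap_dfr(cohort, function(sl, i) {
    img <- sl$image
    th <- if (is.null(global)) estimate_thresh(img) else global
    seg <- segment_tissues(img, th)
    vols <- tissue_volumes(seg)
    pair <- hippocampus_pipeline(img, thresh = th,
                                 opening_radius = opening_radius,
                                 margin = margin)
    tibble::tibble(
      subject_id = sl$subject_id %||% sprintf("S%03d", i),
      vol_gm = vols$vol_gm, vol_wm = vols$vol_wm, vol_csf = vols$vol_csf,
      left_area = pair$left$area, right_area = pair$right$area,
      label = sl$truth$class_label %||% NA_integer_)
  })
}
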