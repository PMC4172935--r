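#' Tissue volumes from one or more label maps
#'
#' Sums per-class pixel counts over slices: the WM/GM/CSF "volumes" are the
#' total numbers of pixels labelled WM, GM and CSF across the supplied label
#' maps. Counts are raw pixels; multiply by `voxel_volume` for physical
#' units.
#'
#' @param label_maps A single `tissue_label_map` or a non-empty list of them
#'   (one per slice).
#' @param voxel_volume Optional scale factor (e.g. mm^3 per voxel) applied to
#'   the three counts; default 1 leaves raw pixel counts.
#' @return A one-row tibble with columns `vol_gm`, `vol_wm`, `vol_csf`,
#'   `n_slices`.
#' @export
tissue_volumes <- function(label_maps, voxel_volume = 1) {
  if (inherits(label_maps, "tissue_label_map")) label_maps <- list(label_maps)
  if (!is.list(label_maps) || length(label_maps) == 0L) {
    stop("tissue_volumes: need at least one tissue_label_map")
  }
  if (!all(vapply(label_maps, inherits, logical(1), "tissue_label_map"))) {
    stop("tissue_volumes: all elements must be tissue_label_map objects")
  }
  lv <- tissue_levels()
  count <- function(code) {
    sum(vapply(label_maps, function(m) sum(m$labels == code), integer(1)))
  }
  tibble::tibble(vol_gm = count(lv[["gm"]]) * voxel_volume,
                 vol_wm = count(lv[["wm"]]) * voxel_volume,
                 vol_csf = count(lv[["csf"]]) * voxel_volume,
                 n_slices = length(label_maps))
}
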