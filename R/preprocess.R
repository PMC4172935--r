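#' Intensity threshold range bracketing grey matter
#'
#' A closed gray-level interval `[lo, hi]` describing the GM class:
#' intensities strictly below `lo` are CSF, within `[lo, hi]` GM, strictly
#' above `hi` WM. This is the only consistent reading of a range-valued
#' threshold compared with `<`, `==`, `>`.
#'
#' @param lo,hi Gray levels with `lo <= hi`.
#' @return An object of class `thresh_range`.
#' @export
thresh_range <- function(lo, hi) {
  stopifnot(is.numeric(lo), is.numeric(hi), length(lo) == 1, length(hi) == 1)
  if (!is.finite(lo) || !is.finite(hi) || lo > hi) {
    stop("thresh_range: need finite lo <= hi")
  }
  structure(list(lo = lo, hi = hi), class = "thresh_range")
}

#' @export
print.thresh_range <- function(x, ...) {
  cat(sprintf("<thresh_range> GM in [%.3f, %.3f]\n", x$lo, x$hi))
  invisible(x)
}

brain_mask_of <- function(image, mask = NULL) {
  if (is.null(mask)) mask <- attr(image, "brain_mask")
  if (is.null(mask)) mask <- image > 0
  if (!identical(dim(mask), dim(image))) {
    stop("brain mask dimensions do not match the image")
  }
  mask
}

#' Average repeated scans of one subject
#'
#' Motion correction by averaging: the per-pixel arithmetic mean of k
#' pre-aligned repeat scans, which reduces additive noise by a factor of
#' `sqrt(k)`. No registration is performed; scans are assumed already
#' aligned. When brain masks are present their intersection is carried over.
#'
#' @param stack Non-empty list of image matrices of identical dimensions
#'   (e.g. from [generate_repeat_stack()]).
#' @return The mean image matrix.
#' @export
average_scans <- function(stack) {
  if (!is.list(stack) || length(stack) == 0L) {
    stop("average_scans: stack must be a non-empty list of images")
  }
  dims <- lapply(stack, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1L]]))) {
    stop("average_scans: all scans must share the same dimensions")
  }
  out <- Reduce(`+`, stack) / length(stack)
  masks <- lapply(stack, attr, "brain_mask")
  if (!any(vapply(masks, is.null, logical(1)))) {
    attr(out, "brain_mask") <- Reduce(`&`, masks)
  }
  out
}

#' Estimate the GM threshold range from an image
#'
#' Chooses the two cut points of a three-class partition of the in-brain
#' intensity histogram by exhaustively maximizing the between-class variance
#' over all cut-point pairs (a three-class Otsu criterion on a 256-bin
#' histogram). The returned range brackets the middle (GM) class. A
#' user-supplied [thresh_range()] always overrides estimation downstream.
#'
#' @param image Image matrix; pixels outside the brain mask (attribute
#'   `brain_mask`, else intensity > 0) are ignored.
#' @param mask Optional logical matrix overriding the brain mask.
#' @param n_bins Number of histogram bins (default 256).
#' @return A [thresh_range()].
#' @export
estimate_thresh <- function(image, mask = NULL, n_bins = 256L) {
  mask <- brain_mask_of(image, mask)
  v <- image[mask]
  if (length(unique(v)) < 3L) {
    stop("estimate_thresh: fewer than 3 distinct in-mask intensities; ",
         "supply a manual thresh_range")
  }
  rng <- range(v)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  mids <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2

  # cumulative moments; class k over bins (cut_{k-1}, cut_k]
  W <- cumsum(counts)
  M <- cumsum(counts * mids)
  n <- W[n_bins]; total_mean <- M[n_bins] / n

  # candidate cuts t1 < t2 over bin indices 1..n_bins-1
  t1 <- seq_len(n_bins - 2L)
  best <- list(score = -Inf, t1 = NA_integer_, t2 = NA_integer_)
  for (i in t1) {
    w1 <- W[i]; m1 <- M[i]
    j <- (i + 1L):(n_bins - 1L)
    w2 <- W[j] - w1; m2 <- M[j] - m1
    w3 <- n - W[j]; m3 <- M[n_bins] - M[j]
    score <- rep(-Inf, length(j))
    ok <- w1 > 0 & w2 > 0 & w3 > 0
    score[ok] <- (m1^2 / w1 + (m2^2 / w2)[ok] + (m3^2 / w3)[ok]) / n -
      total_mean^2
    k <- which.max(score)
    if (length(k) && score[k] > best$score) {
      best <- list(score = score[k], t1 = i, t2 = j[k])
    }
  }
  if (!is.finite(best$score)) {
    stop("estimate_thresh: degenerate histogram; supply a manual thresh_range")
  }
  thresh_range(edges[best$t1 + 1L], edges[best$t2 + 1L])
}

#' Segment a slice into CSF, GM and WM by intensity thresholding
#'
#' Applies the three-way rule against a GM threshold range: within the brain
#' mask, intensity `< lo` is CSF, within `[lo, hi]` GM, `> hi` WM; pixels
#' outside the mask are background. When no mask is available, pixels of
#' intensity exactly 0 are treated as non-brain (the convention of
#' brain-extracted images) and all others are classified.
#'
#' @param image Image matrix.
#' @param thresh A [thresh_range()].
#' @param mask Optional logical brain mask.
#' @return An object of class `tissue_label_map`: list with `labels` (integer
#'   matrix coded per [tissue_levels()]) and `thresh`.
#' @export
segment_tissues <- function(image, thresh, mask = NULL) {
  stopifnot(inherits(thresh, "thresh_range"))
  mask <- brain_mask_of(image, mask)
  lv <- tissue_levels()
  labels <- matrix(lv[["background"]], nrow(image), ncol(image))
  labels[mask & image < thresh$lo] <- lv[["csf"]]
  labels[mask & image >= thresh$lo & image <= thresh$hi] <- lv[["gm"]]
  labels[mask & image > thresh$hi] <- lv[["wm"]]
  new_tissue_label_map(labels, thresh)
}

new_tissue_label_map <- function(labels, thresh) {
  structure(list(labels = labels, thresh = thresh),
            class = "tissue_label_map")
}

#' @export
print.tissue_label_map <- function(x, ...) {
  lv <- tissue_levels()
  counts <- vapply(lv, function(code) sum(x$labels == code), integer(1))
  cat(sprintf("<tissue_label_map> %dx%d: bg %d, CSF %d, GM %d, WM %d\n",
              nrow(x$labels), ncol(x$labels),
              counts[1], counts[2], counts[3], counts[4]))
  invisible(x)
}
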