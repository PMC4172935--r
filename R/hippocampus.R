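#' Rectangular region of interest in slice coordinates
#'
#' Coordinates are (column, row) = (x, y), 0-based, half-open:
#' the rectangle covers pixels with `x1 <= x < x2` and `y1 <= y < y2`.
#' This convention reproduces the published hippocampal corner coordinates
#' on the 498x498 normalized frame without off-by-one ambiguity.
#'
#' @param x1,y1 Top-left corner (inclusive).
#' @param x2,y2 Bottom-right corner (exclusive).
#' @return An object of class `roi_rect`.
#' @export
roi_rect <- function(x1, y1, x2, y2) {
  x1 <- as.integer(x1); y1 <- as.integer(y1)
  x2 <- as.integer(x2); y2 <- as.integer(y2)
  if (anyNA(c(x1, y1, x2, y2)) || x1 < 0L || y1 < 0L || x1 >= x2 || y1 >= y2) {
    stop("roi_rect: need 0 <= x1 < x2 and 0 <= y1 < y2")
  }
  structure(list(x1 = x1, y1 = y1, x2 = x2, y2 = y2), class = "roi_rect")
}

#' @export
print.roi_rect <- function(x, ...) {
  cat(sprintf("<roi_rect> [%d, %d) x [%d, %d)  (%dx%d px)\n",
              x$x1, x$x2, x$y1, x$y2, x$x2 - x$x1, x$y2 - x$y1))
  invisible(x)
}

round_half_up <- function(x) floor(x + 0.5)

#' Standard hippocampal ROI rectangles
#'
#' Returns the fixed rectangular masks bounding the left and right
#' hippocampus in a spatially normalized 498x498 coronal slice: left
#' corners (130, 300)-(225, 360), right corners (280, 300)-(375, 360),
#' read as (column, row), 0-based, half-open. For other image sizes the
#' rectangles are scaled proportionally and rounded half-up to integers.
#'
#' @param image_width,image_height Slice dimensions in pixels.
#' @return A list with `roi_rect` elements `left` and `right`.
#' @export
default_masks <- function(image_width, image_height) {
  image_width <- as.integer(image_width); image_height <- as.integer(image_height)
  if (image_width < 2L || image_height < 2L) {
    stop("default_masks: image must be at least 2x2 pixels")
  }
  sx <- image_width / 498; sy <- image_height / 498
  scale_rect <- function(x1, y1, x2, y2) {
    roi_rect(round_half_up(x1 * sx), round_half_up(y1 * sy),
             round_half_up(x2 * sx), round_half_up(y2 * sy))
  }
  list(left = scale_rect(130, 300, 225, 360),
       right = scale_rect(280, 300, 375, 360))
}

#' Extract a rectangular ROI from a slice
#'
#' @param image Image matrix (rows = y, columns = x).
#' @param rect A [roi_rect()] fully inside the image.
#' @return The sub-image matrix; a `brain_mask` attribute, when present, is
#'   cropped alongside.
#' @export
extract_roi <- function(image, rect) {
  stopifnot(inherits(rect, "roi_rect"))
  if (rect$x2 > ncol(image) || rect$y2 > nrow(image)) {
    stop("extract_roi: rectangle exceeds image bounds")
  }
  out <- image[(rect$y1 + 1L):rect$y2, (rect$x1 + 1L):rect$x2, drop = FALSE]
  bm <- attr(image, "brain_mask")
  if (!is.null(bm)) {
    attr(out, "brain_mask") <-
      bm[(rect$y1 + 1L):rect$y2, (rect$x1 + 1L):rect$x2, drop = FALSE]
  }
  out
}

# 8-connected component labelling by BFS; intended for ROI-sized masks.
label_components8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(0L, h, w)
  cur <- 0L
  for (p in which(mask)) {
    if (labels[p] > 0L) next
    cur <- cur + 1L
    labels[p] <- cur
    frontier <- p
    while (length(frontier)) {
      r <- ((frontier - 1L) %% h) + 1L
      c <- ((frontier - 1L) %/% h) + 1L
      nxt <- integer(0)
      for (dr in -1L:1L) {
        for (dc in -1L:1L) {
          if (dr == 0L && dc == 0L) next
          rr <- r + dr; cc <- c + dc
          ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
          nb <- (cc[ok] - 1L) * h + rr[ok]
          nb <- nb[mask[nb] & labels[nb] == 0L]
          if (length(nb)) {
            labels[nb] <- cur
            nxt <- c(nxt, nb)
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  labels
}

# keep the largest 8-connected component; ties broken by the smallest
# top-left bounding-box corner (row, then column)
largest_component <- function(mask) {
  labels <- label_components8(mask)
  n <- max(labels)
  if (n == 0L) return(matrix(FALSE, nrow(mask), ncol(mask)))
  sizes <- tabulate(labels[labels > 0L], nbins = n)
  cand <- which(sizes == max(sizes))
  if (length(cand) > 1L) {
    corner <- t(vapply(cand, function(l) {
      ij <- which(labels == l, arr.ind = TRUE)
      c(min(ij[, 1L]), min(ij[, 2L]))
    }, integer(2)))
    cand <- cand[order(corner[, 1L], corner[, 2L])][1L]
  }
  labels == cand
}

#' Remove non-hippocampal structures from an ROI
#'
#' Binarizes the ROI at the tissue threshold (`intensity >= thresh$lo`,
#' i.e. tissue versus CSF/background), morphologically opens the binary
#' image with a disc structuring element, and keeps only the largest
#' 8-connected object — the candidate hippocampal body. Smaller objects
#' (noise specks, stray structures) are discarded.
#'
#' @param roi ROI image matrix (from [extract_roi()]).
#' @param thresh A [thresh_range()].
#' @param opening_radius Disc radius in pixels (default 1); 0 skips the
#'   opening.
#' @return Logical matrix: the retained component. All-`FALSE` (with a
#'   warning) when nothing survives the opening.
#' @export
remove_noise <- function(roi, thresh, opening_radius = 1L) {
  stopifnot(inherits(thresh, "thresh_range"))
  if (length(roi) == 0L) stop("remove_noise: empty ROI")
  binary <- roi >= thresh$lo
  if (opening_radius > 0) {
    kern <- EBImage::makeBrush(2L * as.integer(opening_radius) + 1L, "disc")
    opened <- EBImage::opening(binary * 1, kern) > 0.5
  } else {
    opened <- binary
  }
  comp <- largest_component(opened)
  if (!any(comp)) {
    warning("remove_noise: no object survived the opening; empty mask")
  }
  comp
}

#' Trim an ROI to the neighbourhood of the retained component
#'
#' Crops the ROI (and component mask) to the bounding box of the largest
#' component, expanded by a fixed margin and clipped to the ROI bounds;
#' pixels outside the retained component are set to the background value 0
#' so that border structures cannot leak into the area measurement.
#'
#' @param roi ROI image matrix.
#' @param cleaned Logical component mask from [remove_noise()], same
#'   dimensions as `roi`.
#' @param margin Margin in pixels around the bounding box (default 2).
#' @return The trimmed image matrix with the cropped component mask attached
#'   as attribute `component`; a 0x0 matrix when `cleaned` is empty.
#' @export
trim_region <- function(roi, cleaned, margin = 2L) {
  if (!identical(dim(roi), dim(cleaned))) {
    stop("trim_region: roi and cleaned mask dimensions differ")
  }
  if (!any(cleaned)) {
    out <- matrix(numeric(0), 0L, 0L)
    attr(out, "component") <- matrix(FALSE, 0L, 0L)
    return(out)
  }
  ij <- which(cleaned, arr.ind = TRUE)
  r1 <- max(1L, min(ij[, 1L]) - margin); r2 <- min(nrow(roi), max(ij[, 1L]) + margin)
  c1 <- max(1L, min(ij[, 2L]) - margin); c2 <- min(ncol(roi), max(ij[, 2L]) + margin)
  out <- roi[r1:r2, c1:c2, drop = FALSE]
  comp <- cleaned[r1:r2, c1:c2, drop = FALSE]
  out[!comp] <- 0
  attr(out, "component") <- comp
  out
}

#' Separate the hippocampal body from a trimmed ROI
#'
#' The hippocampus is a GM structure surrounded by CSF, so within the
#' retained component it is exactly the set of pixels whose intensity falls
#' in the GM threshold range `[thresh$lo, thresh$hi]`.
#'
#' @param trimmed Trimmed image from [trim_region()].
#' @param thresh A [thresh_range()].
#' @return Logical hippocampus mask (possibly empty).
#' @export
extract_hippocampus <- function(trimmed, thresh) {
  stopifnot(inherits(thresh, "thresh_range"))
  if (length(trimmed) == 0L) return(matrix(FALSE, 0L, 0L))
  mask <- trimmed >= thresh$lo & trimmed <= thresh$hi
  comp <- attr(trimmed, "component")
  if (!is.null(comp)) mask <- mask & comp
  mask
}

#' Hippocampal area in pixels
#'
#' @param mask Logical hippocampus mask.
#' @return Integer count of `TRUE` pixels.
#' @export
hippocampus_area <- function(mask) {
  if (length(mask) == 0L) return(0L)
  as.integer(sum(mask))
}

run_hippo_side <- function(image, rect, thresh, side,
                           opening_radius = 1L, margin = 2L) {
  roi <- extract_roi(image, rect)
  cleaned <- remove_noise(roi, thresh, opening_radius)
  trimmed <- trim_region(roi, cleaned, margin)
  hmask <- extract_hippocampus(trimmed, thresh)
  structure(
    list(side = side, area = hippocampus_area(hmask), roi_used = rect,
         intermediate = list(roi = roi, cleaned = cleaned,
                             trimmed = trimmed, mask = hmask)),
    class = "hippocampus_result")
}

#' @export
print.hippocampus_result <- function(x, ...) {
  cat(sprintf("<hippocampus_result> %s: area %d px in ROI [%d,%d)x[%d,%d)\n",
              x$side, x$area, x$roi_used$x1, x$roi_used$x2,
              x$roi_used$y1, x$roi_used$y2))
  invisible(x)
}

#' Full hippocampus extraction chain for both sides
#'
#' Runs ROI masking, ROI extraction, noise removal (opening + largest
#' object), region trimming and GM-range separation for the left and right
#' hippocampus and measures their areas. An empty mask at any stage yields
#' area 0 with a warning rather than a failure.
#'
#' @param image Spatially normalized slice matrix.
#' @param thresh A [thresh_range()]; `NULL` estimates one via
#'   [estimate_thresh()].
#' @param masks List with `roi_rect` elements `left` and `right`; `NULL`
#'   uses [default_masks()] for the image size.
#' @param opening_radius,margin Stage parameters, see [remove_noise()] and
#'   [trim_region()].
#' @return List of class `hippocampus_pair` with `hippocampus_result`
#'   elements `left` and `right` (left first).
#' @seealso [measure_hippocampi()] for a tibble front end.
#' @export
hippocampus_pipeline <- function(image, thresh = NULL, masks = NULL,
                                 opening_radius = 1L, margin = 2L) {
  if (is.null(thresh)) thresh <- estimate_thresh(image)
  if (is.null(masks)) masks <- default_masks(ncol(image), nrow(image))
  structure(
    list(left = run_hippo_side(image, masks$left, thresh, "left",
                               opening_radius, margin),
         right = run_hippo_side(image, masks$right, thresh, "right",
                                opening_radius, margin),
         thresh = thresh),
    class = "hippocampus_pair")
}

#' Measure left and right hippocampal areas as a tibble
#'
#' Tidy front end to [hippocampus_pipeline()].
#'
#' @inheritParams hippocampus_pipeline
#' @return A two-row tibble with columns `side` and `area`.
#' @export
measure_hippocampi <- function(image, thresh = NULL, masks = NULL,
                               opening_radius = 1L, margin = 2L) {
  pair <- hippocampus_pipeline(image, thresh, masks, opening_radius, margin)
  tibble::tibble(side = c("left", "right"),
                 area = c(pair$left$area, pair$right$area))
}

#' Mirror a slice horizontally
#'
#' Flips the image left-right (column reversal); the brain mask attribute is
#' flipped alongside. Useful together with [mirror_rect()] for left/right
#' symmetry checks.
#'
#' @param image Image matrix.
#' @return The mirrored matrix.
#' @export
mirror_slice <- function(image) {
  out <- image[, ncol(image):1L, drop = FALSE]
  bm <- attr(image, "brain_mask")
  if (!is.null(bm)) attr(out, "brain_mask") <- bm[, ncol(bm):1L, drop = FALSE]
  out
}

#' Mirror an ROI rectangle horizontally
#'
#' @param rect A [roi_rect()].
#' @param image_width Width of the frame the rectangle lives in.
#' @return The mirrored `roi_rect`.
#' @export
mirror_rect <- function(rect, image_width) {
  stopifnot(inherits(rect, "roi_rect"))
  roi_rect(image_width - rect$x2, rect$y1, image_width - rect$x1, rect$y2)
}
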