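# Brute-force oracles, written independently of the package internals:
# plain loops straight from the definitions, used to freeze expected values.

# a fast small phantom for unit tests (third of the reference frame)
small_spec <- function(...) phantom_spec(width = 166L, height = 166L, ...)

# pixel count of the ellipse ((x-cx)/a)^2 + ((y-cy)/b)^2 <= 1 by full
# enumeration over the 0-based pixel grid
oracle_ellipse_area <- function(center, axes, width, height) {
  count <- 0L
  for (xx in 0:(width - 1L)) {
    for (yy in 0:(height - 1L)) {
      if (((xx - center[1]) / axes[1])^2 +
          ((yy - center[2]) / axes[2])^2 <= 1) {
        count <- count + 1L
      }
    }
  }
  count
}

# naive per-pixel triple comparison against the GM range
oracle_segment <- function(image, lo, hi, mask) {
  out <- matrix(0L, nrow(image), ncol(image))
  for (i in seq_len(nrow(image))) {
    for (j in seq_len(ncol(image))) {
      if (!mask[i, j]) next
      v <- image[i, j]
      out[i, j] <- if (v < lo) 1L else if (v <= hi) 2L else 3L
    }
  }
  out
}

# naive triple summation (slice, i, j) of per-class pixel counts
oracle_volumes <- function(label_list) {
  counts <- c(csf = 0L, gm = 0L, wm = 0L)
  for (m in label_list) {
    for (i in seq_len(nrow(m))) {
      for (j in seq_len(ncol(m))) {
        v <- m[i, j]
        if (v == 1L) counts[["csf"]] <- counts[["csf"]] + 1L
        if (v == 2L) counts[["gm"]] <- counts[["gm"]] + 1L
        if (v == 3L) counts[["wm"]] <- counts[["wm"]] + 1L
      }
    }
  }
  counts
}

# build a tissue_label_map with prescribed labels by segmenting a crafted
# image (0 bg, 20 CSF, 80 GM, 200 WM against the range [50, 150])
make_label_map <- function(labels) {
  img <- matrix(c(0, 20, 80, 200)[labels + 1L], nrow(labels), ncol(labels))
  segment_tissues(img, thresh_range(50, 150), mask = labels > 0L)
}

# literal decision rule: disease iff the +1 votes strictly outnumber half
# the voters
oracle_vote <- function(votes) {
  n_pos <- 0L
  for (v in votes) if (v == 1L) n_pos <- n_pos + 1L
  if (n_pos > length(votes) / 2) 1L else -1L
}

# all vote vectors of length n over {+1, -1}
all_vote_vectors <- function(n) {
  grid <- do.call(expand.grid, rep(list(c(-1L, 1L)), n))
  lapply(seq_len(nrow(grid)), function(i) as.integer(grid[i, ]))
}
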