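test_that("default masks reproduce the normalized-frame coordinates", {
  m <- default_masks(498, 498)
  expect_identical(unclass(m$left)[c("x1", "y1", "x2", "y2")],
                   list(x1 = 130L, y1 = 300L, x2 = 225L, y2 = 360L))
  expect_identical(unclass(m$right)[c("x1", "y1", "x2", "y2")],
                   list(x1 = 280L, y1 = 300L, x2 = 375L, y2 = 360L))
  expect_identical(m$left$x2 - m$left$x1, 95L)
  expect_identical(m$left$y2 - m$left$y1, 60L)
  expect_identical(m$right$x2 - m$right$x1, 95L)

  half <- default_masks(249, 249)
  expect_identical(unclass(half$left)[c("x1", "y1", "x2", "y2")],
                   list(x1 = 65L, y1 = 150L, x2 = 113L, y2 = 180L))
  expect_error(default_masks(1, 1), "2x2")
})

test_that("ROI extraction copies the rectangle with correct offsets", {
  withr::with_seed(2, img <- matrix(stats::runif(498 * 498), 498, 498))
  full <- roi_rect(0, 0, 498, 498)
  expect_identical(extract_roi(img, full), img)

  left <- default_masks(498, 498)$left
  sub <- extract_roi(img, left)
  expect_identical(dim(sub), c(60L, 95L))
  # output pixel (x1+3, y1+5) equals input pixel (133, 305), 0-based
  expect_identical(sub[5 + 1, 3 + 1], img[305 + 1, 133 + 1])
  expect_error(extract_roi(img, roi_rect(450, 450, 500, 500)), "bounds")
})

test_that("noise removal keeps the opened largest object only", {
  # 60x95 ROI: CSF background with a solid ellipse and five 1-px specks
  roi <- matrix(60, 60, 95)
  for (i in 1:60) for (j in 1:95) {
    if (((j - 48) / 10)^2 + ((i - 30) / 6)^2 <= 1) roi[i, j] <- 110
  }
  specks <- rbind(c(5, 5), c(10, 80), c(50, 10), c(55, 90), c(3, 45))
  roi[specks] <- 110
  th <- thresh_range(85, 140)
  mask <- remove_noise(roi, th, opening_radius = 1)
  expect_false(any(mask[specks]))
  expect_true(all(roi[mask] == 110))
  # every sufficiently interior ellipse pixel survives the opening
  interior <- matrix(FALSE, 60, 95)
  for (i in 1:60) for (j in 1:95) {
    if (((j - 48) / 8)^2 + ((i - 30) / 4)^2 <= 1) interior[i, j] <- TRUE
  }
  expect_true(all(mask[interior]))

  # idempotence: re-running on the cleaned image changes nothing
  roi2 <- matrix(0, 60, 95); roi2[mask] <- 110
  expect_identical(remove_noise(roi2, th, opening_radius = 1), mask)

  expect_warning(remove_noise(matrix(0, 20, 20), th), "empty")
})

test_that("largest-object selection uses 8-connectivity", {
  # a diagonal chain is one 8-connected object and must beat a 2-px blob
  roi <- matrix(0, 20, 20)
  for (k in 1:6) roi[k, k] <- 110       # diagonal chain, size 6
  roi[15, 15] <- 110; roi[15, 16] <- 110 # small blob
  mask <- remove_noise(roi, thresh_range(85, 140), opening_radius = 0)
  expect_identical(sum(mask), 6L)
  expect_true(all(diag(mask)[1:6]))
})

test_that("region trimming crops to the padded bounding box", {
  roi <- matrix(60, 60, 40)
  cleaned <- matrix(FALSE, 60, 40)
  cleaned[11:30, 6:25] <- TRUE # rows 10-29, cols 5-24 in 0-based terms
  trimmed <- trim_region(roi, cleaned, margin = 2)
  expect_identical(dim(trimmed), c(24L, 24L))
  # clipping at the border, never out of bounds
  edge <- matrix(FALSE, 60, 40); edge[1:5, 1:5] <- TRUE
  trimmed_edge <- trim_region(roi, edge, margin = 2)
  expect_identical(dim(trimmed_edge), c(7L, 7L))
  # bounding box retains every component pixel
  expect_identical(sum(attr(trimmed, "component")), sum(cleaned))
  # empty mask gives an empty image
  empty <- trim_region(roi, matrix(FALSE, 60, 40))
  expect_identical(dim(empty), c(0L, 0L))
  expect_identical(hippocampus_area(extract_hippocampus(empty,
                                                        thresh_range(1, 2))),
                   0L)
})

test_that("GM-range separation recovers the painted ellipse exactly", {
  sl <- generate_slice(phantom_spec(), seed = 1)
  th <- estimate_thresh(sl$image)
  pair <- hippocampus_pipeline(sl$image, th)
  expect_identical(pair$left$area, sl$truth$hippo_left_area)
  expect_identical(pair$right$area, sl$truth$hippo_right_area)
  # final mask is a subset of the retained component
  expect_true(all(pair$left$intermediate$trimmed[
    pair$left$intermediate$mask] >= th$lo))

  # a trimmed patch entirely at WM intensity yields an empty mask
  wm_patch <- matrix(170, 10, 10)
  expect_identical(hippocampus_area(extract_hippocampus(wm_patch, th)), 0L)
})

test_that("extraction area is invariant to translating the anatomy in the ROI", {
  base <- phantom_spec()
  shifted <- phantom_spec(hippo_left_center = base$hippo_left_center + c(3, 0))
  a <- hippocampus_pipeline(generate_slice(base, 1)$image)
  b <- hippocampus_pipeline(generate_slice(shifted, 1)$image)
  expect_identical(a$left$area, b$left$area)
})

test_that("atrophy reduces the extracted areas on both sides", {
  healthy <- hippocampus_pipeline(
    generate_slice(phantom_spec(noise_sd = 8), seed = 4)$image)
  ad <- hippocampus_pipeline(
    generate_slice(phantom_spec(noise_sd = 8, atrophy = 0.4), seed = 4)$image)
  expect_lt(ad$left$area, healthy$left$area)
  expect_lt(ad$right$area, healthy$right$area)
})

test_that("mirroring the slice with mirrored masks swaps the areas exactly", {
  sl <- generate_slice(phantom_spec(noise_sd = 8), seed = 6)
  masks <- default_masks(498, 498)
  pair <- hippocampus_pipeline(sl$image, masks = masks)
  mirrored <- mirror_slice(sl$image)
  mmasks <- list(left = mirror_rect(masks$right, 498),
                 right = mirror_rect(masks$left, 498))
  mpair <- hippocampus_pipeline(mirrored, masks = mmasks)
  expect_identical(mpair$left$area, pair$right$area)
  expect_identical(mpair$right$area, pair$left$area)
})

test_that("measure_hippocampi returns the tidy two-row summary", {
  sl <- generate_slice(phantom_spec(), seed = 2)
  tb <- measure_hippocampi(sl$image)
  expect_identical(tb$side, c("left", "right"))
  expect_identical(tb$area, c(sl$truth$hippo_left_area,
                              sl$truth$hippo_right_area))
})
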