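test_that("noiseless phantom paints exactly the three tissue means", {
  sl <- generate_slice(small_spec(), seed = 1)
  brain <- attr(sl$image, "brain_mask")
  expect_setequal(unique(sl$image[brain]), c(60, 110, 170))
  expect_true(all(sl$image[!brain] == 0))
})

test_that("generation is a pure function of spec and seed", {
  sp <- small_spec(noise_sd = 8, bias_amplitude = 0.1)
  a <- generate_slice(sp, seed = 42)
  b <- generate_slice(sp, seed = 42)
  expect_identical(a, b)
  c <- generate_slice(sp, seed = 43)
  expect_false(identical(a$image, c$image))
})

test_that("painted hippocampal area matches brute-force rasterization under atrophy", {
  sp <- phantom_spec(hippo_semi_axes = c(20, 12), atrophy = 0.5)
  sl <- generate_slice(sp, seed = 1)
  expected <- oracle_ellipse_area(sp$hippo_left_center, c(10, 6),
                                  sp$width, sp$height)
  expect_identical(sl$truth$hippo_left_area, expected)
  expect_identical(sl$truth$hippo_right_area,
                   oracle_ellipse_area(sp$hippo_right_center, c(10, 6),
                                       sp$width, sp$height))
})

test_that("invalid phantom specs are rejected by name of the violated rule", {
  expect_error(phantom_spec(intensity_csf = 120), "CSF < GM < WM")
  expect_error(phantom_spec(atrophy = 1), "atrophy")
  expect_error(phantom_spec(noise_sd = -1), "noise_sd")
  expect_error(phantom_spec(hippo_left_center = c(5, 5)),
               "inside its ROI rectangle")
  expect_error(phantom_spec(hippo_semi_axes = c(80, 12)), "ROI rectangle")
})

test_that("painted area is non-increasing in atrophy", {
  areas <- vapply(c(0, 0.2, 0.4, 0.6, 0.8), function(a) {
    generate_slice(small_spec(atrophy = a), seed = 1)$truth$hippo_left_area
  }, integer(1))
  expect_true(all(diff(areas) <= 0))
  expect_lt(areas[5], areas[1])
})

test_that("repeat stacks share anatomy and reproduce generate_slice at n = 1", {
  sp <- small_spec(noise_sd = 8)
  stack1 <- generate_repeat_stack(sp, n_repeats = 1, seed = 9)
  expect_identical(stack1[[1]], generate_slice(sp, seed = 9)$image)
  expect_identical(attr(stack1, "truth"), generate_slice(sp, seed = 9)$truth)

  stack <- generate_repeat_stack(sp, n_repeats = 4, seed = 9)
  arr <- simplify2array(stack)
  brain <- attr(stack[[1]], "brain_mask")
  # pooled per-pixel sd across the stack estimates noise_sd
  pixvar <- apply(arr, c(1, 2), stats::var)
  expect_equal(sqrt(mean(pixvar[brain])), 8, tolerance = 0.02)
  expect_error(generate_repeat_stack(sp, n_repeats = 0, seed = 1),
               "n_repeats")
})

test_that("cohorts honour group sizes, labels and atrophy ordering", {
  base <- small_spec()
  co <- generate_cohort(cohort_spec(n_ad = 0, n_control = 3, seed = 5), base)
  expect_length(co, 3)
  expect_true(all(tidy(co)$class_label == -1L))

  co2 <- generate_cohort(cohort_spec(n_ad = 20, n_control = 20,
                                     atrophy_ad_mean = 0.4,
                                     atrophy_control_mean = 0,
                                     atrophy_sd = 0.05, seed = 7), base)
  tt <- tidy(co2)
  expect_lt(mean(tt$hippo_left_area[tt$class_label == 1L]),
            mean(tt$hippo_left_area[tt$class_label == -1L]))

  expect_identical(
    tidy(generate_cohort(cohort_spec(n_ad = 4, n_control = 4, seed = 3), base)),
    tidy(generate_cohort(cohort_spec(n_ad = 4, n_control = 4, seed = 3), base)))
})

test_that("bare feature tables have the promised shape and validation", {
  tab <- generate_feature_table(1, mean_ad = rep(0, 5),
                                mean_control = rep(1, 5), seed = 2)
  expect_identical(nrow(tab), 2L)
  expect_setequal(tab$label, c(1L, -1L))
  expect_error(generate_feature_table(3, rep(0, 5), rep(0, 5),
                                      sds = c(1, 1, 0, 1, 1)),
               "positive")
  expect_identical(generate_feature_table(5, rep(0, 5), rep(1, 5), seed = 4),
                   generate_feature_table(5, rep(0, 5), rep(1, 5), seed = 4))
})
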