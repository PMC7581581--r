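test_that("greyscale conversion follows ITU-R 601 and is identity on grey", {
  g <- matrix(c(0L, 128L, 255L, 7L), 2)
  expect_identical(to_greyscale_8bit(g), g)
  white <- array(255, c(2, 2, 3))
  expect_true(all(to_greyscale_8bit(white) == 255L))
  px <- array(c(100, 150, 200), c(1, 1, 3))
  expect_equal(as.integer(to_greyscale_8bit(px)),
               as.integer(round(0.299 * 100 + 0.587 * 150 + 0.114 * 200)))
  expect_equal(as.integer(to_greyscale_8bit(px)), 141L)
  expect_error(to_greyscale_8bit(array(1, c(2, 2, 2))), "channel count")
})

test_that("median filter removes impulses and keeps constants", {
  const <- matrix(77L, 10, 12)
  expect_identical(median_smooth(const, 2), const)
  salt <- matrix(0L, 9, 9); salt[5, 5] <- 255L
  expect_true(all(median_smooth(salt, 2) == 0L))
  expect_error(median_smooth(const, 0), ">= 1")
})

test_that("median filter equals the brute-force neighbourhood oracle", {
  withr::with_seed(7, {
    for (radius in 1:3) {
      m <- matrix(sample(0:255, 81, replace = TRUE), 9, 9)
      expect_identical(median_smooth(m, radius),
                       oracle_disk_median(m, radius))
    }
    # non-square image, including border behaviour
    m <- matrix(sample(0:255, 7 * 13, replace = TRUE), 7, 13)
    expect_identical(median_smooth(m, 2), oracle_disk_median(m, 2))
  })
})

test_that("median filter is idempotent on large two-valued blocks and bounded", {
  m <- matrix(200L, 20, 20); m[5:16, 5:16] <- 40L
  once <- median_smooth(m, 2)
  expect_identical(median_smooth(once, 2), once)
  withr::with_seed(8, {
    r <- matrix(sample(30:200, 100, replace = TRUE), 10, 10)
    sm <- median_smooth(r, 2)
    expect_gte(min(sm), min(r)); expect_lte(max(sm), max(r))
  })
})

test_that("Otsu threshold separates a perfectly bimodal image", {
  m <- matrix(230L, 30, 30)
  m[10:15, 10:15] <- 50L
  roi <- matrix(TRUE, 30, 30)
  th <- threshold_dark(m, roi)
  expect_true(th$threshold > 50 && th$threshold <= 230)
  expect_identical(th$mask, m == 50L)
  expect_error(otsu_threshold(matrix(99L, 5, 5)), "degenerate histogram")
})

test_that("in-package Otsu agrees with EBImage on a whole frame", {
  withr::with_seed(9, {
    m <- matrix(as.integer(round(c(rnorm(300, 60, 12), rnorm(700, 190, 18)))),
                20, 50)
    m <- pmax(0L, pmin(255L, m))
    ours <- otsu_threshold(m)
    ref <- EBImage::otsu(EBImage::Image(m / 255), range = c(0, 1),
                         levels = 256) * 255
    expect_lte(abs(ours - ref), 2)
  })
})

test_that("percent cover counts ROI pixels only", {
  roi <- matrix(FALSE, 10, 10); roi[3:8, 3:8] <- TRUE
  none <- matrix(FALSE, 10, 10)
  expect_equal(percent_cover(none, roi)$percent_dark, 0)
  expect_equal(percent_cover(roi, roi)$percent_dark, 100)
  half <- roi; half[3:8, 3:5] <- FALSE
  expect_equal(percent_cover(half, roi)$percent_dark, 50)
  expect_error(percent_cover(none, matrix(FALSE, 10, 10)), "empty ROI")
  expect_error(percent_cover(none, roi[1:5, ]), "dimensions")
  # pixels outside the ROI are irrelevant
  outside <- none; outside[1, ] <- TRUE
  expect_equal(percent_cover(outside, roi)$percent_dark, 0)
})

test_that("quantification ignores pixels beyond the filter's reach of the ROI", {
  # the median window crosses the ROI boundary, so only pixels farther
  # than the filter radius from the ROI can be irrelevant to the result
  params <- render_params(canvas = c(128, 128), background_noise_sd = 0)
  tr <- sample_chromatophore_truths(c(2, 2, 2, 2, 2), params, seed = 3)
  img <- render_segment_image(tr, params)
  q1 <- quantify_image(img)
  mutated <- img$pixels
  mutated[1:20, 1:20] <- 0L   # far corner, well outside the ellipse
  mutated[100:128, 100:128] <- 255L
  q2 <- quantify_image(mutated, img$roi)
  expect_equal(q2$percent_dark, q1$percent_dark)
  expect_equal(q2$threshold_used, q1$threshold_used)
})

test_that("noise-free renders measure within 2 points of drawn-area truth", {
  params <- render_params(background_noise_sd = 0)
  withr::with_seed(14, {
    for (stage_mix in list(c(20, 10, 5, 3, 2), c(2, 3, 5, 10, 20),
                           c(8, 8, 8, 8, 8))) {
      tr <- sample_chromatophore_truths(stage_mix, params)
      img <- render_segment_image(tr, params)
      truth_pct <- 100 * sum(img$truth_dark_mask) / sum(img$roi)
      expect_lte(abs(quantify_image(img)$percent_dark - truth_pct), 2)
    }
  })
})

test_that("percent cover increases strictly with drawn dark area", {
  params <- render_params(canvas = c(256, 256), background_noise_sd = 0)
  covers <- truth_area <- numeric(6)
  withr::with_seed(15, {
    for (i in 1:6) {
      cnt <- c(0, 0, 0, 0, 0); cnt[(i - 1) %% 5 + 1] <- 4 * i
      tr <- sample_chromatophore_truths(cnt, params)
      img <- render_segment_image(tr, params)
      truth_area[i] <- sum(img$truth_dark_mask)
      covers[i] <- quantify_image(img)$percent_dark
    }
  })
  expect_equal(cor(covers, truth_area, method = "spearman"), 1)
})

test_that("noise-only images quantify to (almost) no dark cover", {
  params <- render_params(canvas = c(128, 128), background_noise_sd = 5)
  empty <- data.frame(row = numeric(), col = numeric(), stage = integer(),
                      radius = numeric(), intensity_drop = numeric())
  img <- render_segment_image(empty, params, seed = 20)
  # Otsu on pure noise splits the noise distribution; use a fixed sensible
  # threshold as a pipeline would for a blank control frame
  q <- quantify_image(img, threshold = 180)
  expect_lte(q$percent_dark, 1)
})

test_that("the full recipe is deterministic and ordered by dispersion", {
  params <- render_params(canvas = c(128, 128), background_noise_sd = 4)
  sparse <- render_segment_image(
    sample_chromatophore_truths(c(12, 0, 0, 0, 0), params, seed = 30),
    params, seed = 31)
  dense <- render_segment_image(
    sample_chromatophore_truths(c(0, 0, 0, 0, 12), params, seed = 32),
    params, seed = 33)
  expect_gt(quantify_image(dense)$percent_dark,
            quantify_image(sparse)$percent_dark)
  expect_identical(quantify_image(dense)$percent_dark,
                   quantify_image(dense)$percent_dark)
})
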