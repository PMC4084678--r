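test_that("rgb_to_hsv matches the hexcone transform on primary and gray pixels", {
  img <- array(0, dim = c(2, 2, 3))
  img[1, 1, ] <- c(1, 0, 0)            # red
  img[1, 2, ] <- c(0, 0, 1)            # blue
  img[2, 1, ] <- c(128, 128, 128) / 255  # gray
  img[2, 2, ] <- c(0, 1, 0)            # green
  hsv <- rgb_to_hsv(img)
  expect_equal(hsv[1, 1, ], c(0, 1, 1))
  expect_equal(hsv[1, 2, ], c(240, 1, 1))
  expect_equal(hsv[2, 1, 2], 0)                    # achromatic: sat 0
  expect_equal(hsv[2, 1, 3], 128 / 255)
  expect_equal(hsv[2, 2, 1], 120)
  expect_equal(dim(hsv), dim(img))
})

test_that("flatten_value sets value, preserves hue/saturation, and is idempotent", {
  set.seed(1)
  img <- array(runif(5 * 4 * 3), dim = c(5, 4, 3))
  hsv <- rgb_to_hsv(img)
  flat <- flatten_value(hsv, 1)
  expect_true(all(flat[, , 3] == 1))
  expect_identical(flat[, , 1], hsv[, , 1])
  expect_identical(flat[, , 2], hsv[, , 2])
  expect_identical(flatten_value(flat, 1), flat)
  expect_error(flatten_value(hsv, 1.5), "\\[0, 1\\]")
})

test_that("segment_channel applies circular hue distance and saturation floor", {
  px <- function(h, s, v) array(c(h, s, v), dim = c(1, 1, 3))
  spec <- channel_spec(240, 30, 0.3)
  expect_true(segment_channel(px(240, 0.9, 1), spec)[1, 1])
  expect_false(segment_channel(px(0, 0.9, 1), spec)[1, 1])
  expect_false(segment_channel(px(240, 0.1, 1), spec)[1, 1])
  # hue interval wraps across 0 degrees
  spec2 <- channel_spec(10, 20, 0.3)
  expect_true(segment_channel(px(355, 0.9, 1), spec2)[1, 1])
  expect_false(segment_channel(px(345, 0.9, 1), spec2)[1, 1])
})

test_that("hue distance is circular, symmetric and bounded by 180", {
  expect_equal(hue_distance(10, 355), 15)
  expect_equal(hue_distance(355, 10), 15)
  expect_equal(hue_distance(0, 180), 180)
  set.seed(42)
  h1 <- runif(200, 0, 360); h2 <- runif(200, 0, 360)
  d <- hue_distance(h1, h2)
  expect_true(all(d >= 0 & d <= 180))
  expect_equal(d, hue_distance(h2, h1))
  # brute-force modular distance oracle
  d0 <- pmin(abs(h1 - h2), abs(h1 - h2 + 360), abs(h1 - h2 - 360))
  expect_equal(d, d0)
})

test_that("every mask pixel agrees with the threshold predicates on random images", {
  set.seed(7)
  spec <- channel_spec(240, 35, 0.25)
  for (rep in 1:5) {
    img <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
    hsv <- flatten_value(rgb_to_hsv(img), 1)
    mask <- segment_channel(hsv, spec)
    pred <- hue_distance(hsv[, , 1], spec$reference_hue) <= spec$hue_tolerance &
      hsv[, , 2] >= spec$min_saturation
    dim(pred) <- dim(mask)
    expect_identical(mask, pred)
  }
})

test_that("segmentation is independent of the value channel after flattening", {
  set.seed(8)
  img <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
  hsv <- rgb_to_hsv(img)
  spec <- channel_spec(240, 35, 0.25)
  m1 <- segment_channel(flatten_value(hsv, 1), spec)
  m0 <- segment_channel(flatten_value(hsv, 0.25), spec)
  expect_identical(m1, m0)
})

test_that("extract_elements filters by size and border and respects connectivity", {
  m <- matrix(FALSE, 12, 20)
  m[2:4, 2:4] <- TRUE        # 9 pixels: below threshold
  m[7:10, 5:7] <- TRUE       # 12 pixels: kept
  els <- extract_elements(m, min_pixels = 10)
  expect_length(els, 1)
  expect_equal(els[[1]]$pixel_count, 12L)
  expect_length(extract_elements(matrix(FALSE, 5, 5)), 0)

  # border exclusion removes a 15-pixel blob touching the left edge
  b <- matrix(FALSE, 10, 10)
  b[3:7, 1:3] <- TRUE
  expect_length(extract_elements(b, 10, exclude_border = TRUE), 0)
  expect_length(extract_elements(b, 10, exclude_border = FALSE), 1)

  # a diagonal pair is one element under 8-connectivity, two under 4
  d <- matrix(FALSE, 4, 4)
  d[1, 1] <- d[2, 2] <- TRUE
  expect_length(extract_elements(d, 1, connectivity = 8), 1)
  expect_length(extract_elements(d, 1, connectivity = 4), 2)
})

test_that("extracted elements partition a subset of the mask and obey invariants", {
  set.seed(11)
  for (rep in 1:5) {
    m <- random_mask(24, 24, 0.35)
    els <- extract_elements(m, min_pixels = 3, exclude_border = TRUE)
    for (el in els) {
      expect_gte(el$pixel_count, 3)
      expect_equal(nrow(el$pixels), el$pixel_count)
      expect_true(all(m[el$pixels]))
      expect_false(any(el$pixels[, 1] %in% c(1, nrow(m)) |
                         el$pixels[, 2] %in% c(1, ncol(m))))
    }
    ids <- vapply(els, `[[`, 0L, "element_id")
    expect_true(all(diff(ids) > 0))  # scan order
  }
})

test_that("manual_override performs the set edit and validates inputs", {
  m <- matrix(FALSE, 5, 5)
  expect_identical(manual_override(m), m)
  m2 <- manual_override(m, add = cbind(2, 3))
  expect_equal(sum(m2), 1)
  expect_true(m2[2, 3])
  # remove then add back restores the original
  m3 <- manual_override(m2, remove = cbind(2, 3))
  m4 <- manual_override(m3, add = cbind(2, 3))
  expect_identical(m4, m2)
  expect_error(manual_override(m, add = cbind(2, 3), remove = cbind(2, 3)),
               "disjoint")
  expect_error(manual_override(m, add = cbind(9, 1)), "out-of-bounds")
})
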