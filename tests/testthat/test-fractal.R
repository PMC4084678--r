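test_that("pad_to_pow2 pads to the smallest power-of-two square", {
  m <- matrix(TRUE, 100, 80)
  p <- pad_to_pow2(m)
  expect_equal(dim(p), c(128, 128))
  expect_true(all(p[1:100, 1:80]))
  expect_false(any(p[101:128, ]))
  expect_false(any(p[, 81:128]))
  expect_identical(pad_to_pow2(matrix(TRUE, 64, 64)), matrix(TRUE, 64, 64))
  expect_identical(pad_to_pow2(matrix(TRUE, 1, 1)), matrix(TRUE, 1, 1))
})

test_that("box_count matches direct expectations and rejects bad scales", {
  expect_equal(box_count(matrix(TRUE, 4, 4), 2), 4)
  m <- matrix(FALSE, 8, 8); m[3, 5] <- TRUE
  for (e in c(1, 2, 4, 8)) expect_equal(box_count(m, e), 1)
  expect_error(box_count(m, 3), "divide")
})

test_that("Sierpinski triangle counts follow the 3^j law at every dyadic scale", {
  st <- fractal_fixture("sierpinski_triangle", order = 5)
  expect_equal(dim(st), c(32, 32))
  for (j in 0:5) {
    e <- 32 / 2^j
    expect_equal(box_count(st, e), 3^j)
    expect_equal(brute_box_count(st, e), 3^j)
  }
})

test_that("box counts equal the brute-force cell scan on random masks", {
  set.seed(101)
  for (rep in 1:20) {
    nr <- sample(1:48, 1); nc <- sample(1:48, 1)
    m <- pad_to_pow2(random_mask(nr, nc, runif(1, 0.05, 0.6)))
    s <- hepfract:::box_count_series(m)
    for (k in seq_along(s$e))
      expect_identical(s$n[k], brute_box_count(m, s$e[k]))
  }
})

test_that("analytic masks give exact dimensions", {
  expect_equal(box_counting_fd(matrix(TRUE, 128, 128))$fd, 2.0)
  line <- matrix(FALSE, 128, 128); line[1, ] <- TRUE
  expect_equal(box_counting_fd(line)$fd, 1.0)
  single <- matrix(FALSE, 8, 8); single[4, 4] <- TRUE
  expect_equal(box_counting_fd(single)$fd, 0.0)
  expect_equal(box_counting_fd(matrix(TRUE, 1, 1))$fd, 0.0)
  expect_error(box_counting_fd(matrix(FALSE, 4, 4)), "empty")
})

test_that("fractal fixtures estimate near their theoretical dimensions", {
  st <- fractal_fixture("sierpinski_triangle", order = 7)
  expect_equal(box_counting_fd(st)$fd, log(3) / log(2), tolerance = 0.05 / 1.585)
  sc <- fractal_fixture("sierpinski_carpet", order = 5)  # side 243
  expect_lt(abs(box_counting_fd(sc)$fd - log(8) / log(3)), 0.08)
  ko <- fractal_fixture("koch_outline", order = 5, side = 243)
  expect_lt(abs(box_counting_fd(ko)$fd - log(4) / log(3)), 0.08)
})

test_that("the estimate is bounded by the planar limits and is deterministic", {
  set.seed(5)
  for (rep in 1:20) {
    m <- random_mask(sample(2:40, 1), sample(2:40, 1), runif(1, 0.02, 0.9))
    if (!any(m)) m[1, 1] <- TRUE
    r1 <- box_counting_fd(m)
    r2 <- box_counting_fd(m)
    expect_gte(r1$fd, 0)
    expect_lte(r1$fd, 2)
    expect_identical(r1, r2)
    expect_true(all(diff(r1$fit_points$n) >= 0))  # N grows as e shrinks
    expect_equal(r1$fit_points$n[1], 1)           # one box at full size
  }
})

test_that("box counts are invariant to translation by the padded box size", {
  m <- matrix(FALSE, 64, 64)
  m[9:24, 5:20] <- fractal_fixture("sierpinski_triangle", order = 4)
  shifted <- matrix(FALSE, 64, 64)
  shifted[(9:24), (5:20) + 0] <- m[9:24, 5:20]  # same content
  s0 <- hepfract:::box_count_series(m)
  # translate within the 64-grid by multiples of 64 is identity; instead
  # verify grid-aligned block translation preserves counts at that scale
  m2 <- matrix(FALSE, 64, 64)
  m2[9:24 + 32, 5:20 + 32] <- m[9:24, 5:20]
  expect_equal(box_count(m, 8), box_count(m2, 8))
  expect_equal(box_count(m, 4), box_count(m2, 4))
  expect_equal(box_count(m, 2), box_count(m2, 2))
  expect_equal(s0$n[length(s0$n)], sum(m))
})

test_that("element_fd measures contours by default and filled sets on request", {
  expect_equal(element_fd(list(pixels = cbind(5, 7)))$fd, 0.0)
  # an element filling its power-of-two bounding box: filled FD exactly 2
  full <- expand.grid(r = 1:16, c = 1:16)
  el <- list(pixels = cbind(full$r, full$c))
  expect_equal(element_fd(el, contour = FALSE)$fd, 2.0)
  # its contour (a square frame) measures strictly below the filled set
  expect_lt(element_fd(el, contour = TRUE)$fd,
            element_fd(el, contour = FALSE)$fd)
  # position independence: translation leaves the result unchanged
  el2 <- list(pixels = cbind(full$r + 13, full$c + 40))
  expect_identical(element_fd(el2), element_fd(el))
})

test_that("element_fd_table returns one row per element with finite FDs", {
  m <- matrix(FALSE, 24, 24)
  m[3:8, 3:8] <- TRUE
  m[15:20, 12:22] <- TRUE
  els <- extract_elements(m, 5)
  tab <- element_fd_table(els, channel = "nuclei", case_id = 1,
                          slide_id = 2, image_id = 3)
  expect_equal(nrow(tab), 2)
  expect_true(all(is.finite(tab$fd)))
  expect_equal(tab$channel, rep("nuclei", 2))
  empty <- element_fd_table(list(), channel = "vessels")
  expect_equal(nrow(empty), 0)
})
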