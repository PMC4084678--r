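test_that("fractal fixtures match their defining pixel counts", {
  fs <- fractal_fixture("filled_square", side = 64)
  expect_equal(sum(fs), 4096)
  expect_equal(attr(fs, "theoretical_fd"), 2)
  sc1 <- fractal_fixture("sierpinski_carpet", order = 1)
  expect_equal(dim(sc1), c(3, 3))
  expect_equal(sum(sc1), 8)            # centre cell empty
  expect_false(sc1[2, 2])
  for (k in 2:5) {
    st <- fractal_fixture("sierpinski_triangle", order = k)
    expect_equal(sum(st), 3^k)         # recursion count, exhaustive
  }
  ln <- fractal_fixture("line", side = 32)
  expect_equal(sum(ln), 32)
  expect_equal(sum(fractal_fixture("single_pixel", side = 16)), 1)
})

test_that("nucleus rendering is seed-deterministic and respects its contract", {
  p1 <- render_nucleus(c(50, 50), 12, 0.3, seed = 5)
  p2 <- render_nucleus(c(50, 50), 12, 0.3, seed = 5)
  expect_identical(p1, p2)
  p3 <- render_nucleus(c(50, 50), 12, 0.3, seed = 6)
  expect_false(identical(p1, p3))
  # roughness 0 is a discrete disk: compare against the direct definition
  d <- render_nucleus(c(30, 30), 8, 0, seed = 1)
  rr <- d[, 1] - 30; cc <- d[, 2] - 30
  expect_true(all(rr^2 + cc^2 <= 8^2))
  grid <- expand.grid(r = -9:9, c = -9:9)
  inside <- grid[grid$r^2 + grid$c^2 <= 64, ]
  expect_equal(nrow(d), nrow(inside))
  expect_error(render_nucleus(c(1, 1), 1, 0.2), ">= 2")
  expect_error(render_nucleus(c(1, 1), 10, 0.9), "0.6")
})

test_that("median contour dimension rises with the roughness amplitude", {
  med_fd <- function(amp, n = 40) {
    fds <- vapply(seq_len(n), function(i) {
      s <- hepfract:::derive_seed(99, "rough", round(100 * amp), i)
      r <- hepfract:::with_seed(s + 1, runif(1, 22, 40))
      element_fd(list(pixels = render_nucleus(c(150, 150), r, amp,
                                              seed = s)))$fd
    }, 0)
    median(fds)
  }
  m <- vapply(c(0, 0.2, 0.4), med_fd, 0)
  expect_lt(m[1], m[2])
  expect_lt(m[2], m[3])
})

test_that("vessel rendering is deterministic and degenerates to a straight segment", {
  v1 <- render_vessel(c(20, 20), 30, 3, 0.4, seed = 9, bounds = c(96, 96))
  v2 <- render_vessel(c(20, 20), 30, 3, 0.4, seed = 9, bounds = c(96, 96))
  expect_identical(v1, v2)
  # zero tortuosity, unit thickness, fixed heading: a straight line of pixels
  s <- render_vessel(c(10, 40), 20, 1, 0, seed = 1, bounds = c(96, 96),
                     heading = 0)
  expect_equal(sort(unique(s[, 2])), 40)
  expect_equal(sort(s[, 1]), 10:30)
})

test_that("vessel contour dimension rises with tortuosity and branching", {
  med_fd <- function(tort, branch) {
    fds <- vapply(1:30, function(i) {
      s <- hepfract:::derive_seed(7, "tort", round(100 * tort), i)
      px <- render_vessel(c(250, 250), 150, 4, tort, branch,
                          bounds = c(512, 512), seed = s)
      element_fd(list(pixels = px))$fd
    }, 0)
    median(fds)
  }
  lo <- med_fd(0.05, 0)
  mid <- med_fd(0.25, 0)
  hi <- med_fd(0.5, 0.04)
  expect_lt(lo, mid)
  expect_lt(mid, hi)
})

test_that("cohort_spec validates structure and the class-complexity ordering", {
  spec <- cohort_spec(n_cases = 4, seed = 3)
  expect_equal(spec$case_classes, c("HCC", "LM", "HCC", "LM"))
  expect_error(cohort_spec(slides_per_case = 3), "even")
  bad <- hepfract:::default_class_params()
  bad$LM$nucleus_roughness <- 0.5
  expect_error(cohort_spec(class_params = bad), "ordered")
})

test_that("generated images carry ground truth consistent with the shipped thresholds", {
  spec <- tiny_cohort_spec(seed = 13)
  im <- generate_image(spec, 1, 1, 1)
  expect_equal(dim(im$rgb), c(96, 96, 3))
  expect_equal(im$true_image_label, "tumor")
  expect_equal(im$true_case_label, "HCC")
  seg <- segment_image(im$rgb)
  for (ch in c("nuclei", "vessels")) {
    pred <- seg$masks[[ch]]
    tru <- im[[paste0(ch, "_mask")]]
    expect_gte(sum(pred & tru) / sum(tru), 0.99)        # recall
    expect_gte(sum(pred & tru) / max(sum(pred), 1), 0.99)  # precision
  }
  nrm <- generate_image(spec, 2, 2, 1)
  expect_equal(nrm$true_image_label, "normal")
  expect_equal(nrm$tissue, "normal")
})

test_that("cohorts regenerate identically from the same seed", {
  spec <- tiny_cohort_spec(seed = 21)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$manifest, c2$manifest)
  im1 <- c1$image_fn(2, 1, 1)
  im2 <- c2$image_fn(2, 1, 1)
  expect_identical(im1$rgb, im2$rgb)
  expect_identical(im1$nuclei_mask, im2$nuclei_mask)
  # manifest structure follows the study design: half tumour slides
  expect_equal(mean(c1$manifest$true_image_label == "tumor"), 0.5)
  expect_equal(nrow(c1$manifest),
               spec$n_cases * spec$slides_per_case * spec$images_per_slide)
})

test_that("on-disk cohorts are byte-stable and round-trip through PNG", {
  spec <- tiny_cohort_spec(seed = 34)
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  co <- generate_cohort(spec, dir = d1)
  generate_cohort(spec, dir = d2)
  m1 <- file.path(d1, "manifest.csv")
  expect_true(file.exists(m1))
  # identical bytes apart from the embedded output paths
  t1 <- readLines(m1); t2 <- readLines(file.path(d2, "manifest.csv"))
  expect_identical(gsub(d1, "", t1, fixed = TRUE),
                   gsub(d2, "", t2, fixed = TRUE))
  img <- read_image(co$manifest$path[1])
  gen <- co$image_fn(1, 1, 1)$rgb
  expect_equal(img, gen, tolerance = 1 / 254)   # 8-bit quantisation
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("roughness calibration converges onto an attainable target", {
  cal <- calibrate_roughness(1.35, n_nuclei = 15, seed = 4, tol = 0.06,
                             max_iter = 6)
  expect_true(cal$roughness >= 0 && cal$roughness <= 0.6)
  expect_lt(abs(cal$median_fd - 1.35), 0.06)
})
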