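test_that("network initialisation is seeded, shaped and symmetric-uniform", {
  n1 <- init_network(c(8, 10, 2), seed = 4)
  n2 <- init_network(c(8, 10, 2), seed = 4)
  n3 <- init_network(c(8, 10, 2), seed = 5)
  expect_identical(n1, n2)
  expect_false(identical(n1$w1, n3$w1))
  expect_equal(dim(n1$w1), c(10, 8))
  expect_equal(dim(n1$w2), c(2, 10))
  expect_equal(n1$b1, rep(0, 10))
  expect_true(max(abs(n1$w1)) <= 1 / sqrt(8))
  expect_error(init_network(c(0, 3, 2)), "positive")
})

test_that("the forward pass is a softmax probability vector with the score convention", {
  # hand-built model with zero weights: both classes get 0.5
  zero <- structure(list(
    w1 = matrix(0, 3, 2), b1 = rep(0, 3),
    w2 = matrix(0, 2, 3), b2 = rep(0, 2),
    center = c(0, 0), scale = c(1, 1), levels = c("a", "b"),
    config = list()), class = "fdnn")
  p <- predict(zero, c(1.3, -0.2), type = "prob")
  expect_equal(unname(p[1, ]), c(0.5, 0.5))
  pr <- predict(zero, c(1.3, -0.2), type = "prediction")[[1]]
  expect_equal(pr$probability_score, 50)

  # random models: rows sum to one, score = 100 * max output
  set.seed(9)
  net <- init_network(c(4, 6, 3), seed = 2)
  model <- structure(c(net, list(center = rep(0, 4), scale = rep(1, 4),
                                 levels = c("x", "y", "z"),
                                 config = list())), class = "fdnn")
  xs <- matrix(rnorm(40), 10, 4)
  probs <- predict(model, xs, type = "prob")
  expect_equal(rowSums(probs), rep(1, 10), tolerance = 1e-9)
  preds <- predict(model, xs, type = "prediction")
  for (i in 1:10) {
    expect_equal(preds[[i]]$probability_score, 100 * max(probs[i, ]))
    expect_gt(preds[[i]]$probability_score, 0)
    expect_lte(preds[[i]]$probability_score, 100)
  }
  expect_error(predict(model, c(1, 2)), "feature length")
})

test_that("a hand-computed 2-2-2 forward pass matches the implementation", {
  model <- structure(list(
    w1 = matrix(c(0.5, -0.3, 0.2, 0.8), 2, 2, byrow = TRUE),
    b1 = c(0.1, -0.1),
    w2 = matrix(c(1, -1, 0.5, 0.25), 2, 2, byrow = TRUE),
    b2 = c(0, 0.2),
    center = c(0, 0), scale = c(1, 1), levels = c("a", "b"),
    config = list()), class = "fdnn")
  x <- c(0.4, -0.6)
  # pencil-and-paper: h = sigmoid(W1 x + b1), o = softmax(W2 h + b2)
  h <- 1 / (1 + exp(-(c(0.5 * 0.4 - 0.3 * -0.6 + 0.1,
                        0.2 * 0.4 + 0.8 * -0.6 - 0.1))))
  z <- c(h[1] - h[2], 0.5 * h[1] + 0.25 * h[2] + 0.2)
  o <- exp(z) / sum(exp(z))
  expect_equal(unname(predict(model, x, type = "prob")[1, ]), unname(o),
               tolerance = 1e-12)
})

test_that("back-propagation gradients match central finite differences", {
  set.seed(12)
  net <- init_network(c(3, 3, 2), seed = 8)
  x <- matrix(rnorm(15), 5, 3)
  tmat <- diag(2)[sample(1:2, 5, replace = TRUE), ]
  ga <- hepfract:::nn_gradient(net, x, tmat)
  h <- 1e-5
  rel_err <- function(part) {
    num <- net[[part]]
    for (i in seq_along(net[[part]])) {
      np <- net; np[[part]][i] <- np[[part]][i] + h
      nm <- net; nm[[part]][i] <- nm[[part]][i] - h
      num[i] <- (hepfract:::nn_loss(np, x, tmat) -
                   hepfract:::nn_loss(nm, x, tmat)) / (2 * h)
    }
    max(abs(num - ga[[part]]) / pmax(abs(num) + abs(ga[[part]]), 1e-8))
  }
  for (part in c("w1", "b1", "w2", "b2"))
    expect_lt(rel_err(part), 1e-6)
})

test_that("training separates a gapped two-class set and is reproducible", {
  d <- separable_dataset()
  fit1 <- fdnn(d$x, d$y, hidden = 6, max_epochs = 200, seed = 21)
  fit2 <- fdnn(d$x, d$y, hidden = 6, max_epochs = 200, seed = 21)
  expect_identical(coef(fit1), coef(fit2))
  expect_gte(fit1$test$accuracy, 0.95)
  # descent sanity: best-epoch training loss no worse than the first epoch
  expect_lte(fit1$history$train_loss[fit1$best_epoch],
             fit1$history$train_loss[1])
  # the split respects the 50/25/25 fractions to within one sample per class
  expect_equal(as.integer(table(fit1$assignment)), c(60L, 30L, 30L))
})

test_that("test metrics come from samples never used in fitting", {
  d <- separable_dataset(seed = 6)
  fit <- fdnn(d$x, d$y, hidden = 4, max_epochs = 50, seed = 13)
  expect_length(intersect(which(fit$assignment == 1L),
                          which(fit$assignment == 3L)), 0)
  expect_equal(sum(fit$test$confusion), sum(fit$assignment == 3L))
})

test_that("degenerate inputs are rejected", {
  d <- separable_dataset(n_per_class = 15)
  expect_error(fdnn(d$x, rep("a", 30)), "two classes")
  both <- c(1:5, 16:20)   # five of each class: below the size floor
  expect_error(fdnn(d$x[both, ], d$y[both]), "20 samples")
  xbad <- d$x; xbad[1, 1] <- NA
  expect_error(fdnn(xbad, d$y), "non-finite")
})

test_that("cross-validation partitions the data and pools one prediction per sample", {
  d <- separable_dataset(n_per_class = 40, seed = 17)
  cv <- cross_validate(d$x, d$y, folds = 10, seed = 5, hidden = 4,
                       max_epochs = 120)
  expect_equal(sum(cv$confusion), 80)
  sizes <- table(cv$fold)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_equal(length(cv$fold), 80)
  expect_gte(cv$accuracy, 0.95)
  expect_error(cross_validate(d$x[1:5, ], d$y[1:5], folds = 10), "fewer")
})

test_that("models survive a JSON round trip", {
  d <- separable_dataset(seed = 23)
  fit <- fdnn(d$x, d$y, hidden = 5, max_epochs = 60, seed = 2)
  path <- tempfile(fileext = ".json")
  write_fdnn(fit, path)
  back <- read_fdnn(path)
  expect_equal(predict(back, d$x, type = "prob"),
               predict(fit, d$x, type = "prob"))
  expect_equal(back$levels, fit$levels)
})
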