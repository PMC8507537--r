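test_that("all four classifier kinds separate well-separated pixel clouds", {
  d <- gaussian_pixels(n = 300, d = 2, delta = 6)   # d-prime ~ 6
  for (kind in c("LDA", "QDA", "SVM", "LOGREG")) {
    m <- train_pixel_classifier(d$x, d$y, kind)
    p <- predict(m, d$x)
    expect_true(all(p >= 0 & p <= 1))
    acc <- mean((p > 0.5) == (d$y == 1))
    expect_gt(acc, 0.99)
  }
  # single-class input refuses to train
  expect_error(train_pixel_classifier(d$x, rep(1, nrow(d$x)), "LDA"),
               class = "maflim_validation_error")
})

test_that("posteriors are calibrated near 0.5 when classes are identical", {
  set.seed(8)
  n <- 5000
  x <- data.frame(f1 = rnorm(2 * n), f2 = rnorm(2 * n))
  y <- rep(c(0, 1), each = n)
  for (kind in c("LDA", "QDA", "LOGREG", "SVM")) {
    m <- train_pixel_classifier(x, y, kind)
    expect_lt(abs(mean(predict(m, x)) - 0.5), 0.05)
  }
})

test_that("QDA exploits variance differences that LDA cannot", {
  set.seed(9)
  n <- 1500
  x <- data.frame(f1 = c(rnorm(n, 0, 0.5), rnorm(n, 0, 2.5)),
                  f2 = c(rnorm(n, 0, 0.5), rnorm(n, 0, 2.5)))
  y <- rep(c(0, 1), each = n)
  qda <- train_pixel_classifier(x, y, "QDA")
  lda <- train_pixel_classifier(x, y, "LDA")
  acc <- function(m) mean((predict(m, x) > 0.5) == (y == 1))
  expect_gt(acc(qda), acc(lda))
  expect_gt(acc(qda), 0.7)
})

test_that("own Gaussian discriminants agree with the MASS reference", {
  d <- gaussian_pixels(n = 250, d = 3, delta = 1.5, sd2 = 1.6, seed = 13)
  xs <- scale(as.matrix(d$x))
  own_lda <- train_pixel_classifier(d$x, d$y, "LDA")
  own_qda <- train_pixel_classifier(d$x, d$y, "QDA")
  ref_lda <- MASS::lda(xs, grouping = factor(d$y))
  ref_qda <- MASS::qda(xs, grouping = factor(d$y))
  p_ref_l <- predict(ref_lda, xs)$posterior[, "1"]
  p_ref_q <- predict(ref_qda, xs)$posterior[, "1"]
  expect_lt(max(abs(predict(own_lda, d$x) - p_ref_l)), 0.02)
  expect_lt(max(abs(predict(own_qda, d$x) - p_ref_q)), 0.02)
})

test_that("near-singular covariances are regularized with a warning", {
  set.seed(10)
  x <- data.frame(f1 = rnorm(100))
  x$f2 <- x$f1                      # perfectly collinear
  y <- rep(c(0, 1), 50)
  x$f1 <- x$f1 + y * 2
  x$f2 <- x$f2 + y * 2
  w <- testthat::capture_warnings(m <- train_pixel_classifier(x, y, "QDA"))
  expect_match(w, "regularized", all = TRUE)
  expect_gte(length(w), 1)                # one per degenerate class
  expect_true(all(is.finite(predict(m, x))))
})

test_that("SVM posterior calibration is monotone in the decision value", {
  d <- gaussian_pixels(n = 200, d = 2, delta = 2, seed = 14)
  m <- train_pixel_classifier(d$x, d$y, "SVM")
  xs <- sweep(sweep(as.matrix(d$x), 2, m$center), 2, m$scale, "/")
  dec <- drop(xs %*% m$params$w) + m$params$b
  p <- predict(m, d$x)
  ord <- order(dec)
  expect_true(all(diff(p[ord]) >= -1e-12))
  expect_gt(m$calib[2], 0)          # increasing sigmoid
})

test_that("posterior maps cover exactly the valid mask", {
  sc <- generate_scene(default_class_params("null")$healthy,
                       rows = 5, cols = 5, n_time = 128, seed = 3)
  pp <- preprocess(sc$image)
  fits <- fit_image(pp$image, sc$irf, pp$mask)
  stack <- build_feature_stack(pp$image, fits, pp$mask)
  df <- as.data.frame(stack)
  m <- train_pixel_classifier(rbind(df, df + 0.01),
                              rep(c(0, 1), each = nrow(df)), "LDA",
                              features = c("I390n", "tau_avg_452"))
  pm <- posterior_map(m, stack)
  expect_true(all(is.na(pm$p[!stack$valid])))
  expect_true(all(pm$p[stack$valid] >= 0 & pm$p[stack$valid] <= 1))

  # a missing feature is reported by name
  stack2 <- stack
  stack2$features$tau_avg_452 <- NULL
  expect_error(posterior_map(m, structure(
    list(features = stack2$features, valid = stack2$valid),
    class = "feature_stack")), "tau_avg_452")
})

test_that("image_score is the mean squared posterior and is monotone", {
  expect_equal(image_score(c(1, 1, 1)), 1)
  expect_equal(image_score(c(0.5, 0.5)), 0.25)
  expect_equal(image_score(c(0.2, 0.4, 0.6, 0.8)), 0.30)
  # raising any pixel posterior never lowers the score
  set.seed(4)
  p <- runif(50)
  s0 <- image_score(p)
  for (i in c(1, 25, 50)) {
    p2 <- p; p2[i] <- min(1, p2[i] + 0.2)
    expect_gte(image_score(p2), s0)
  }
  expect_error(image_score(numeric(0)), class = "maflim_validation_error")
})

test_that("threshold optimization matches brute force under the FPR cap", {
  # separable case
  th <- optimize_threshold(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(attr(th, "sensitivity"), 1.0)
  expect_equal(attr(th, "fpr"), 0.0)
  # inverted degenerate case warns with zero sensitivity
  expect_warning(
    th0 <- optimize_threshold(c(0.9, 0.95), c(1, 0)),
    "sensitivity")
  expect_equal(attr(th0, "sensitivity"), 0)

  # interleaved scores match exhaustive search over all cut points
  set.seed(11)
  for (rep in 1:20) {
    scores <- round(runif(20), 2)     # ties likely
    labels <- rep(c(1, 0), 10)
    th <- suppressWarnings(optimize_threshold(scores, labels))
    ref <- brute_force_threshold(scores, labels)
    expect_equal(attr(th, "sensitivity"), ref$sens)
    expect_equal(attr(th, "fpr"), ref$fpr)
    expect_lte(attr(th, "fpr"), 0.3)
  }
})

test_that("image classification is inclusive at the threshold", {
  expect_equal(classify_image(0.5, 0.5), "positive")
  expect_equal(classify_image(0, 0.5), "negative")
  expect_equal(classify_image(1, 1), "positive")
})

test_that("ensemble posteriors are exact convex combinations", {
  v <- matrix(TRUE, 2, 2)
  pa <- structure(list(p = matrix(0.5, 2, 2), valid = v),
                  class = "probability_map")
  pb <- structure(list(p = matrix(1.0, 2, 2), valid = v),
                  class = "probability_map")
  expect_equal(ensemble_posterior(pa, pb, 1)$p, pa$p)
  expect_equal(ensemble_posterior(pa, pb, 0)$p, pb$p)
  expect_equal(ensemble_posterior(pa, pb, 0.4)$p[1, 1], 0.8)
  # convexity: always between the member posteriors
  set.seed(5)
  pa$p[] <- runif(4); pb$p[] <- runif(4)
  for (w in c(0.3, 0.7)) {
    pe <- ensemble_posterior(pa, pb, w)$p
    expect_true(all(pe >= pmin(pa$p, pb$p) - 1e-12))
    expect_true(all(pe <= pmax(pa$p, pb$p) + 1e-12))
  }
  # mask mismatch is an error
  pb2 <- pb; pb2$valid[1, 1] <- FALSE
  expect_error(ensemble_posterior(pa, pb2, 0.5),
               class = "maflim_validation_error")
})

test_that("classifiers round-trip through JSON with identical predictions", {
  d <- gaussian_pixels(n = 120, d = 3, delta = 2, seed = 15)
  for (kind in c("LDA", "QDA", "SVM", "LOGREG")) {
    m <- train_pixel_classifier(d$x, d$y, kind)
    m$threshold <- 0.37
    path <- withr::local_tempfile(fileext = ".json")
    write_classifier(m, path)
    m2 <- read_classifier(path)
    expect_identical(predict(m2, d$x), predict(m, d$x))
    expect_equal(m2$threshold, 0.37)
  }
  # ensembles serialize too
  ma <- train_pixel_classifier(d$x, d$y, "SVM", features = c("f1", "f2"))
  mb <- train_pixel_classifier(d$x, d$y, "QDA", features = "f3")
  ens <- maflim_ensemble(ma, mb, w1 = 0.4, threshold = 0.2)
  path <- withr::local_tempfile(fileext = ".json")
  write_classifier(ens, path)
  ens2 <- read_classifier(path)
  expect_identical(predict(ens2, d$x), predict(ens, d$x))
})
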