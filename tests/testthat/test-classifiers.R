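make_blobs <- function(n_per = 20, centers = list(c(0, 0), c(10, 0), c(0, 10)),
                       sd = 0.5, seed = 1) {
  withr::with_seed(seed, {
    X <- do.call(rbind, lapply(centers, function(ct)
      cbind(rnorm(n_per, ct[1], sd), rnorm(n_per, ct[2], sd))))
    colnames(X) <- c("f1", "f2")
    list(X = X, y = rep(c("I", "II", "III")[seq_along(centers)], each = n_per))
  })
}

test_that("kNN votes among the k nearest with the documented tie rules", {
  X <- matrix(c(0, 1, 10), ncol = 1)
  y <- c("I", "I", "III")
  m <- fit_classifier(X, y, classifier_spec("knn", k = 3))
  expect_equal(as.character(predict(m, 0.5)), "I")   # 2-vs-1 vote
  m1 <- fit_classifier(X, y, classifier_spec("knn", k = 1))
  expect_equal(as.character(predict(m1, 10)), "III") # exact training point
  # k = n_train, single class
  ma <- fit_classifier(matrix(1:3, ncol = 1), c("II", "II", "II"),
                       classifier_spec("knn", k = 3))
  expect_equal(as.character(predict(ma, -50)), "II")
  expect_error(fit_classifier(X, y, classifier_spec("knn", k = 5)), "exceed")
  expect_error(classifier_spec("knn", k = 2), "odd")
})

test_that("kNN matches a brute-force oracle on 1000 random instances", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(6:15, 1)
    X <- matrix(rnorm(n * 3), n, 3)
    y <- factor(sample(c("I", "II", "III"), n, replace = TRUE))
    while (nlevels(droplevels(y)) < 2) y <- factor(sample(c("I", "II", "III"), n, TRUE))
    y <- droplevels(y)
    k <- sample(c(1, 3), 1)
    q <- rnorm(3)
    m <- fit_classifier(X, as.character(y), classifier_spec("knn", k = k))
    expect_equal(as.character(predict(m, q)),
                 oracle_knn_predict(X, as_grade_factor(as.character(y)), q, k))
  }
})

test_that("kNN agrees with class::knn when the vote is untied", {
  skip_if_not_installed("class")
  set.seed(55)
  hits <- 0
  for (i in 1:200) {
    X <- matrix(rnorm(30), 10, 3)
    y <- rep(c("I", "II"), 5)
    q <- matrix(rnorm(3), 1)
    m <- fit_classifier(X, y, classifier_spec("knn", k = 3))
    Z <- scale(X)
    zq <- (q - attr(Z, "scaled:center")) / attr(Z, "scaled:scale")
    ref <- as.character(class::knn(Z, zq, factor(y), k = 3))
    expect_equal(as.character(predict(m, q)), ref)
    hits <- hits + 1
  }
  expect_equal(hits, 200)
})

test_that("PNN in the small-spread limit reduces to 1-NN (1000 fuzz cases)", {
  set.seed(77)
  for (i in 1:1000) {
    n <- sample(5:12, 1)
    X <- matrix(rnorm(n * 2), n, 2)
    y <- sample(c("I", "II", "III"), n, replace = TRUE)
    q <- rnorm(2)
    mp <- fit_classifier(X, y, classifier_spec("pnn", spread = 1e-4))
    m1 <- fit_classifier(X, y, classifier_spec("knn", k = 1))
    expect_identical(as.character(predict(mp, q)), as.character(predict(m1, q)))
  }
})

test_that("PNN symmetric-tie falls back to the nearest sample's (lower-grade) class", {
  X <- matrix(c(-1, 1), ncol = 1)
  y <- c("I", "III")
  m <- fit_classifier(X, y, classifier_spec("pnn", spread = 1))
  p <- predict(m, 0)
  sc <- attr(p, "scores")
  expect_equal(unname(sc[1, "I"]), unname(sc[1, "III"]))
  expect_equal(as.character(p), "I")  # nearest is tied too; stable order wins
})

test_that("PNN separates two well-spaced Gaussian classes almost perfectly", {
  withr::with_seed(42, {
    Xtr <- matrix(c(rnorm(50, 0), rnorm(50, 10)), ncol = 1)
    ytr <- rep(c("I", "III"), each = 50)
    Xte <- matrix(c(rnorm(100, 0), rnorm(100, 10)), ncol = 1)
    yte <- rep(c("I", "III"), each = 100)
  })
  m <- fit_classifier(Xtr, ytr, classifier_spec("pnn", spread = 1))
  acc <- mean(as.character(predict(m, Xte)) == yte)
  expect_gte(acc, 0.99)  # Bayes error ~ pnorm(-5) is negligible
})

test_that("PNN scores are positive and predictions are translation-invariant", {
  b <- make_blobs(seed = 3)
  q <- matrix(rnorm(20 * 2, 5, 3), 20, 2)
  m0 <- fit_classifier(b$X, b$y, classifier_spec("pnn", spread_mult = 0.3))
  p0 <- predict(m0, q)
  expect_true(all(attr(p0, "scores") > 0))
  shift <- c(100, -40)
  m1 <- fit_classifier(sweep(b$X, 2, shift, "+"), b$y,
                       classifier_spec("pnn", spread_mult = 0.3))
  p1 <- predict(m1, sweep(q, 2, shift, "+"))
  expect_identical(as.character(p0), as.character(p1))
  # same for kNN; per-feature affine maps also cancel in the standardization
  mk0 <- fit_classifier(b$X, b$y, classifier_spec("knn"))
  mk1 <- fit_classifier(sweep(b$X, 2, c(3, 0.25), "*"), b$y, classifier_spec("knn"))
  expect_identical(as.character(predict(mk0, q)),
                   as.character(predict(mk1, sweep(q, 2, c(3, 0.25), "*"))))
})

test_that("all back ends only ever emit labels from the training set", {
  b <- make_blobs(n_per = 8, seed = 9)
  set.seed(10)
  q <- matrix(rnorm(60, 0, 50), 30, 2)
  for (kind in c("knn", "pnn", "svm")) {
    m <- fit_classifier(b$X, b$y, classifier_spec(kind))
    p <- predict(m, q)
    expect_true(all(as.character(p) %in% unique(b$y)))
  }
})

test_that("SVM handles separable, blob, and unlearnable cases as expected", {
  # linearly separable 4-point toy: perfect training accuracy
  X <- rbind(c(0, 0), c(0, 1), c(5, 5), c(5, 6))
  y <- c("I", "I", "III", "III")
  m <- fit_classifier(X, y, classifier_spec("svm"))
  expect_equal(as.character(predict(m, X)), y)
  # three well-separated blobs: LOO accuracy 100%
  b <- make_blobs(seed = 4)
  pred <- loo_predict(b$X, b$y, classifier_spec("svm"))
  expect_equal(mean(as.character(pred) == b$y), 1)
  # duplicated points with flipped labels cannot be learned
  b2 <- make_blobs(centers = list(c(0, 0), c(10, 0)), seed = 6)
  Xd <- rbind(b2$X, b2$X)
  yd <- c(b2$y, ifelse(b2$y == "I", "II", "I"))
  md <- fit_classifier(Xd, yd, classifier_spec("svm"))
  expect_lte(mean(as.character(predict(md, Xd)) == yd), 0.5)
  expect_error(fit_classifier(matrix(c(1, NA), 2, 1), c("I", "II"),
                              classifier_spec("svm")), "finite")
})

test_that("standardization statistics come from the training fold only", {
  set.seed(31)
  Xtr <- matrix(rnorm(20), 10, 2)
  Xte <- matrix(rnorm(10, 5, 3), 5, 2)
  st_train <- texgrade:::standardize_fit(Xtr)
  st_leaky <- texgrade:::standardize_fit(rbind(Xtr, Xte))
  z_train <- texgrade:::standardize_apply(Xte, st_train)
  z_leaky <- texgrade:::standardize_apply(Xte, st_leaky)
  expect_false(isTRUE(all.equal(z_train, z_leaky)))
  m <- fit_classifier(Xtr, rep(c("I", "II"), 5), classifier_spec("knn"))
  expect_equal(m$stats$center, st_train$center)
})

test_that("the fast LOO path is identical to the naive fit/predict loop", {
  set.seed(202)
  for (i in 1:8) {
    n <- 21
    X <- matrix(rnorm(n * 4), n, 4)
    y <- rep(c("I", "II", "III"), each = 7)
    X[y == "II", 2] <- X[y == "II", 2] + 2
    X[y == "III", 2] <- X[y == "III", 2] + 4
    for (spec in list(classifier_spec("knn", k = 1), classifier_spec("knn", k = 3),
                      classifier_spec("pnn", spread = 0.7),
                      classifier_spec("pnn", spread_mult = 0.25))) {
      expect_identical(loo_predict(X, y, spec),
                       loo_predict(X, y, spec, naive = TRUE))
    }
  }
})
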