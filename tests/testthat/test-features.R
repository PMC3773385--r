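test_that("quantization bins linearly, maps constants to 0, and is affine-invariant", {
  expect_true(all(quantize(matrix(42, 5, 5), 16) == 0L))
  # full 8-bit ramp with G=16: each level covers 16 consecutive intensities
  q <- quantize(matrix(0:255, 1), 16)
  expect_equal(as.vector(table(q)), rep(16L, 16))
  expect_equal(sort(unique(as.vector(q))), 0:15)
  # positive affine rescale leaves the quantized image unchanged
  set.seed(1)
  v <- matrix(sample(0:120, 100, replace = TRUE), 10, 10)
  for (a in c(2, 1.5)) {
    q1 <- quantize(v, 8)
    q2 <- quantize(a * v + 7, 8)
    expect_identical(unclass(q1), unclass(q2))
  }
})

test_that("first-order statistics match hand-computed moments", {
  expect_equal(first_order_features(matrix(9, 3, 3)),
               c(mean = 9, std = 0, skewness = 0, kurtosis = 0))
  expect_equal(first_order_features(matrix(c(0, 0, 255, 255), 2, 2)),
               c(mean = 127.5, std = 127.5, skewness = 0, kurtosis = -2))
  # symmetric histogram has zero skewness
  sym <- matrix(c(10, 20, 30, 40, 50, 30), 2, 3)
  expect_equal(first_order_features(sym)[["skewness"]], 0)
})

test_that("co-occurrence matrices are symmetric, normalized, and match enumeration", {
  # 2-level checkerboard at 0 degrees
  cb <- matrix((row(matrix(0, 4, 4)) + col(matrix(0, 4, 4))) %% 2, 4, 4)
  attr(cb, "G") <- 2L
  P <- cooccurrence_matrix(cb, 0)
  expect_equal(unclass(P), matrix(c(0, .5, .5, 0), 2), ignore_attr = TRUE)
  # constant image: single occupied cell
  cst <- quantize(matrix(5, 6, 6), 4)
  expect_equal(sum(cooccurrence_matrix(cst, 90) == 1), 1)
  # random images: sum 1, symmetric, equal to the brute-force oracle
  set.seed(11)
  for (i in 1:20) {
    q <- matrix(sample(0:2, 64, replace = TRUE), 8, 8)
    attr(q, "G") <- 3L
    d <- sample(c(0, 45, 90, 135), 1)
    P <- cooccurrence_matrix(q, d)
    expect_equal(sum(P), 1, tolerance = 1e-12)
    expect_equal(unclass(P), t(unclass(P)))
    expect_equal(unclass(P), oracle_glcm(q, 3, d), ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
  expect_error(cooccurrence_matrix(matrix(0L, 1, 1), 0), "smaller")
})

test_that("Haralick descriptors match closed forms and the oracle", {
  Pcb <- matrix(c(0, .5, .5, 0), 2)
  d <- glcm_descriptors(Pcb)
  expect_equal(d[["CONTRAST"]], 1)
  expect_equal(d[["ENERGY"]], 0.5)
  expect_equal(d[["ENTROPY"]], 1)
  # constant image: energy 1, everything else degenerate
  cst <- quantize(matrix(7, 5, 5), 8)
  dc <- glcm_descriptors(cooccurrence_matrix(cst, 0))
  expect_equal(dc[["ENERGY"]], 1)
  expect_equal(dc[["CONTRAST"]], 0)
  expect_equal(dc[["ENTROPY"]], 0)
  expect_equal(dc[["CORR"]], 0)
  # uniform P over G^2 cells
  G <- 4
  expect_equal(glcm_descriptors(matrix(1 / G^2, G, G))[["ENERGY"]], 1 / G^2)
  expect_error(glcm_descriptors(matrix(c(1, 0, 0, 0.5), 2)), "normalized")
})

test_that("run-length matrices reproduce manual run enumeration", {
  toy <- rbind(c(1, 1, 2, 2), c(3, 3, 3, 3), c(1, 2, 1, 2), c(4, 4, 4, 1)) - 1L
  attr(toy, "G") <- 4L
  R <- run_length_matrix(toy, 0)
  expect_equal(R$n_runs, 9)
  expect_equal(colSums(R$counts)[1:4], c(5, 2, 1, 1), ignore_attr = TRUE)
  d <- rlm_descriptors(R)
  expect_equal(d[["SRE"]], (5 + 2 / 4 + 1 / 9 + 1 / 16) / 9, tolerance = 1e-12)
  expect_equal(d[["GLNU"]], 3)
  expect_equal(d[["RLNU"]], 31 / 9, tolerance = 1e-12)
  # constant N x N at 0 degrees: closed forms
  N <- 6
  cst <- quantize(matrix(1, N, N), 4)
  dc <- rlm_descriptors(run_length_matrix(cst, 0))
  expect_equal(dc[["SRE"]], 1 / N^2)
  expect_equal(dc[["GLNU"]], N)
  expect_equal(dc[["RLNU"]], N)
  expect_equal(dc[["RP"]], 1 / N)
  # checkerboard: all runs length 1
  cb <- matrix((row(diag(4)) + col(diag(4))) %% 2, 4, 4)
  attr(cb, "G") <- 2L
  db <- rlm_descriptors(run_length_matrix(cb, 0))
  expect_equal(db[["SRE"]], 1)
  expect_equal(db[["RP"]], 1)
})

test_that("run-length pixel conservation holds in all four directions", {
  set.seed(3)
  q <- matrix(sample(0:3, 9 * 7, replace = TRUE), 9, 7)
  attr(q, "G") <- 4L
  for (d in c(0, 45, 90, 135)) {
    R <- run_length_matrix(q, d)
    j <- seq_len(ncol(R$counts))
    expect_equal(sum(colSums(R$counts) * j), 63)
  }
})

test_that("RLM descriptors match the brute-force oracle on random images", {
  set.seed(21)
  for (i in 1:20) {
    q <- matrix(sample(0:2, 64, replace = TRUE), 8, 8)
    attr(q, "G") <- 3L
    d <- sample(c(0, 45, 90, 135), 1)
    got <- rlm_descriptors(run_length_matrix(q, d))
    expect_equal(got, oracle_rlm_desc(q, d), tolerance = 1e-12)
  }
})

test_that("SRE lies in (0, 1] with equality iff all runs have length 1", {
  set.seed(5)
  for (i in 1:30) {
    q <- matrix(sample(0:2, 36, replace = TRUE), 6, 6)
    attr(q, "G") <- 3L
    R <- run_length_matrix(q, 0)
    d <- rlm_descriptors(R)
    expect_gt(d[["SRE"]], 0)
    expect_lte(d[["SRE"]], 1)
    all_len1 <- sum(R$counts[, 1]) == R$n_runs
    expect_equal(d[["SRE"]] == 1, all_len1)
    expect_gte(d[["LRE"]], 1)
    expect_equal(d[["LRE"]] == 1, all_len1)
  }
})

test_that("directional aggregation returns mean and nonnegative range", {
  expect_equal(directional_aggregate(c(1, 2, 3, 4)), c(average = 2.5, range = 3))
  expect_equal(directional_aggregate(rep(7, 4)), c(average = 7, range = 0))
  expect_error(directional_aggregate(c(1, 2, 3)), "4")
})

test_that("extract_features emits 30 named finite values, deterministically", {
  set.seed(9)
  px <- matrix(sample(0:255, 48 * 48, replace = TRUE), 48, 48)
  f <- extract_features(px)
  expect_identical(names(f), feature_names())
  expect_length(f, 30)
  expect_true(all(is.finite(f)))
  expect_identical(f, extract_features(px))
  # constant ROI degenerates as the closed forms dictate
  fc <- extract_features(matrix(100, 32, 32))
  expect_equal(fc[["std"]], 0)
  expect_equal(fc[["CONTRASTa"]], 0)
  # 0/90-degree SRE of a constant N x N image is 1/N^2; diagonals differ,
  # so the 4-direction average must match the oracle, not 1/N^2
  sre_dirs <- vapply(c(0, 45, 90, 135), function(d)
    oracle_rlm_desc(quantize(matrix(100, 32, 32), 16), d)[["SRE"]], numeric(1))
  expect_equal(sre_dirs[1], 1 / 32^2)
  expect_equal(fc[["SREa"]], mean(sre_dirs), tolerance = 1e-12)
})

test_that("quantized-domain features are invariant under affine intensity maps", {
  set.seed(13)
  px <- matrix(sample(10:100, 40 * 40, replace = TRUE), 40, 40)
  f1 <- extract_features(px)
  f2 <- extract_features(2L * px + 5L)
  quant_feats <- setdiff(feature_names(), c("mean", "std", "skewness", "kurtosis"))
  expect_equal(f1[quant_feats], f2[quant_feats], tolerance = 1e-12)
})
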