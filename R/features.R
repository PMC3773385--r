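#' Canonical names of the 30 texture features
#'
#' Order: 4 first-order statistics; 16 co-occurrence descriptors (8 Haralick
#' descriptors, each averaged `a` and ranged `r` over the four scan
#' directions); 10 run-length descriptors (5 Galloway descriptors x
#' `{a, r}`).
#'
#' @return character vector of length 30
#' @export
feature_names <- function() {
  fo <- c("mean", "std", "skewness", "kurtosis")
  glcm <- c("ENERGY", "CONTRAST", "CORR", "VAR", "IDM", "ENTROPY", "SUMAVG", "SUMENT")
  rlm <- c("SRE", "LRE", "GLNU", "RLNU", "RP")
  c(fo,
    paste0(rep(glcm, each = 2), c("a", "r")),
    paste0(rep(rlm, each = 2), c("a", "r")))
}

#' Texture extraction configuration
#'
#' @param glcm_levels gray levels for co-occurrence quantization
#' @param rlm_levels gray levels for run-length quantization
#' @param glcm_distance co-occurrence pixel offset distance
#' @param directions scan directions in degrees; the average/range
#'   aggregation requires exactly the four canonical directions
#' @return a list of class `feature_config`
#' @export
feature_config <- function(glcm_levels = 32L, rlm_levels = 16L,
                           glcm_distance = 1L, directions = c(0, 45, 90, 135)) {
  stopifnot(glcm_levels >= 2L, rlm_levels >= 2L, glcm_distance >= 1L)
  if (length(directions) != 4L || !setequal(directions, c(0, 45, 90, 135)))
    stop("`directions` must be the four canonical directions 0, 45, 90, 135")
  structure(list(glcm_levels = as.integer(glcm_levels),
                 rlm_levels = as.integer(rlm_levels),
                 glcm_distance = as.integer(glcm_distance),
                 directions = c(0, 45, 90, 135)),
            class = "feature_config")
}

#' Quantize an intensity image to G gray levels
#'
#' Per-image linear min-max binning: `level = min(G - 1,
#' floor((v - min) * G / (max - min)))`. This convention is exactly
#' invariant under positive affine rescaling of the intensities and maps
#' constant images wholly to level 0.
#'
#' @param roi a [grayscale_roi()] or numeric matrix
#' @param G number of gray levels (>= 2)
#' @return integer matrix with values in `[0, G - 1]` and attribute `G`
#' @export
quantize <- function(roi, G) {
  stopifnot(G >= 2L)
  v <- roi_pixels(roi)
  lo <- min(v); hi <- max(v)
  q <- if (hi == lo) array(0L, dim(v)) else {
    m <- floor((v - lo) * as.numeric(G) / (hi - lo))
    m[m > G - 1] <- G - 1            # only the global maximum can overflow
    storage.mode(m) <- "integer"
    dim(m) <- dim(v)
    m
  }
  attr(q, "G") <- as.integer(G)
  q
}

#' First-order intensity statistics
#'
#' Population moments of the raw (unquantized) intensities: mean, standard
#' deviation, skewness `m3 / m2^1.5`, and Fisher excess kurtosis
#' `m4 / m2^2 - 3`. A zero-variance image returns skewness and kurtosis 0
#' by convention.
#'
#' @inheritParams quantize
#' @return named numeric vector `(mean, std, skewness, kurtosis)`
#' @export
first_order_features <- function(roi) {
  v <- as.numeric(roi_pixels(roi))
  m <- mean(v)
  d <- v - m
  m2 <- mean(d^2)
  if (m2 == 0) return(c(mean = m, std = 0, skewness = 0, kurtosis = 0))
  c(mean = m, std = sqrt(m2),
    skewness = mean(d^3) / m2^1.5,
    kurtosis = mean(d^4) / m2^2 - 3)
}

# Row/column offset for a scan direction (degrees). Row index grows
# downwards; 45 degrees points up-right, 135 up-left.
direction_offset <- function(direction) {
  switch(as.character(direction),
         "0"   = c(0L, 1L),
         "45"  = c(-1L, 1L),
         "90"  = c(-1L, 0L),
         "135" = c(-1L, -1L),
         stop("direction must be one of 0, 45, 90, 135"))
}

#' Gray-level co-occurrence matrix
#'
#' Counts ordered level pairs at the directional offset, adds the transpose
#' (symmetrization) and normalizes to sum 1. Pairs with either pixel outside
#' the image are excluded.
#'
#' @param qimg quantized image from [quantize()]
#' @param direction scan direction in degrees (0, 45, 90, 135)
#' @param distance offset length in pixels
#' @return G x G matrix of class `cooccurrence_matrix`
#' @export
cooccurrence_matrix <- function(qimg, direction, distance = 1L) {
  G <- attr(qimg, "G")
  if (is.null(G)) G <- max(qimg) + 1L
  off <- direction_offset(direction) * as.integer(distance)
  n <- nrow(qimg); m <- ncol(qimg)
  if (abs(off[1]) >= n || abs(off[2]) >= m)
    stop("image is smaller than the co-occurrence offset")
  rs <- max(1L, 1L - off[1]):min(n, n - off[1])
  cs <- max(1L, 1L - off[2]):min(m, m - off[2])
  a <- qimg[rs, cs, drop = FALSE]
  b <- qimg[rs + off[1], cs + off[2], drop = FALSE]
  counts <- tabulate(as.vector(a) + as.vector(b) * G + 1L, nbins = G * G)
  C <- matrix(counts, G, G)
  P <- C + t(C)
  P <- P / sum(P)
  structure(P, class = c("cooccurrence_matrix", "matrix"),
            direction = direction, distance = as.integer(distance))
}

#' Haralick descriptors of a co-occurrence matrix
#'
#' Eight classic descriptors computed on 0-based level indices: energy
#' (angular second moment), contrast, correlation (0 when a marginal has
#' zero variance), variance, inverse difference moment, entropy (base-2,
#' with `0 log 0 := 0`), and sum average / sum entropy over the
#' diagonal-sum distribution `p_{x+y}`.
#'
#' @param P normalized symmetric co-occurrence matrix
#' @return named numeric vector of 8 descriptors
#' @export
glcm_descriptors <- function(P) {
  P <- unclass(P)
  if (abs(sum(P) - 1) > 1e-9 || max(abs(P - t(P))) > 1e-9)
    stop("P must be a normalized, symmetric co-occurrence matrix")
  G <- nrow(P)
  lev <- 0:(G - 1)
  px <- rowSums(P)
  mu <- sum(lev * px)
  sig2 <- sum((lev - mu)^2 * px)
  I <- matrix(lev, G, G)
  J <- t(I)
  nz <- P > 0
  pxy <- as.vector(rowsum(as.vector(P), group = as.vector(I + J)))
  k <- 0:(2 * G - 2)
  c(ENERGY   = sum(P^2),
    CONTRAST = sum((I - J)^2 * P),
    CORR     = if (sig2 == 0) 0 else (sum(I * J * P) - mu^2) / sig2,
    VAR      = sum((I - mu)^2 * P),
    IDM      = sum(P / (1 + (I - J)^2)),
    ENTROPY  = -sum(P[nz] * log2(P[nz])),
    SUMAVG   = sum(k * pxy),
    SUMENT   = -sum(pxy[pxy > 0] * log2(pxy[pxy > 0])))
}

#' Gray-level run-length matrix
#'
#' Counts maximal constant-level runs along every scan line of the given
#' direction. Horizontal (0 degree) lines are image rows, vertical (90) are
#' columns, 45-degree lines are anti-diagonals and 135-degree lines main
#' diagonals (including the length-1 corner lines).
#'
#' @inheritParams cooccurrence_matrix
#' @return list with `counts` (G x Lmax run-count matrix), `n_runs`,
#'   `n_pixels` and `direction`
#' @export
run_length_matrix <- function(qimg, direction) {
  G <- attr(qimg, "G")
  if (is.null(G)) G <- max(qimg) + 1L
  n <- nrow(qimg); m <- ncol(qimg)
  sep <- -1L
  v <- switch(as.character(direction),
    "0"  = as.vector(t(cbind(qimg, sep))),
    "90" = as.vector(rbind(qimg, sep)),
    "45" = {
      sp <- split(as.vector(qimg), as.vector(row(qimg) + col(qimg)))
      unlist(lapply(sp, function(x) c(x, sep)), use.names = FALSE)
    },
    "135" = {
      sp <- split(as.vector(qimg), as.vector(row(qimg) - col(qimg)))
      unlist(lapply(sp, function(x) c(x, sep)), use.names = FALSE)
    },
    stop("direction must be one of 0, 45, 90, 135"))
  r <- rle(as.integer(v))
  keep <- r$values != sep
  lev <- r$values[keep]
  len <- r$lengths[keep]
  Lmax <- max(n, m)
  counts <- matrix(tabulate(lev + (len - 1L) * G + 1L, nbins = G * Lmax), G, Lmax)
  list(counts = counts, n_runs = sum(counts), n_pixels = n * m,
       direction = direction)
}

#' Galloway descriptors of a run-length matrix
#'
#' Short-run emphasis, long-run emphasis, gray-level nonuniformity,
#' run-length nonuniformity and run percentage.
#'
#' @param R run-length matrix from [run_length_matrix()]
#' @return named numeric vector `(SRE, LRE, GLNU, RLNU, RP)`
#' @export
rlm_descriptors <- function(R) {
  Nr <- R$n_runs
  if (Nr <= 0) stop("run-length matrix has no runs")
  j <- seq_len(ncol(R$counts))
  nj <- colSums(R$counts)
  ni <- rowSums(R$counts)
  c(SRE  = sum(nj / j^2) / Nr,
    LRE  = sum(nj * j^2) / Nr,
    GLNU = sum(ni^2) / Nr,
    RLNU = sum(nj^2) / Nr,
    RP   = Nr / R$n_pixels)
}

#' Average and range over the four scan directions
#'
#' @param values numeric vector of exactly 4 per-direction values
#' @return named vector `(average, range)`
#' @export
directional_aggregate <- function(values) {
  if (length(values) != 4L || !all(is.finite(values)))
    stop("expected exactly 4 finite per-direction values")
  c(average = mean(values), range = max(values) - min(values))
}

#' Extract the 30 texture features of one ROI
#'
#' Composes [first_order_features()], [cooccurrence_matrix()] /
#' [glcm_descriptors()] and [run_length_matrix()] / [rlm_descriptors()] over
#' the four directions, aggregating each directional descriptor into its
#' average (`a`) and range (`r`).
#'
#' @inheritParams quantize
#' @param config a [feature_config()]
#' @return named numeric vector of length 30 in [feature_names()] order
#' @export
extract_features <- function(roi, config = feature_config()) {
  px <- roi_pixels(roi)
  fo <- first_order_features(px)
  qg <- quantize(px, config$glcm_levels)
  qr <- quantize(px, config$rlm_levels)
  dirs <- config$directions
  glcm_dir <- vapply(dirs, function(d)
    glcm_descriptors(cooccurrence_matrix(qg, d, config$glcm_distance)),
    numeric(8))
  rlm_dir <- vapply(dirs, function(d)
    rlm_descriptors(run_length_matrix(qr, d)),
    numeric(5))
  agg <- function(mat) {
    out <- numeric(0)
    for (i in seq_len(nrow(mat))) {
      ar <- directional_aggregate(mat[i, ])
      out <- c(out, ar[["average"]], ar[["range"]])
      names(out)[length(out) - 1:0] <- paste0(rownames(mat)[i], c("a", "r"))
    }
    out
  }
  out <- c(fo, agg(glcm_dir), agg(rlm_dir))
  stopifnot(identical(names(out), feature_names()), all(is.finite(out)))
  out
}

#' Build a feature table for a list of ROIs
#'
#' @param rois list of [grayscale_roi()] objects
#' @param config a [feature_config()]
#' @return data frame in [feature_table_columns()] order, one row per ROI
#' @export
extract_feature_table <- function(rois, config = feature_config()) {
  feats <- t(vapply(rois, extract_features, numeric(30), config = config))
  meta <- data.frame(
    roi_id = vapply(rois, function(r) r$roi_id, character(1)),
    source_id = vapply(rois, function(r) r$source_id, character(1)),
    grade = vapply(rois, function(r) r$grade, character(1)),
    stringsAsFactors = FALSE)
  cbind(meta, as.data.frame(feats))
}

# Numeric feature matrix (and its column names) from a feature table.
feature_matrix <- function(table, features = NULL) {
  if (is.null(features))
    features <- intersect(feature_names(), names(table))
  missing <- setdiff(features, names(table))
  if (length(missing))
    stop("feature table is missing columns: ", paste(missing, collapse = ", "))
  as.matrix(table[, features, drop = FALSE])
}
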