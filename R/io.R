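#' Grayscale region of interest
#'
#' Lightweight container for one intensity image plus its provenance. Pixel
#' values are 8-bit integers in `[0, 255]`; the grade label, when known, is
#' one of `"I"`, `"II"`, `"III"`.
#'
#' @param pixels integer matrix of intensities in `[0, 255]`
#' @param grade histological grade label or `NA` when unknown
#' @param source_id section/patient identifier or `NA`
#' @param roi_id ROI identifier or `NA`
#' @return an object of class `grayscale_roi`
#' @export
grayscale_roi <- function(pixels, grade = NA_character_,
                          source_id = NA_character_, roi_id = NA_character_) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels) || min(pixels) < 0L || max(pixels) > 255L)
    stop("pixel intensities must lie in [0, 255]")
  if (!is.na(grade) && !grade %in% GRADE_LEVELS)
    stop("`grade` must be one of ", paste(GRADE_LEVELS, collapse = ", "), " or NA")
  structure(
    list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
         grade = as.character(grade), source_id = as.character(source_id),
         roi_id = as.character(roi_id)),
    class = "grayscale_roi")
}

#' @export
print.grayscale_roi <- function(x, ...) {
  cat(sprintf("<grayscale_roi> %dx%d  grade=%s  source=%s  id=%s\n",
              x$height, x$width, x$grade, x$source_id, x$roi_id))
  invisible(x)
}

# Accept a grayscale_roi or a bare matrix wherever only pixels matter.
roi_pixels <- function(x) {
  if (inherits(x, "grayscale_roi")) x$pixels
  else if (is.matrix(x)) x
  else stop("expected a grayscale_roi or a matrix")
}

#' Convert an RGB pixel array to 8-bit luminance
#'
#' Rec. 601 weights (0.299 R + 0.587 G + 0.114 B), rounded half-up and
#' clamped to `[0, 255]`. Already-grayscale input is returned unchanged, so
#' the conversion is idempotent.
#'
#' @param arr integer matrix (grayscale) or H x W x C array with C >= 3
#'   (an alpha channel, if present, is ignored)
#' @return integer matrix of gray intensities
#' @export
rgb_to_gray <- function(arr) {
  if (is.matrix(arr)) {
    storage.mode(arr) <- "integer"
    return(arr)
  }
  d <- dim(arr)
  if (length(d) == 3L && d[3] == 1L) {
    m <- arr[, , 1L]
    storage.mode(m) <- "integer"
    return(m)
  }
  if (length(d) != 3L || d[3] < 3L)
    stop("expected a grayscale matrix or an array with >= 3 channels")
  g <- 0.299 * arr[, , 1L] + 0.587 * arr[, , 2L] + 0.114 * arr[, , 3L]
  m <- pmin(pmax(floor(g + 0.5), 0), 255)
  storage.mode(m) <- "integer"
  dim(m) <- d[1:2]
  m
}

# Read a PNG/TIFF/JPEG file into an integer 0..255 array (matrix or HxWxC).
read_image_array <- function(path) {
  if (!file.exists(path)) stop("image file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = tryCatch(png::readPNG(path),
                   error = function(e) stop("unreadable PNG file: ", path, call. = FALSE)),
    tif = ,
    tiff = tryCatch(tiff::readTIFF(path, as.is = TRUE),
                    error = function(e) stop("unreadable TIFF file: ", path, call. = FALSE)),
    jpg = ,
    jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE))
        stop("JPEG input requires the EBImage package; convert to PNG/TIFF otherwise")
      e <- tryCatch(EBImage::readImage(path),
                    error = function(err) stop("unreadable JPEG file: ", path, call. = FALSE))
      a <- EBImage::imageData(e) * 255
      # EBImage stores x,y(,c); transpose to row/column convention
      if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
    },
    stop("unsupported image format '", ext, "' for ", path)
  )
  if (ext == "png") {
    arr <- arr * 255
    if (max(abs(arr - round(arr))) > 1e-6)
      stop("image ", path, " has bit depth > 8; rescale to 8-bit explicitly before loading")
    arr <- round(arr)
  }
  if (max(arr) > 255)
    stop("image ", path, " has bit depth > 8; rescale to 8-bit explicitly before loading")
  arr
}

#' Load an image file as a grayscale ROI
#'
#' Reads an 8-bit PNG, TIFF or JPEG, converting RGB input to luminance with
#' [rgb_to_gray()]. Images with more than 8 bits per channel are rejected
#' with an instruction to rescale.
#'
#' @param path image file path
#' @inheritParams grayscale_roi
#' @return a [grayscale_roi()]
#' @export
load_image <- function(path, grade = NA_character_,
                       source_id = NA_character_, roi_id = NA_character_) {
  if (is.na(roi_id)) roi_id <- tools::file_path_sans_ext(basename(path))
  grayscale_roi(rgb_to_gray(read_image_array(path)),
                grade = grade, source_id = source_id, roi_id = roi_id)
}

#' Write a grayscale ROI to a PNG file
#'
#' @param roi a [grayscale_roi()] or integer matrix
#' @param path destination `.png` path
#' @return `path`, invisibly
#' @export
write_image <- function(roi, path) {
  px <- roi_pixels(roi)
  png::writePNG(px / 255, path)
  invisible(path)
}

#' Extract fixed-size square windows from an image
#'
#' Coordinates are 0-based `(row, col)` top-left corners of half-open
#' `roi_size x roi_size` windows; every window must lie fully inside the
#' image.
#'
#' @param image a [grayscale_roi()] or matrix at least `roi_size` in each
#'   dimension
#' @param coords list of length-2 integer vectors `(row, col)`, 0-based
#' @param roi_size window side length in pixels
#' @return list of [grayscale_roi()] windows
#' @export
extract_rois <- function(image, coords, roi_size = 512L) {
  px <- roi_pixels(image)
  meta <- if (inherits(image, "grayscale_roi")) image else
    list(grade = NA_character_, source_id = NA_character_, roi_id = NA_character_)
  lapply(seq_along(coords), function(i) {
    rc <- as.integer(coords[[i]])
    if (length(rc) != 2L || anyNA(rc)) stop("coordinate ", i, " is not a (row, col) pair")
    if (rc[1] < 0L || rc[2] < 0L ||
        rc[1] + roi_size > nrow(px) || rc[2] + roi_size > ncol(px))
      stop(sprintf("ROI window at (%d, %d) of size %d exceeds the %dx%d image",
                   rc[1], rc[2], roi_size, nrow(px), ncol(px)))
    grayscale_roi(px[rc[1] + seq_len(roi_size), rc[2] + seq_len(roi_size), drop = FALSE],
                  grade = meta$grade, source_id = meta$source_id,
                  roi_id = sprintf("%s_r%d_c%d", meta$roi_id, rc[1], rc[2]))
  })
}

#' Canonical feature-table column order
#'
#' Identifier columns followed by the 30 texture features in their fixed,
#' documented order (see [feature_names()]).
#'
#' @return character vector of column names
#' @export
feature_table_columns <- function() c("roi_id", "source_id", "grade", feature_names())

#' Write / read a feature table as CSV
#'
#' The on-disk format is plain CSV in the fixed column order of
#' [feature_table_columns()]. Feature values survive a round-trip to at
#' least 12 significant digits; reading a file with missing columns raises a
#' schema error listing the absent names.
#'
#' @param table data frame with the canonical columns
#' @param path CSV file path
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns the table.
#' @export
write_feature_table <- function(table, path) {
  cols <- feature_table_columns()
  missing <- setdiff(cols, names(table))
  if (length(missing))
    stop("feature table is missing columns: ", paste(missing, collapse = ", "))
  write.csv(table[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  cols <- feature_table_columns()
  missing <- setdiff(cols, names(tab))
  if (length(missing))
    stop("feature table at ", path, " is missing columns: ",
         paste(missing, collapse = ", "))
  tab <- tab[, cols]
  for (f in feature_names()) tab[[f]] <- as.numeric(tab[[f]])
  tab
}

#' Write / read a dataset manifest as JSON
#'
#' A manifest is a data frame with columns `roi_id`, `source_id`, `grade`
#' and either a `path` (image on disk) or a `seed` (synthetic generator)
#' column.
#'
#' @param manifest manifest data frame
#' @param path JSON file path
#' @return the manifest (read) or `path` invisibly (write)
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- jsonlite::fromJSON(path)
  need <- c("roi_id", "source_id", "grade")
  missing <- setdiff(need, names(m))
  if (length(missing))
    stop("manifest at ", path, " is missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(m$roi_id)) stop("manifest roi_id values must be unique")
  m
}
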