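#' Default per-grade generator parameters
#'
#' The generator emulates the morphology that distinguishes the three
#' histological grades at low magnification: grade I fields are rich in
#' large homogeneous bright alveolar structures with sparse nuclei and no
#' necrosis; with increasing grade, cellularity (small dark nuclei) and
#' mottled mid-gray necrosis/inflammation patches grow while alveoli
#' recede. Counts are chosen so that the grade ordering of the object
#' densities is strict: nuclei I < II < III, alveoli I > II > III,
#' necrosis 0 = I < II <= III.
#'
#' @param grade `"I"`, `"II"` or `"III"`
#' @return list of class `grade_params`
#' @export
grade_params <- function(grade) {
  base <- list(
    background_mean = 180, background_sd = 5,
    alveolus_mean = 200, alveolus_sd = 4,
    necrosis_mean = 140, necrosis_sd = 15,
    nucleus_mean = 60, nucleus_sd = 3)
  p <- switch(as.character(grade),
    I = list(alveolus_count = 150, alveolus_radius = c(8, 20),
             nucleus_density = 3,  nucleus_radius = c(2, 4),
             necrosis_patch_count = 0, necrosis_radius = c(35, 65)),
    II = list(alveolus_count = 60, alveolus_radius = c(8, 18),
              nucleus_density = 8, nucleus_radius = c(2, 4),
              necrosis_patch_count = 4, necrosis_radius = c(35, 65)),
    III = list(alveolus_count = 10, alveolus_radius = c(8, 16),
               nucleus_density = 16, nucleus_radius = c(2, 4),
               necrosis_patch_count = 8, necrosis_radius = c(50, 90)),
    stop("unknown grade label: ", grade))
  out <- utils::modifyList(base, p)
  out$grade <- as.character(grade)
  validate_grade_params(out)
  structure(out, class = "grade_params")
}

validate_grade_params <- function(p) {
  stopifnot(p$alveolus_count >= 0, p$nucleus_density >= 0,
            p$necrosis_patch_count >= 0,
            all(p$alveolus_radius > 0), all(p$nucleus_radius > 0),
            all(p$necrosis_radius > 0),
            p$background_mean >= 0, p$background_mean <= 255,
            p$background_sd >= 0)
  invisible(p)
}

#' Study design of the emulated dataset
#'
#' The default mirrors a 13-section study (4/4/5 sections for grades
#' I/II/III, one section per patient) with five 512 x 512 ROIs per section:
#' 65 ROIs in total, 20/20/25 per grade.
#'
#' @param sections_per_grade integer vector of section counts per grade
#' @param rois_per_section ROIs extracted per section
#' @param roi_size ROI side length in pixels
#' @return list of class `study_design`
#' @export
study_design <- function(sections_per_grade = c(4L, 4L, 5L),
                         rois_per_section = 5L, roi_size = 512L) {
  stopifnot(length(sections_per_grade) == 3L, all(sections_per_grade >= 1L),
            rois_per_section >= 1L, roi_size >= 8L)
  structure(list(sections_per_grade = as.integer(sections_per_grade),
                 rois_per_section = as.integer(rois_per_section),
                 roi_size = as.integer(roi_size)),
            class = "study_design")
}

# Paint an axis-aligned elliptical object onto img (matrix), in place-ish.
draw_ellipse <- function(img, cy, cx, ry, rx, mean, sd) {
  n <- nrow(img); m <- ncol(img)
  rows <- max(1L, floor(cy - ry)):min(n, ceiling(cy + ry))
  cols <- max(1L, floor(cx - rx)):min(m, ceiling(cx + rx))
  if (!length(rows) || !length(cols)) return(img)
  mask <- outer(((rows - cy) / ry)^2, ((cols - cx) / rx)^2, "+") <= 1
  k <- sum(mask)
  if (k == 0L) return(img)
  vals <- mean + if (sd > 0) rnorm(k, 0, sd) else 0
  sub <- img[rows, cols, drop = FALSE]
  sub[mask] <- vals
  img[rows, cols] <- sub
  img
}

#' Generate one synthetic grade-like ROI
#'
#' Deterministic for a fixed `(grade, params, seed)` triple. Objects are
#' drawn back-to-front: Gaussian background noise, bright smooth alveoli
#' (ellipses), mottled mid-gray necrosis patches, then small dark nuclei
#' disks. Intensities are rounded and clamped to 8 bits.
#'
#' @param grade grade label `"I"`, `"II"` or `"III"`
#' @param params a [grade_params()] list
#' @param seed integer RNG seed
#' @param roi_size side length in pixels
#' @return a [grayscale_roi()]
#' @export
generate_roi <- function(grade, params = grade_params(grade), seed = 1L,
                         roi_size = 512L) {
  if (!grade %in% GRADE_LEVELS) stop("unknown grade label: ", grade)
  validate_grade_params(params)
  p <- params
  withr::with_seed(as.integer(seed), {
    img <- matrix(p$background_mean +
                    if (p$background_sd > 0) rnorm(roi_size^2, 0, p$background_sd) else 0,
                  roi_size, roi_size)
    runif_in <- function(rg) runif(1, rg[1], rg[2])
    for (i in seq_len(p$alveolus_count))
      img <- draw_ellipse(img, runif(1, 1, roi_size), runif(1, 1, roi_size),
                          runif_in(p$alveolus_radius), runif_in(p$alveolus_radius),
                          p$alveolus_mean, p$alveolus_sd)
    for (i in seq_len(p$necrosis_patch_count))
      img <- draw_ellipse(img, runif(1, 1, roi_size), runif(1, 1, roi_size),
                          runif_in(p$necrosis_radius), runif_in(p$necrosis_radius),
                          p$necrosis_mean, p$necrosis_sd)
    n_nuclei <- round(p$nucleus_density * roi_size^2 / 1e4)
    for (i in seq_len(n_nuclei)) {
      r <- runif_in(p$nucleus_radius)
      img <- draw_ellipse(img, runif(1, 1, roi_size), runif(1, 1, roi_size),
                          r, r, p$nucleus_mean, p$nucleus_sd)
    }
    px <- matrix(as.integer(pmin(pmax(floor(img + 0.5), 0), 255)),
                 roi_size, roi_size)
    grayscale_roi(px, grade = grade)
  })
}

#' Generate a full synthetic study dataset
#'
#' Sections are assigned a grade (all ROIs of a section share its grade and
#' `source_id`), and per-ROI seeds are derived deterministically from
#' `master_seed`, so two calls with the same seed produce bit-identical
#' datasets.
#'
#' @param design a [study_design()]
#' @param params named list of per-grade [grade_params()] (defaults to the
#'   package defaults for `I`, `II`, `III`)
#' @param master_seed integer master RNG seed
#' @return list with `manifest` (data frame: roi_id, source_id, grade,
#'   seed) and `images` (named list of [grayscale_roi()])
#' @export
generate_dataset <- function(design = study_design(),
                             params = list(I = grade_params("I"),
                                           II = grade_params("II"),
                                           III = grade_params("III")),
                             master_seed = 1L) {
  section_grades <- rep(GRADE_LEVELS, times = design$sections_per_grade)
  n_sections <- length(section_grades)
  n_rois <- n_sections * design$rois_per_section
  roi_seeds <- withr::with_seed(as.integer(master_seed),
                                sample.int(.Machine$integer.max - 1L, n_rois))
  manifest <- data.frame(
    roi_id = sprintf("S%02d_R%d", rep(seq_len(n_sections), each = design$rois_per_section),
                     rep(seq_len(design$rois_per_section), n_sections)),
    source_id = sprintf("S%02d", rep(seq_len(n_sections), each = design$rois_per_section)),
    grade = rep(section_grades, each = design$rois_per_section),
    seed = roi_seeds,
    stringsAsFactors = FALSE)
  images <- lapply(seq_len(n_rois), function(i) {
    roi <- generate_roi(manifest$grade[i], params[[manifest$grade[i]]],
                        seed = manifest$seed[i], roi_size = design$roi_size)
    roi$source_id <- manifest$source_id[i]
    roi$roi_id <- manifest$roi_id[i]
    roi
  })
  names(images) <- manifest$roi_id
  list(manifest = manifest, images = images)
}

#' Per-grade medians of the three trend features
#'
#' Medians of `SREa`, `GLNUa` and `RLNUa` per grade; in the emulated data
#' (and in graded tissue) SREa and RLNUa increase with grade while GLNUa
#' decreases.
#'
#' @param table feature table containing `SREa`, `GLNUa`, `RLNUa`, `grade`
#' @return 3 x 3 numeric matrix, rows = features, columns = grades I..III
#' @export
trend_report <- function(table) {
  need <- c("SREa", "GLNUa", "RLNUa")
  missing <- setdiff(c(need, "grade"), names(table))
  if (length(missing))
    stop("feature table is missing columns: ", paste(missing, collapse = ", "))
  absent <- setdiff(GRADE_LEVELS, unique(table$grade))
  if (length(absent))
    stop("feature table has no rows for grade: ", paste(absent, collapse = ", "))
  out <- vapply(GRADE_LEVELS, function(g)
    vapply(need, function(f) median(table[[f]][table$grade == g]), numeric(1)),
    numeric(3))
  rownames(out) <- need
  out
}
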