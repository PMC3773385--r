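#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run in one validated list.
#' Unset fields take the documented defaults, so `pipeline_config()` is the
#' canonical study configuration.
#'
#' @param output_dir directory for the report bundle
#' @param seed master seed for dataset generation
#' @param design a [study_design()]
#' @param params per-grade [grade_params()] list
#' @param feature_cfg a [feature_config()]
#' @param alpha significance-filter threshold
#' @param classifiers classifier kinds for the leave-one-out report
#' @param ecv_classifier classifier kind for the external cross-validation
#'   report
#' @param knn_k neighbours for the kNN back end
#' @param max_subset_size largest subset enumerated in the search
#' @param n_trials external cross-validation trials
#' @param ecv_seed master seed for the split sequence
#' @param write_images also write the generated ROIs as PNG files
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(output_dir = tempfile("texgrade_run_"),
                            seed = 1L,
                            design = study_design(),
                            params = list(I = grade_params("I"),
                                          II = grade_params("II"),
                                          III = grade_params("III")),
                            feature_cfg = feature_config(),
                            alpha = 0.001,
                            classifiers = c("knn", "pnn", "svm"),
                            ecv_classifier = "pnn",
                            knn_k = 3L,
                            max_subset_size = 5L,
                            n_trials = 10L,
                            ecv_seed = seed,
                            write_images = FALSE) {
  stopifnot(alpha > 0, alpha <= 1, n_trials >= 1L,
            all(classifiers %in% c("knn", "pnn", "svm")),
            ecv_classifier %in% c("knn", "pnn", "svm"))
  structure(list(output_dir = output_dir, seed = as.integer(seed),
                 design = design, params = params, feature_cfg = feature_cfg,
                 alpha = alpha, classifiers = classifiers,
                 ecv_classifier = ecv_classifier, knn_k = as.integer(knn_k),
                 max_subset_size = as.integer(max_subset_size),
                 n_trials = as.integer(n_trials),
                 ecv_seed = as.integer(ecv_seed),
                 write_images = isTRUE(write_images)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' Recognized keys mirror the arguments of [pipeline_config()]; unknown
#' keys are rejected. Nested `design`, `params` and `feature_cfg` blocks
#' override individual fields of the defaults.
#'
#' @param path `.yaml`/`.yml`/`.json` file
#' @return a [pipeline_config()]
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  args <- raw[setdiff(names(raw), c("design", "params", "feature_cfg"))]
  if (!is.null(raw$design))
    args$design <- do.call(study_design, raw$design)
  if (!is.null(raw$feature_cfg))
    args$feature_cfg <- do.call(feature_config, raw$feature_cfg)
  if (!is.null(raw$params)) {
    params <- list(I = grade_params("I"), II = grade_params("II"),
                   III = grade_params("III"))
    for (g in names(raw$params)) {
      params[[g]] <- utils::modifyList(params[[g]], raw$params[[g]])
      validate_grade_params(params[[g]])
    }
    args$params <- params
  }
  do.call(pipeline_config, args)
}

#' Run the full analysis pipeline
#'
#' Generate (synthetic dataset) -> extract (feature table) -> select
#' (filter + exhaustive search) -> evaluate (leave-one-out per classifier,
#' external cross-validation). Every stage writes its artifact into
#' `config$output_dir`, so each downstream report is recomputable from the
#' persisted feature table alone, and a rerun with the same config is
#' numerically identical.
#'
#' @param config a [pipeline_config()] or path to a YAML/JSON config file
#' @param quiet suppress progress messages
#' @return (invisibly) list with the feature table, filter result, best
#'   subsets, LOO results, ECV result and file paths
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  out <- function(f) file.path(config$output_dir, f)

  say("[generate] synthetic dataset, master seed ", config$seed)
  ds <- generate_dataset(config$design, config$params, master_seed = config$seed)
  write_manifest(ds$manifest, out("manifest.json"))
  if (config$write_images) {
    dir.create(out("images"), showWarnings = FALSE)
    for (id in names(ds$images))
      write_image(ds$images[[id]], out(file.path("images", paste0(id, ".png"))))
  }

  say("[extract] 30 texture features x ", length(ds$images), " ROIs")
  tab <- extract_feature_table(ds$images, config$feature_cfg)
  write_feature_table(tab, out("features.csv"))

  say("[select] ANOVA filter at p < ", config$alpha, " + exhaustive search")
  filt <- significance_filter(tab, alpha = config$alpha)
  cand <- filt$retained
  if (!length(cand)) cand <- names(which.min(filt$pvalues))

  best <- list()
  loo <- list()
  for (kind in config$classifiers) {
    spec <- classifier_spec(kind, k = config$knn_k)
    cand_k <- if (kind == "svm") cand[order(filt$pvalues[cand])] else cand
    best[[kind]] <- exhaustive_search(tab, spec = spec, candidate_features = cand_k,
                                      max_subset_size = config$max_subset_size)
    loo[[kind]] <- loo_evaluate(tab, spec = best[[kind]]$spec,
                                subset = best[[kind]]$features)
    say(sprintf("[evaluate-loo] %s: %.1f%% with {%s}", kind,
                loo[[kind]]$overall, paste(best[[kind]]$features, collapse = ", ")))
  }
  selection_report <- list(
    alpha = config$alpha, pvalues = as.list(filt$pvalues),
    wilks_p = filt$wilks_p, retained = cand,
    best_subsets = lapply(best, function(b)
      list(features = b$features, loo_accuracy = b$accuracy,
           n_evaluated = b$n_evaluated)))
  jsonlite::write_json(selection_report, out("selection.json"),
                       auto_unbox = TRUE, digits = NA)
  loo_report <- data.frame(
    classifier = names(loo),
    t(vapply(loo, function(r) c(r$partial, overall = r$overall), numeric(4))),
    best_features = vapply(best, function(b) paste(b$features, collapse = "+"),
                           character(1)),
    check.names = FALSE)
  write.csv(loo_report, out("loo_report.csv"), row.names = FALSE)

  say("[evaluate-ecv] ", config$n_trials, " stratified splits, ",
      config$ecv_classifier, " classifier")
  ecv <- ecv_evaluate(tab, spec = classifier_spec(config$ecv_classifier,
                                                  k = config$knn_k),
                      n_trials = config$n_trials, master_seed = config$ecv_seed,
                      alpha = config$alpha,
                      max_subset_size = config$max_subset_size)
  ecv_report <- data.frame(trial = seq_len(nrow(ecv$accuracies)),
                           ecv$accuracies,
                           n_features = ecv$subset_sizes, check.names = FALSE)
  write.csv(ecv_report, out("ecv_report.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(mean = as.list(ecv$summary$mean_1dp), sd = as.list(ecv$summary$sd_1dp)),
    out("ecv_summary.json"), auto_unbox = TRUE, digits = NA)
  say(sprintf("[done] ECV mean overall %.1f +/- %.1f %%",
              ecv$summary$mean_1dp[["overall"]], ecv$summary$sd_1dp[["overall"]]))

  invisible(list(manifest = ds$manifest, features = tab, filter = filt,
                 best = best, loo = loo, ecv = ecv,
                 paths = vapply(c("manifest.json", "features.csv", "selection.json",
                                  "loo_report.csv", "ecv_report.csv",
                                  "ecv_summary.json"), out, character(1))))
}
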