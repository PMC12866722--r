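# End-to-end experiment runner for the three diagnostic tasks: cancer
# presence (binary), early-stage presence (binary after a stage filter),
# and 11-class typing. Stages: simulate (or read) -> preprocess ->
# cross-validate -> diagnose -> interpret -> write results + manifest.

#' Experiment configuration
#'
#' @param task `"presence"`, `"early_stage"` or `"multiclass"`
#' @param plan a [cohort_plan()] for simulated runs, or `NULL` when reading
#'   spectra from `input`
#' @param input path to a spectra CSV (see [read_spectra()]); ignored when
#'   `plan` is given
#' @param truth optional ground-truth sidecar path for `input`
#' @param preprocess a [preprocess_config()]
#' @param model a [model_config()]; `NULL` picks a default matching the
#'   task's class count
#' @param k cross-validation folds
#' @param seed master seed (overrides `plan$seed` and `model$seed`)
#' @param threshold binary positive-call threshold on the mean cancer
#'   probability
#' @param early_stages stage labels treated as early (TNM T1N0M0/T2N0M0,
#'   FIGO I for ovarian)
#' @param out_dir output directory
#' @param make_plots write ROC / history / heatmap images
#' @return an object of class `run_config`
#' @export
run_config <- function(task = c("presence", "early_stage", "multiclass"),
                       plan = NULL, input = NULL, truth = NULL,
                       preprocess = preprocess_config(), model = NULL,
                       k = 5L, seed = 1L, threshold = 0.5,
                       early_stages = c("T1N0M0", "T2N0M0", "FIGO_I"),
                       out_dir = NULL, make_plots = FALSE) {
  task <- match.arg(task)
  if (is.null(plan) && is.null(input))
    stop("either a cohort plan or an input path is required")
  if (is.null(plan) || is.null(model)) {
    # defer n_classes resolution for file input until run time
  }
  structure(list(task = task, plan = plan, input = input, truth = truth,
                 preprocess = preprocess, model = model, k = as.integer(k),
                 seed = as.integer(seed), threshold = threshold,
                 early_stages = early_stages, out_dir = out_dir,
                 make_plots = make_plots),
            class = "run_config")
}

#' Keep only early-stage cancer samples (plus all controls)
#'
#' Drops cancer samples whose stage annotation is not in the early set;
#' logs the excluded sample count.
#'
#' @param ds a [sers_cohort()]
#' @param early stage labels treated as early
#' @return the filtered [sers_cohort()]
#' @export
early_stage_filter <- function(ds, early = c("T1N0M0", "T2N0M0",
                                             "FIGO_I")) {
  keep <- ds$info$class == "non_cancer" | ds$info$stage %in% early
  excluded <- unique(ds$info$sample_id[!keep])
  message("early-stage filter: ", length(excluded), " sample(s) excluded")
  subset_cohort(ds, spectra = which(keep))
}

# default task-appropriate model config
default_model_for <- function(task, n_classes, seed) {
  model_config(n_classes = n_classes, seed = seed)
}

#' Run a full diagnostic experiment
#'
#' Executes the configured pipeline and writes, under `out_dir`:
#' `metrics.json` (accuracies, per-class sensitivity/specificity, AUCs,
#' band importances, peak-ratio statistics), CSV tables (sample diagnoses,
#' per-spectrum predictions, confusion matrix, importance profile,
#' differential spectra), optional plots, and `manifest.json` recording the
#' seed, a configuration hash and the package version. Rerunning with the
#' same configuration and seed reproduces `metrics.json` byte-for-byte.
#'
#' @param cfg a [run_config()]
#' @return invisibly, a list with the cohort, cross-validation result,
#'   diagnoses, evaluation, interpretability objects and output paths
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  t0 <- Sys.time()

  # ---- data ----
  if (!is.null(cfg$plan)) {
    plan <- cfg$plan
    plan$seed <- cfg$seed
    ds <- simulate_cohort(plan)
  } else {
    ds <- read_spectra(cfg$input, truth = cfg$truth)
  }
  if (cfg$task == "early_stage") ds <- early_stage_filter(ds,
                                                          cfg$early_stages)
  if (cfg$task %in% c("presence", "early_stage") &&
      length(unique(ds$info$class)) > 2L) {
    # collapse all cancer types into one positive class
    ds$info$class[ds$info$class != "non_cancer"] <- "cancer"
  }
  classes <- sort(unique(ds$info$class))
  message(sprintf("[data] %d spectra / %d samples / %d classes",
                  n_spectra(ds), n_samples(ds), length(classes)))

  # ---- preprocessing (full chain; unnormalized copy for ratio stats) ----
  pp_full <- preprocess_pipeline(ds, cfg$preprocess)
  pp_raw <- preprocess_pipeline(ds, cfg$preprocess,
                                steps = setdiff(cfg$preprocess$steps,
                                                "normalize"))
  message("[preprocess] steps: ",
          paste(cfg$preprocess$steps, collapse = " -> "))

  # ---- model ----
  mcfg <- cfg$model %||% default_model_for(cfg$task, length(classes),
                                           cfg$seed)
  mcfg$seed <- cfg$seed
  if (mcfg$n_classes != length(classes))
    stop("model n_classes (", mcfg$n_classes,
         ") does not match the cohort (", length(classes), ")")
  cv <- cross_validate(pp_full, mcfg, k = cfg$k)
  message("[crossval] done")

  # ---- diagnosis ----
  thr <- if (length(classes) == 2L) cfg$threshold else NULL
  diagnoses <- aggregate_samples(cv, use = "refined", threshold = thr)
  diagnoses_cnn <- aggregate_samples(cv, use = "cnn", threshold = thr)
  ev <- evaluate_diagnoses(diagnoses)
  ev_cnn <- evaluate_diagnoses(diagnoses_cnn)
  message(sprintf("[diagnose] sample-level accuracy %.3f (CNN %.3f)",
                  ev$accuracy, ev_cnn$accuracy))

  # ---- interpretability (fold-1 CNN, saliency over all spectra) ----
  imp <- feature_importance(cv$models$cnn[[1]], pp_full$intensities,
                            method = "saliency", grid = ds$grid)
  bands <- band_importance(imp, centers = c(1080, 1380), window = 10)
  dmat <- differential_matrix(pp_full, reference = "non_cancer")
  cancer_classes <- setdiff(classes, "non_cancer")
  ratio_1080 <- peak_ratio_test(pp_raw, 1080, 643)
  ratio_1380 <- peak_ratio_test(pp_raw, 1380, 643)

  metrics <- list(
    task = cfg$task, n_samples = n_samples(ds), n_spectra = n_spectra(ds),
    classes = classes,
    sample_accuracy = ev$accuracy,
    sample_accuracy_cnn = ev_cnn$accuracy,
    macro_sensitivity = ev$macro_sensitivity,
    macro_specificity = ev$macro_specificity,
    auc = as.list(ev$auc), macro_auc = ev$macro_auc,
    per_class = ev$per_class,
    importance_percent_1080 = unname(bands["1080"]),
    importance_percent_1380 = unname(bands["1380"]),
    ratio_1080_643 = list(means = as.list(ratio_1080$means),
                          t = ratio_1080$t, p = ratio_1080$p,
                          stars = ratio_1080$stars),
    ratio_1380_643 = list(means = as.list(ratio_1380$means),
                          t = ratio_1380$t, p = ratio_1380$p,
                          stars = ratio_1380$stars))

  paths <- list()
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(name) file.path(cfg$out_dir, name)
    jsonlite::write_json(metrics, w("metrics.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    data.table::fwrite(diagnoses, w("sample_diagnoses.csv"))
    data.table::fwrite(cv$predictions, w("predictions.csv"))
    data.table::fwrite(as.data.frame.matrix(ev$confusion), w("confusion.csv"),
                       row.names = TRUE)
    data.table::fwrite(imp, w("importance.csv"))
    data.table::fwrite(data.frame(class = rownames(dmat), dmat,
                                  check.names = FALSE),
                       w("differential.csv"))
    probability_heatmap(cv, csv = w("probability_heatmap.csv"),
                        plot = if (cfg$make_plots)
                          w("probability_heatmap.png"))
    if (cfg$make_plots) {
      plot_roc(ev, w("roc.png"))
      plot_history(cv, w("history.png"))
    }
    manifest <- list(task = cfg$task, seed = cfg$seed,
                     config_hash = rlang::hash(cfg),
                     package_version = as.character(
                       packageVersion("sersdx")),
                     n_samples = n_samples(ds), n_spectra = n_spectra(ds),
                     k = cfg$k)
    jsonlite::write_json(manifest, w("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    paths <- list(metrics = w("metrics.json"),
                  manifest = w("manifest.json"))
  }
  message(sprintf("[done] %.1f s elapsed",
                  as.numeric(Sys.time() - t0, units = "secs")))
  invisible(list(cohort = ds, preprocessed = pp_full, cv = cv,
                 diagnoses = diagnoses, evaluation = ev,
                 evaluation_cnn = ev_cnn, importance = imp,
                 band_importance = bands, differential = dmat,
                 ratio_1080 = ratio_1080, ratio_1380 = ratio_1380,
                 metrics = metrics, paths = paths))
}
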