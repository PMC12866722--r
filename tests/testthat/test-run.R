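# Experiment runner: early-stage filtering, output contract, manifest.

test_that("early-stage filter keeps controls and early cancers only", {
  plan <- binary_cohort_plan(samples_per_class = 12,
                             spectra_per_sample = 2, seed = 61,
                             grid = coarse_grid())
  ds <- simulate_cohort(plan)
  expect_message(f <- early_stage_filter(ds), "excluded")
  expect_true(all(f$info$class == "non_cancer" |
                    f$info$stage %in% c("T1N0M0", "T2N0M0", "FIGO_I")))
  kept_cancer <- unique(f$info$sample_id[f$info$class == "cancer"])
  all_cancer <- unique(ds$info$sample_id[ds$info$class == "cancer"])
  late <- unique(ds$info$sample_id[!is.na(ds$info$stage) &
                                     !ds$info$stage %in%
                                       c("T1N0M0", "T2N0M0", "FIGO_I")])
  expect_setequal(kept_cancer, setdiff(all_cancer, late))
  expect_equal(sum(f$info$class == "non_cancer"),
               sum(ds$info$class == "non_cancer"))
})

test_that("run_experiment writes the full result contract", {
  dir <- withr::local_tempdir()
  cfg <- run_config(task = "presence",
                    plan = binary_cohort_plan(samples_per_class = 4,
                                              spectra_per_sample = 6),
                    model = model_config(2, epochs = 5),
                    k = 2, seed = 67, out_dir = dir)
  res <- suppressMessages(run_experiment(cfg))
  for (f in c("metrics.json", "manifest.json", "sample_diagnoses.csv",
              "predictions.csv", "confusion.csv", "importance.csv",
              "differential.csv", "probability_heatmap.csv"))
    expect_true(file.exists(file.path(dir, f)), info = f)
  metrics <- jsonlite::read_json(file.path(dir, "metrics.json"))
  expect_true(is.numeric(metrics$sample_accuracy))
  expect_equal(metrics$task, "presence")
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$seed, 67L)
  expect_match(manifest$config_hash, "^[0-9a-f]+$")
})
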