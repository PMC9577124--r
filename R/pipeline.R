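#' @importFrom rlang .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Assemble a full run configuration
#'
#' Bundles every tunable of the pipeline into one serializable list so a
#' run can be re-executed from its persisted config and seed alone.
#'
#' @param world A [world_config()].
#' @param test_frac Held-out case fraction.
#' @param denoise_threshold Stage-1 disagreement threshold.
#' @param pseudo_label_enabled Run the pseudo-labeling step.
#' @param epochs_stage1,epochs_stage2 Training epochs per stage.
#' @param n_boot Bootstrap iterations in the evaluation.
#' @param seed Global seed (also used to derive stage seeds).
#' @return A `run_config` list.
#' @export
run_config <- function(world = world_config(), test_frac = 0.3,
                       denoise_threshold = 0.1, pseudo_label_enabled = TRUE,
                       epochs_stage1 = 15, epochs_stage2 = 25,
                       n_boot = 1000, seed = 1) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full pipeline: simulate, train in two stages, predict, evaluate
#'
#' Executes simulate -> stage-1 train -> curate -> stage-2 train ->
#' predict -> evaluate and writes all stage artifacts under `out_dir`:
#' the world (cohort, spot images, ground-truth manifest), the curation
#' report (JSON + discarded/pseudo-labeled TSVs), the scores CSV, the
#' metrics JSON, and a run manifest recording the config and seed. A
#' leakage guard refuses any train/test case overlap before training.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created; must not pre-exist unless
#'   `overwrite`).
#' @param overwrite Allow writing into an existing directory.
#' @param write_images Also write the spot PNGs (default FALSE to keep
#'   runs light).
#' @return Invisibly, a list with `fit` (the [two_stage_train()] result),
#'   `report` (the evaluation report), `scores`, and `out_dir`.
#' @export
run_pipeline <- function(config = run_config(), out_dir, overwrite = FALSE,
                         write_images = FALSE) {
  if (dir.exists(out_dir) && !overwrite) stop("out_dir exists; pass overwrite = TRUE")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  world <- simulate_world(config$world)
  write_cohort(world$cohort, file.path(out_dir, "cohort.tsv"))
  if (write_images) write_world(world, file.path(out_dir, "world"))

  fit <- two_stage_train(
    world, test_frac = config$test_frac,
    epochs_stage1 = config$epochs_stage1, epochs_stage2 = config$epochs_stage2,
    denoise_threshold = config$denoise_threshold,
    pseudo_label_enabled = config$pseudo_label_enabled, seed = config$seed
  )

  # curation report
  readr::write_tsv(fit$curated$discarded[, c("spot_id", "case_id", "reason")],
                   file.path(out_dir, "discarded.tsv"))
  pl <- fit$curated$pseudo_labeled
  readr::write_tsv(
    if (nrow(pl)) pl[, c("case_id", "tma_id", "fu_years")] else
      tibble::tibble(case_id = character(), tma_id = character(), fu_years = double()),
    file.path(out_dir, "pseudo_labeled.tsv"))
  jsonlite::write_json(fit$counts, file.path(out_dir, "curation_report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)

  scores <- tibble::tibble(
    spot_id = fit$test$spot_id, case_id = fit$test$case_id,
    pcai = unname(fit$test$score)
  )
  readr::write_csv(scores, file.path(out_dir, "scores.csv"))

  test_cohort <- world$cohort[world$cohort$case_id %in% fit$split$test_cases, ]
  report <- evaluate_scores(scores, assign_risk_label(test_cohort, mode = "test"),
                            n_boot = config$n_boot)
  jsonlite::write_json(
    list(auc = report$auc, balanced_accuracy = report$balanced_accuracy,
         confusion = as.list(stats::setNames(as.integer(report$confusion),
                                             names(report$confusion))),
         cox = tidy(report$cox), auc_raw_spot = fit$auc_raw,
         auc_cleaned_spot = fit$auc_cleaned),
    file.path(out_dir, "metrics.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA)

  manifest <- list(
    package_version = as.character(utils::packageVersion("pcai")),
    seed = config$seed,
    config = config[setdiff(names(config), "world")],
    world_config = unclass(config$world),
    stages = c("simulate", "train_stage1", "curate", "train_stage2",
               "predict", "evaluate")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(fit = fit, report = report, scores = scores, out_dir = out_dir))
}
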