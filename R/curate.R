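#' Discard training samples whose stage-1 prediction contradicts the label
#'
#' A sample is discarded iff the stage-1 model's predicted probability of
#' the sample's own label falls below the disagreement threshold. The
#' rationale: 0.6 mm TMA spots are sometimes sampled at a location that is
#' unrepresentative of the whole prostate, so a confident contradiction of
#' the outcome-derived label flags a likely unrepresentative spot.
#' Denoising never changes a label, only membership.
#'
#' @param samples A tibble with at least `spot_id` and `risk_label`
#'   (values "high"/"low").
#' @param stage1_scores Numeric vector, aligned with `samples`: the
#'   stage-1 predicted probability of the *high* class.
#' @param threshold Discard when `P(label) <` threshold (default 0.1;
#'   0 discards nothing).
#' @return A `curated_dataset`: list with `kept` (tibble), `discarded`
#'   (tibble with `p_label` and `reason`), `pseudo_labeled` (empty here).
#' @export
denoise <- function(samples, stage1_scores, threshold = 0.1) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  if (length(stage1_scores) != nrow(samples)) {
    stop("need one stage-1 score per sample")
  }
  if (anyNA(stage1_scores)) stop("missing stage-1 score(s)")
  p_label <- ifelse(samples$risk_label == "high", stage1_scores, 1 - stage1_scores)
  drop <- p_label < threshold
  discarded <- samples[drop, ]
  if (nrow(discarded) > 0) {
    discarded$p_label <- p_label[drop]
    discarded$reason <- sprintf("P(label)=%.3f < %.3f", p_label[drop], threshold)
  } else {
    discarded$p_label <- numeric(0)
    discarded$reason <- character(0)
  }
  structure(list(kept = samples[!drop, ], discarded = discarded,
                 pseudo_labeled = samples[0, ]), class = "curated_dataset")
}

#' Pseudo-label likely low-risk cases to balance each TMA
#'
#' Candidates are "possible-low-risk" cases: no bad outcome but follow-up
#' of 5 years or less, so not yet confirmable as low risk. Per TMA,
#' candidates are added as low-risk starting at the longest follow-up and
#' descending, until the TMA reaches label balance (low count = high
#' count) or the candidate pool is depleted. Ties in follow-up break by
#' `case_id` for determinism. Pseudo-labeling only ever adds lows.
#'
#' @param samples Labelled training samples: tibble with `case_id`,
#'   `tma_id`, `risk_label` ("high"/"low").
#' @param candidates Possible-low-risk candidates: tibble with `case_id`,
#'   `tma_id`, `fu_years`, `bad_outcome` (all must be event-free with
#'   `fu_years <= 5`).
#' @return A `curated_dataset` whose `kept` is the input plus the added
#'   lows, and `pseudo_labeled` lists the additions.
#' @export
pseudo_label <- function(samples, candidates) {
  if (nrow(candidates) > 0) {
    ok <- !candidates$bad_outcome & candidates$fu_years <= 5
    if (!all(ok)) {
      stop("candidates must be possible-low-risk: event-free with follow-up <= 5 years")
    }
  }
  samples$risk_label <- as.character(samples$risk_label)
  added <- list()
  for (tma in unique(samples$tma_id)) {
    in_tma <- samples$risk_label[samples$tma_id == tma]
    deficit <- sum(in_tma == "high") - sum(in_tma == "low")
    if (deficit <= 0) next
    pool <- candidates[candidates$tma_id == tma, ]
    if (nrow(pool) == 0) next
    pool <- pool[order(-pool$fu_years, pool$case_id), ]
    take <- utils::head(pool, deficit)
    take$risk_label <- rep("low", nrow(take))
    added[[tma]] <- take
  }
  added <- if (length(added)) dplyr::bind_rows(added) else candidates[0, ]
  kept <- dplyr::bind_rows(
    samples,
    if (nrow(added)) added[intersect(names(added), c(names(samples), "risk_label"))]
  )
  structure(list(kept = kept, discarded = samples[0, ], pseudo_labeled = added),
            class = "curated_dataset")
}

#' Draft a TMA-balanced training epoch
#'
#' From every TMA, `k = min(#high, #low)` samples are drawn without
#' replacement from each class, so each TMA contributes an exactly
#' class-balanced subset and the model cannot profit from TMA-specific
#' staining or thickness bias. TMAs with a missing class contribute
#' nothing (until pseudo-labeling opens them up). Redrawn fresh each
#' epoch from the global RNG.
#'
#' @param samples Tibble with `tma_id` and `risk_label` ("high"/"low").
#' @param replace Draw with replacement instead (default FALSE).
#' @return Integer row indices into `samples` forming the epoch draft.
#' @export
tma_balanced_draft <- function(samples, replace = FALSE) {
  idx <- integer(0)
  for (tma in unique(samples$tma_id)) {
    hi <- which(samples$tma_id == tma & samples$risk_label == "high")
    lo <- which(samples$tma_id == tma & samples$risk_label == "low")
    k <- min(length(hi), length(lo))
    if (k == 0) next
    pick <- function(v) if (length(v) == 1 && !replace) v else v[sample.int(length(v), k, replace = replace)]
    idx <- c(idx, pick(hi), pick(lo))
  }
  idx
}

#' Draft a globally class-balanced training epoch (ablation arm)
#'
#' Ignores TMA membership: draws `min(#high, #low)` from each class over
#' the whole training set.
#'
#' @inheritParams tma_balanced_draft
#' @return Integer row indices into `samples`.
#' @export
global_balanced_draft <- function(samples, replace = FALSE) {
  hi <- which(samples$risk_label == "high")
  lo <- which(samples$risk_label == "low")
  k <- min(length(hi), length(lo))
  if (k == 0) return(integer(0))
  c(hi[sample.int(length(hi), k, replace = replace)],
    lo[sample.int(length(lo), k, replace = replace)])
}

#' @export
print.curated_dataset <- function(x, ...) {
  cat(sprintf("<curated_dataset> %d kept (%d pseudo-labeled low), %d discarded\n",
              nrow(x$kept), nrow(x$pseudo_labeled), nrow(x$discarded)))
  if (nrow(x$kept)) {
    tab <- table(x$kept$risk_label)
    cat("  kept labels: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-TMA label bookkeeping for a curation stage
#'
#' @param samples Tibble with `tma_id`, `risk_label`.
#' @return Tibble of per-TMA high/low counts plus a total row.
#' @export
curation_counts <- function(samples) {
  per <- samples |>
    dplyr::count(.data$tma_id, .data$risk_label) |>
    tidyr::pivot_wider(names_from = "risk_label", values_from = "n", values_fill = 0)
  for (col in c("high", "low")) if (!col %in% names(per)) per[[col]] <- 0L
  dplyr::bind_rows(per, tibble::tibble(tma_id = "total",
                                       high = sum(per$high), low = sum(per$low)))
}

#' Run the full two-stage training procedure on a synthetic world
#'
#' Stage 1 trains a prototype model on the raw TMA-balanced draft of the
#' train split. Its predictions then denoise the train split (discarding
#' spots whose label they contradict) and pseudo-labeling adds likely
#' low-risk cases per TMA; stage 2 trains on the curated set. The test
#' split is fixed before any curation, is never pseudo-labeled, and is
#' evaluated both raw and (separately, with the stage-1 denoiser) cleaned.
#'
#' For tractability the procedure trains the single mid-context scale
#' (0.5, the scale the ablation experiments also use) unless `scales`
#' names several.
#'
#' @param world A `tma_world` from [simulate_world()].
#' @param test_frac Fraction of cases held out (default 0.3).
#' @param scales A named list of [scale_spec()]s; default a single 0.5
#'   scale with a patch size fitting the world's spots.
#' @param spec A [model_spec()] template for both stages.
#' @param epochs_stage1,epochs_stage2 Training epochs per stage.
#' @param denoise_threshold Stage-1 disagreement threshold (default 0.1).
#' @param pseudo_label_enabled Include the pseudo-labeling step (default
#'   TRUE).
#' @param seed Seed for the split, drafting and training randomness.
#' @return A `two_stage_fit` list: `model_stage1`, `model_stage2`,
#'   `curated` (the curated dataset), `counts` (per-stage label
#'   bookkeeping), `test` (test-split tibble with stage-2 scores),
#'   `auc_raw`, `auc_cleaned`, `split`.
#' @export
two_stage_train <- function(world, test_frac = 0.3, scales = NULL, spec = NULL,
                            epochs_stage1 = 15, epochs_stage2 = 25,
                            denoise_threshold = 0.1,
                            pseudo_label_enabled = TRUE, seed = 1) {
  if (is.null(scales)) {
    patch <- min(48L, floor(world$config$spot_px * 0.5))
    scales <- list(s05 = scale_spec(0.5, patch))
  }
  if (is.null(spec)) {
    spec <- model_spec(patch_px = scales[[1]]$patch_px, seed = seed)
  }

  labelled <- assign_risk_label(world$cohort, mode = "train")
  labelled <- dplyr::inner_join(world$spots, labelled, by = c("case_id", "tma_id"))

  cases <- unique(labelled$case_id)
  test_cases <- with_seed(seed, sample(cases, round(test_frac * length(cases))))
  train <- labelled[!labelled$case_id %in% test_cases, ]
  test <- labelled[labelled$case_id %in% test_cases, ]
  assert_no_leakage(train$case_id, test$case_id)

  # encode every spot once per scale; training reuses cached features
  feats <- encode_world(world, scales, spec)

  train_def <- train[train$risk_label %in% c("high", "low"), ]
  train_def$risk_label <- as.character(train_def$risk_label)
  counts <- list(stage1 = curation_counts(train_def))

  fit_one <- function(samples, epochs, fit_seed) {
    f <- feats[[1]][samples$spot_id]
    y <- samples$risk_label == "high"
    draft <- function(ep) tma_balanced_draft(samples)
    with_seed(fit_seed, {
      train_mil(init_mil_model(spec, head_seed = fit_seed), f, y,
                epochs = epochs, draft_fun = draft)
    })
  }

  model1 <- fit_one(train_def, epochs_stage1, seed + 101L)
  s1_train <- predict_bags(model1, feats[[1]][train_def$spot_id])$score

  cur <- denoise(train_def, s1_train, threshold = denoise_threshold)
  counts$denoised <- curation_counts(cur$kept)

  if (pseudo_label_enabled) {
    cand <- train[train$risk_label == "undefined" &
                    !train$bad_outcome & train$fu_years <= 5, ]
    cur2 <- pseudo_label(cur$kept, cand)
    curated <- structure(list(kept = cur2$kept, discarded = cur$discarded,
                              pseudo_labeled = cur2$pseudo_labeled),
                         class = "curated_dataset")
  } else {
    curated <- cur
  }
  counts$curated <- curation_counts(curated$kept)

  model2 <- fit_one(curated$kept, epochs_stage2, seed + 202L)

  test_def <- test[test$risk_label %in% c("high", "low"), ]
  test_def$score <- predict_bags(model2, feats[[1]][test_def$spot_id])$score
  auc_raw <- auc_score(test_def$score, test_def$risk_label == "high")

  s1_test <- predict_bags(model1, feats[[1]][test_def$spot_id])$score
  cleaned <- denoise(test_def, s1_test, threshold = denoise_threshold)$kept
  auc_cleaned <- if (length(unique(cleaned$risk_label)) == 2) {
    auc_score(cleaned$score, cleaned$risk_label == "high")
  } else NA_real_

  structure(list(
    model_stage1 = model1, model_stage2 = model2, curated = curated,
    counts = counts, test = test_def, auc_raw = auc_raw,
    auc_cleaned = auc_cleaned,
    split = list(test_cases = test_cases)
  ), class = "two_stage_fit")
}

assert_no_leakage <- function(train_cases, test_cases) {
  overlap <- intersect(unique(train_cases), unique(test_cases))
  if (length(overlap) > 0) {
    stop("leakage guard: case_id(s) appear in both train and test: ",
         paste(utils::head(overlap, 5), collapse = ", "))
  }
  invisible(TRUE)
}

# encode all world spots once per scale; returns list(scale -> named list of
# feature matrices keyed by spot_id)
encode_world <- function(world, scales, spec) {
  enc_model <- init_mil_model(spec)
  lapply(scales, function(sc) {
    out <- vector("list", length(world$images))
    names(out) <- names(world$images)
    for (id in names(world$images)) {
      bag <- make_instances(world$images[[id]], sc, offset = c(0L, 0L))
      out[[id]] <- encode_instances(bag, enc_model)
    }
    out
  })
}

#' @export
print.two_stage_fit <- function(x, ...) {
  cat(sprintf("<two_stage_fit> held-out spot AUC: raw %.3f, cleaned %s\n",
              x$auc_raw,
              if (is.na(x$auc_cleaned)) "NA" else sprintf("%.3f", x$auc_cleaned)))
  print(x$curated)
  invisible(x)
}

#' Three-arm sampling ablation on one synthetic world
#'
#' Trains three stage-2 models with identical architecture but different
#' training-set selection, mirroring the sampling ablation: (a) globally
#' class-balanced drafting on the raw train set, (b) TMA-balanced drafting
#' on the raw train set, (c) TMA-balanced drafting on the denoised and
#' pseudo-labeled train set. All arms share the world, the split, the
#' cached instance features and the stage-1 curation model, and are
#' evaluated on the same raw held-out spots. By default the held-out set
#' consists of whole TMA blocks the training arms never saw, so that a
#' model which overfits TMA-specific staining or thickness signatures is
#' penalised rather than rewarded.
#'
#' @param split_by Hold out whole TMA blocks (`"tma"`, default) or a
#'   random fraction of cases (`"case"`).
#'
#' @inheritParams two_stage_train
#' @param epochs Stage-2 epochs per arm.
#' @return A tibble with one row per arm: `arm`, `auc`.
#' @export
ablation_arms <- function(world, test_frac = 0.3, split_by = c("tma", "case"),
                          scales = NULL, spec = NULL,
                          epochs = 25, epochs_stage1 = 15,
                          denoise_threshold = 0.1, seed = 1) {
  split_by <- match.arg(split_by)
  if (is.null(scales)) {
    patch <- min(48L, floor(world$config$spot_px * 0.5))
    scales <- list(s05 = scale_spec(0.5, patch))
  }
  if (is.null(spec)) spec <- model_spec(patch_px = scales[[1]]$patch_px, seed = seed)

  labelled <- assign_risk_label(world$cohort, mode = "train")
  labelled <- dplyr::inner_join(world$spots, labelled, by = c("case_id", "tma_id"))
  if (split_by == "tma") {
    # hold out whole TMA blocks so a model that memorized TMA signatures
    # gains nothing at test time (the withheld-block convention)
    tmas <- unique(labelled$tma_id)
    test_tmas <- with_seed(seed, sample(tmas, max(2, round(test_frac * length(tmas)))))
    test_cases <- unique(labelled$case_id[labelled$tma_id %in% test_tmas])
  } else {
    cases <- unique(labelled$case_id)
    test_cases <- with_seed(seed, sample(cases, round(test_frac * length(cases))))
  }
  train <- labelled[!labelled$case_id %in% test_cases, ]
  test <- labelled[labelled$case_id %in% test_cases, ]
  assert_no_leakage(train$case_id, test$case_id)

  feats <- encode_world(world, scales, spec)[[1]]
  train_def <- train[train$risk_label %in% c("high", "low"), ]
  train_def$risk_label <- as.character(train_def$risk_label)
  test_def <- test[test$risk_label %in% c("high", "low"), ]

  fit_with_draft <- function(samples, draft_fun, fit_seed) {
    with_seed(fit_seed, {
      train_mil(init_mil_model(spec, head_seed = fit_seed),
                feats[samples$spot_id], samples$risk_label == "high",
                epochs = epochs, draft_fun = draft_fun)
    })
  }
  eval_arm <- function(model) {
    auc_score(predict_bags(model, feats[test_def$spot_id])$score,
              test_def$risk_label == "high")
  }

  # stage-1 prototype for the curated arm
  model1 <- with_seed(seed + 101L, {
    train_mil(init_mil_model(spec, head_seed = seed + 101L),
              feats[train_def$spot_id], train_def$risk_label == "high",
              epochs = epochs_stage1,
              draft_fun = function(ep) tma_balanced_draft(train_def))
  })
  s1 <- predict_bags(model1, feats[train_def$spot_id])$score
  cur <- denoise(train_def, s1, threshold = denoise_threshold)
  cand <- train[train$risk_label == "undefined" & !train$bad_outcome &
                  train$fu_years <= 5, ]
  curated <- pseudo_label(cur$kept, cand)$kept

  m_global <- fit_with_draft(train_def,
                             function(ep) global_balanced_draft(train_def),
                             seed + 301L)
  m_tma <- fit_with_draft(train_def,
                          function(ep) tma_balanced_draft(train_def),
                          seed + 302L)
  m_cur <- fit_with_draft(curated,
                          function(ep) tma_balanced_draft(curated),
                          seed + 303L)

  tibble::tibble(
    arm = c("global", "tma_balanced", "tma_balanced_curated"),
    auc = c(eval_arm(m_global), eval_arm(m_tma), eval_arm(m_cur))
  )
}
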