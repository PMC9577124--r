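test_that("denoising discards exactly the confidently contradicted samples", {
  samples <- curation_samples(list(t1 = c(2, 2)))
  # labels: high, high, low, low
  scores <- c(0.05, 0.50, 0.95, 0.60)
  # P(label): 0.05, 0.50, 0.05, 0.40 -> discard first and third at 0.1
  cur <- denoise(samples, scores, threshold = 0.1)
  expect_equal(cur$discarded$case_id, samples$case_id[c(1, 3)])
  expect_equal(cur$kept$case_id, samples$case_id[c(2, 4)])
  # labels are never changed, only membership
  expect_equal(cur$kept$risk_label, samples$risk_label[c(2, 4)])
  expect_match(cur$discarded$reason[1], "P\\(label\\)")
})

test_that("denoising with threshold zero keeps everything and is idempotent", {
  samples <- curation_samples(list(t1 = c(3, 1)))
  scores <- c(0.9, 0.2, 0.01, 0.99)
  cur0 <- denoise(samples, scores, threshold = 0)
  expect_equal(nrow(cur0$discarded), 0)
  cur <- denoise(samples, scores, threshold = 0.1)
  keep_idx <- match(cur$kept$case_id, samples$case_id)
  again <- denoise(cur$kept, scores[keep_idx], threshold = 0.1)
  expect_equal(again$kept, cur$kept)
  expect_equal(nrow(again$discarded), 0)
})

test_that("denoise validates its inputs", {
  samples <- curation_samples(list(t1 = c(1, 1)))
  expect_error(denoise(samples, c(0.5), threshold = 0.1), "one stage-1 score")
  expect_error(denoise(samples, c(0.5, NA), threshold = 0.1), "missing")
  expect_error(denoise(samples, c(0.5, 0.5), threshold = 1.5), "\\[0, 1\\]")
})

test_that("pseudo-labeling fills each TMA by descending follow-up until balance", {
  # hand-traced fixture: 6 high / 2 low, candidates at 4.9, 4.5, 3.0 years
  samples <- curation_samples(list(t1 = c(6, 2)))
  candidates <- tibble::tibble(
    case_id = c("p1", "p2", "p3"), tma_id = "t1",
    fu_years = c(4.5, 4.9, 3.0), bad_outcome = FALSE
  )
  cur <- pseudo_label(samples, candidates)
  # deficit is 4 but only 3 candidates: all added (depletion), 6 high / 5 low
  expect_equal(nrow(cur$pseudo_labeled), 3)
  expect_equal(cur$pseudo_labeled$case_id, c("p2", "p1", "p3"))  # fu descending
  expect_equal(sum(cur$kept$risk_label == "low"), 5)
  expect_equal(sum(cur$kept$risk_label == "high"), 6)
  expect_true(all(cur$pseudo_labeled$risk_label == "low"))
})

test_that("pseudo-labeling stops exactly at balance and breaks ties by case id", {
  samples <- curation_samples(list(t1 = c(3, 1)))
  candidates <- tibble::tibble(
    case_id = c("pb", "pa", "pc"), tma_id = "t1",
    fu_years = c(4.0, 4.0, 4.0), bad_outcome = FALSE
  )
  cur <- pseudo_label(samples, candidates)
  expect_equal(nrow(cur$pseudo_labeled), 2)  # deficit 3 - 1
  expect_equal(cur$pseudo_labeled$case_id, c("pa", "pb"))  # tie -> case_id order
})

test_that("an already balanced TMA gains no pseudo-labels", {
  samples <- curation_samples(list(t1 = c(2, 2)))
  candidates <- tibble::tibble(case_id = "p1", tma_id = "t1",
                               fu_years = 4, bad_outcome = FALSE)
  cur <- pseudo_label(samples, candidates)
  expect_equal(nrow(cur$pseudo_labeled), 0)
  expect_equal(cur$kept$case_id, samples$case_id)
})

test_that("candidates must be event-free with short follow-up", {
  samples <- curation_samples(list(t1 = c(2, 0)))
  bad_evt <- tibble::tibble(case_id = "p1", tma_id = "t1",
                            fu_years = 4, bad_outcome = TRUE)
  expect_error(pseudo_label(samples, bad_evt), "possible-low-risk")
  long_fu <- tibble::tibble(case_id = "p1", tma_id = "t1",
                            fu_years = 6, bad_outcome = FALSE)
  expect_error(pseudo_label(samples, long_fu), "possible-low-risk")
})

test_that("TMA-balanced drafts take min(high, low) per TMA without replacement", {
  samples <- curation_samples(list(t1 = c(8, 3), t2 = c(5, 5), t3 = c(7, 0)))
  set.seed(13)
  idx <- tma_balanced_draft(samples)
  draft <- samples[idx, ]
  expect_equal(anyDuplicated(idx), 0)
  t1 <- draft[draft$tma_id == "t1", ]
  expect_equal(sum(t1$risk_label == "high"), 3)
  expect_equal(sum(t1$risk_label == "low"), 3)
  expect_equal(nrow(draft[draft$tma_id == "t2", ]), 10)
  # a TMA missing one class contributes nothing
  expect_equal(nrow(draft[draft$tma_id == "t3", ]), 0)
})

test_that("every epoch draft is exactly class-balanced within every TMA", {
  samples <- curation_samples(list(t1 = c(4, 9), t2 = c(1, 6), t3 = c(5, 5)))
  set.seed(17)
  for (epoch in 1:10) {
    draft <- samples[tma_balanced_draft(samples), ]
    counts <- table(draft$tma_id, draft$risk_label)
    expect_equal(unname(counts[, "high"]), unname(counts[, "low"]))
  }
})

test_that("global drafting balances classes but ignores TMA membership", {
  samples <- curation_samples(list(t1 = c(6, 0), t2 = c(0, 4)))
  set.seed(19)
  idx <- global_balanced_draft(samples)
  draft <- samples[idx, ]
  expect_equal(sum(draft$risk_label == "high"), 4)
  expect_equal(sum(draft$risk_label == "low"), 4)
  # the TMA-balanced draft on the same data is empty: both TMAs one-class
  expect_equal(length(tma_balanced_draft(samples)), 0)
})

test_that("curation bookkeeping reports per-TMA counts plus a total row", {
  samples <- curation_samples(list(t1 = c(2, 3), t2 = c(4, 0)))
  counts <- curation_counts(samples)
  expect_equal(counts$high[counts$tma_id == "total"], 6)
  expect_equal(counts$low[counts$tma_id == "total"], 3)
  expect_equal(counts$low[counts$tma_id == "t2"], 0)
})

test_that("the leakage guard rejects any train/test case overlap", {
  expect_silent(pcai:::assert_no_leakage(c("a", "b"), c("c")))
  expect_error(pcai:::assert_no_leakage(c("a", "b"), c("b", "c")), "leakage")
})

test_that("two-stage training on a small world produces a coherent fit", {
  world <- simulate_world(world_config(n_tmas = 3, cases_per_tma = 12,
                                       spot_px = 96, seed = 11))
  fit <- two_stage_train(world, epochs_stage1 = 4, epochs_stage2 = 6, seed = 11)
  expect_s3_class(fit, "two_stage_fit")
  expect_true(fit$auc_raw >= 0 && fit$auc_raw <= 1)
  # the test split never overlaps train and is never pseudo-labeled
  expect_equal(intersect(fit$curated$kept$case_id, fit$split$test_cases),
               character(0))
  expect_true(all(fit$test$case_id %in% fit$split$test_cases))
  # curated counts move the train balance toward 50/50
  raw <- fit$counts$stage1
  cur <- fit$counts$curated
  raw_gap <- abs(raw$high[raw$tma_id == "total"] - raw$low[raw$tma_id == "total"])
  cur_gap <- abs(cur$high[cur$tma_id == "total"] - cur$low[cur$tma_id == "total"])
  expect_lte(cur_gap, raw_gap)
})

test_that("the denoiser discards a set enriched in planted-unrepresentative spots", {
  # per-seed discard sets are tiny, so enrichment is assessed on the
  # pooled discard set over three consecutive seeds
  discarded_unrep <- 0; discarded_n <- 0; base_rates <- c()
  for (s in 1:3) {
    world <- simulate_world(world_config(unrepresentative_rate = 0.15, seed = s))
    fit <- two_stage_train(world, seed = s)
    unrep <- world$truth$unrepresentative[
      match(fit$curated$discarded$case_id, world$truth$case_id)]
    discarded_unrep <- discarded_unrep + sum(unrep)
    discarded_n <- discarded_n + length(unrep)
    base_rates <- c(base_rates, mean(world$truth$unrepresentative))
  }
  expect_gt(discarded_n, 0)
  expect_gte(discarded_unrep / discarded_n, 2 * mean(base_rates))
})

test_that("disabling pseudo-labeling makes the curated set a subset of raw", {
  world <- simulate_world(world_config(n_tmas = 2, cases_per_tma = 10,
                                       spot_px = 96, seed = 21))
  fit <- two_stage_train(world, epochs_stage1 = 3, epochs_stage2 = 3,
                         pseudo_label_enabled = FALSE, seed = 21)
  labelled <- assign_risk_label(world$cohort, mode = "train")
  raw_cases <- labelled$case_id[labelled$risk_label %in% c("high", "low")]
  expect_true(all(fit$curated$kept$case_id %in% raw_cases))
  expect_equal(nrow(fit$curated$pseudo_labeled), 0)
})
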