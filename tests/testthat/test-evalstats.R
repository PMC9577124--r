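test_that("confusion matrix counts [tn, fp, fn, tp] with high as positive", {
  truth <- c("high", "high", "low", "low", "low")
  pred <- c("high", "low", "low", "high", "low")
  cm <- confusion_matrix2(truth, pred)
  expect_equal(unclass(cm), c(tn = 2L, fp = 1L, fn = 1L, tp = 1L))
  expect_error(confusion_matrix2(c("yes"), c("high")), "high")
})

test_that("balanced accuracy is the mean of sensitivity and specificity", {
  expect_equal(balanced_accuracy(c(tn = 90, fp = 10, fn = 5, tp = 15)),
               (15 / 20 + 90 / 100) / 2)
  # positional [tn, fp, fn, tp] order accepted
  expect_equal(balanced_accuracy(c(90, 10, 5, 15)),
               balanced_accuracy(c(tn = 90, fp = 10, fn = 5, tp = 15)))
  expect_error(balanced_accuracy(c(tn = 10, fp = 5, fn = 0, tp = 0)),
               "sensitivity undefined")
})

test_that("rank-based AUC matches the exhaustive pair fraction, ties at half", {
  # hand case with a tie across classes: pairs (3,1)+, (3,2)+, (2,1)+,
  # (2,2) tie -> (3 + 0.5) / 4
  scores <- c(3, 2, 1, 2)
  pos <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(auc_score(scores, pos), 3.5 / 4)
  expect_equal(auc_score(scores, pos), pairwise_auc_oracle(scores, pos))
})

test_that("AUC agrees with an independent library implementation", {
  set.seed(7)
  scores <- runif(80)
  pos <- runif(80) < plogis(4 * scores - 2)
  pos[1:2] <- c(TRUE, FALSE)
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(
    response = as.integer(pos), predictor = scores, quiet = TRUE,
    direction = "<", levels = c("0", "1")
  ))))
  expect_equal(auc_score(scores, pos), ref, tolerance = 1e-12)
})

test_that("AUC is invariant under monotone score transforms", {
  set.seed(11)
  scores <- rnorm(50)
  pos <- rep(c(TRUE, FALSE), 25)
  expect_equal(auc_score(plogis(scores), pos), auc_score(scores, pos))
})

test_that("bootstrap CI brackets the point AUC and is seed-deterministic", {
  set.seed(3)
  scores <- c(rnorm(40, 1), rnorm(40))
  pos <- rep(c(TRUE, FALSE), each = 40)
  set.seed(5)
  ci1 <- auc_bootstrap_ci(scores, pos, n_boot = 200)
  set.seed(5)
  ci2 <- auc_bootstrap_ci(scores, pos, n_boot = 200)
  expect_equal(ci1, ci2)
  expect_lte(ci1$ci_low, ci1$auc)
  expect_gte(ci1$ci_high, ci1$auc)
  expect_equal(ci1$auc, auc_score(scores, pos))
})

test_that("bootstrap resamples whole cases when case_id is supplied", {
  # two spots per case with identical scores: case-level resampling can
  # never split a case, so the two spots of a case always co-occur and
  # every bootstrap AUC stays a valid pooled estimate
  scores <- rep(c(0.9, 0.8, 0.2, 0.1), each = 2)
  pos <- rep(c(TRUE, TRUE, FALSE, FALSE), each = 2)
  case_id <- rep(c("a", "b", "c", "d"), each = 2)
  set.seed(1)
  ci <- auc_bootstrap_ci(scores, pos, n_boot = 100, case_id = case_id)
  expect_equal(ci$auc, 1)
  expect_equal(ci$ci_low, 1)  # perfectly separated within every resample
})

test_that("permutation p-value is +1-smoothed, symmetric and in (0, 1]", {
  set.seed(9)
  scores_a <- runif(30); scores_b <- runif(30)
  pos <- rep(c(TRUE, FALSE), 15)
  set.seed(2)
  p_ab <- auc_permutation_test(scores_a, scores_b, pos, n_perm = 200)
  set.seed(2)
  p_ba <- auc_permutation_test(scores_b, scores_a, pos, n_perm = 200)
  expect_equal(p_ab$p_value, p_ba$p_value)
  expect_gte(p_ab$p_value, 1 / 201)
  expect_lte(p_ab$p_value, 1)
  # identical predictors: every permuted delta ties the observed 0
  set.seed(4)
  p_same <- auc_permutation_test(scores_a, scores_a, pos, n_perm = 50)
  expect_equal(p_same$p_value, 1)
})

test_that("weighted kappa is 1 for perfect agreement and ~0 under independence", {
  expect_equal(weighted_kappa(diag(c(5, 9, 3))), 1)
  marg <- c(10, 20, 30)
  indep <- outer(marg, marg) / sum(marg)
  expect_equal(weighted_kappa(indep), 0)
  expect_error(weighted_kappa(matrix(1, 2, 3)), "square")
})

test_that("weighted kappa uses block-distance weights |i-j|/(k-1)", {
  # 2x2 hand trace: w = [[0,1],[1,0]],
  # O = [[0.4,0.1],[0.2,0.3]], E from marginals [[0.3,0.2],[0.25,0.25]]
  m <- matrix(c(40, 10, 20, 30), 2, 2, byrow = TRUE)
  observed_dis <- 0.1 + 0.2
  p <- m / sum(m)
  e <- outer(rowSums(p), colSums(p))
  expect_equal(weighted_kappa(m), 1 - observed_dis / (e[1, 2] + e[2, 1]))
})

test_that("score bins are equal-width on [0, 1] and right-closed", {
  b <- bin_pcai(c(0, 1 / 7, 1 / 7 + 1e-9, 0.999, 1), n_bins = 7)
  expect_equal(length(levels(b)), 7)
  expect_equal(as.integer(b), c(1L, 1L, 2L, 7L, 7L))
  expect_equal(attr(b, "edges"), seq(0, 1, length.out = 8))
  b5 <- bin_pcai(c(0.2, 0.200001), n_bins = 5)
  expect_equal(as.integer(b5), c(1L, 2L))
  expect_error(bin_pcai(c(-0.1)), "\\[0, 1\\]")
})

test_that("a case scores as the maximum over its assessable spots", {
  scores <- tibble::tibble(
    case_id = c("a", "a", "a", "b", "b"),
    pcai = c(0.2, 0.9, 0.5, 0.1, NA)
  )
  expect_message(out <- case_score(scores), NA)
  expect_equal(out$case_score, c(0.9, 0.1))
  expect_equal(out$n_spots, c(3L, 1L))
  # a case with no assessable spot is excluded with a message
  scores2 <- tibble::tibble(case_id = c("a", "b"), pcai = c(0.3, NA))
  expect_message(out2 <- case_score(scores2), "no assessable spot")
  expect_equal(out2$case_id, "a")
})

test_that("Kaplan-Meier equals the empirical survival function without censoring", {
  times <- c(1, 2, 3, 4, 5)
  surv <- tibble::tibble(time_years = times, event = TRUE, group = "all")
  km <- km_curve(surv)
  expect_equal(km$survival, 1 - seq_along(times) / length(times))
  expect_equal(km$n_risk, rev(seq_along(times)))
})

test_that("censored cases leave the risk set without dropping the curve", {
  surv <- tibble::tibble(
    time_years = c(1, 2, 3), event = c(TRUE, FALSE, TRUE), group = "g"
  )
  km <- km_curve(surv)
  # S(1) = 2/3; censoring at 2 removes one at risk; S(3) = 2/3 * (1 - 1/1) = 0
  expect_equal(km$survival[km$time == 1], 2 / 3)
  expect_equal(km$survival[km$time == 3], 0)
})

test_that("Cox hazard ratio is reported per 0.1 score units", {
  set.seed(21)
  n <- 400
  score <- runif(n)
  time <- rexp(n, 0.1 * exp(2 * score))
  cens <- runif(n, 0, 12)
  surv <- tibble::tibble(
    time_years = pmin(time, cens), event = time <= cens, score = score
  )
  out <- cox_hr(surv, "score", unit = 0.1)
  direct <- survival::coxph(
    survival::Surv(time_years, as.integer(event)) ~ score, data = surv
  )
  expect_equal(out$log_hr, unname(coef(direct)) * 0.1, tolerance = 1e-8)
  expect_equal(out$hr, exp(out$log_hr))
  expect_gt(out$c_index, 0.5)
  td <- tidy(out)
  expect_equal(td$hazard_ratio, out$hr)
})

test_that("evaluation report combines AUC, confusion, KM and Cox coherently", {
  set.seed(31)
  n <- 60
  cohort <- tibble::tibble(
    case_id = sprintf("c%02d", 1:n), tma_id = "t1",
    age = rnorm(n, 64, 6), psa = rlnorm(n, 2, 0.5), isup = 2, pt = 2,
    pn = FALSE, pv = FALSE, pl = FALSE,
    fu_years = runif(n, 0.5, 9),
    bcr = FALSE, t_bcr = NA_real_, met = FALSE, t_met = NA_real_,
    cdeath = FALSE, t_cdeath = NA_real_
  )
  risk <- runif(n)
  cohort$bcr <- risk > 0.6
  cohort$t_bcr <- ifelse(cohort$bcr, pmin(cohort$fu_years, 2.5), NA)
  scores <- tibble::tibble(
    spot_id = paste0("s", 1:n), case_id = cohort$case_id,
    pcai = pmin(pmax(risk + rnorm(n, 0, 0.1), 0), 1)
  )
  rep <- evaluate_scores(scores, cohort, n_boot = 50)
  expect_s3_class(rep$km, "km_curves")
  expect_s3_class(rep$cox, "cox_hr")
  expect_gt(rep$auc$auc, 0.8)
  expect_equal(rep$balanced_accuracy, balanced_accuracy(rep$confusion))
  g <- glance(rep)
  expect_equal(g$auc, rep$auc$auc)
})

test_that("ROC points integrate back to the rank AUC", {
  set.seed(41)
  scores <- runif(60)
  pos <- runif(60) < scores
  pos[1:2] <- c(TRUE, FALSE)
  df <- roc_points(scores, pos)
  # trapezoidal area under the (fpr, tpr) staircase, plus closing segment
  fpr <- c(df$fpr, 1); tpr <- c(df$tpr, 1)
  area <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  expect_equal(area, auc_score(scores, pos), tolerance = 1e-10)
  expect_s3_class(plot_roc(scores, pos), "ggplot")
})
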