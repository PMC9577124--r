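#' Build a 2x2 confusion matrix from truth and prediction
#'
#' Rows are truth (low/high), columns prediction. Stored as the count
#' vector `[tn, fp, fn, tp]` with "high" the positive class.
#'
#' @param truth Factor/character vector with values "high"/"low" (or
#'   logical, TRUE = high).
#' @param pred Predicted classes, same coding.
#' @return An object of class `confusion2`: named integer vector
#'   `c(tn, fp, fn, tp)`.
#' @export
confusion_matrix2 <- function(truth, pred) {
  to_pos <- function(x) {
    if (is.logical(x)) return(x)
    x <- as.character(x)
    bad <- !x %in% c("high", "low")
    if (any(bad)) stop("classes must be 'high' or 'low'")
    x == "high"
  }
  t_pos <- to_pos(truth); p_pos <- to_pos(pred)
  if (length(t_pos) != length(p_pos)) stop("truth and pred lengths differ")
  cm <- c(
    tn = sum(!t_pos & !p_pos), fp = sum(!t_pos & p_pos),
    fn = sum(t_pos & !p_pos), tp = sum(t_pos & p_pos)
  )
  structure(as.integer(cm), names = names(cm), class = "confusion2")
}

#' Balanced accuracy of a binary confusion matrix
#'
#' Mean of sensitivity and specificity:
#' `(tp / (tp + fn) + tn / (tn + fp)) / 2`.
#'
#' @param cm A `confusion2` object or a named (or `[tn, fp, fn, tp]`
#'   ordered) numeric vector of the four counts.
#' @return Balanced accuracy in \[0, 1\].
#' @examples
#' balanced_accuracy(c(tn = 514, fp = 197, fn = 109, tp = 288)) # 0.724
#' @export
balanced_accuracy <- function(cm) {
  cm <- as_cm4(cm)
  if (cm["tp"] + cm["fn"] == 0) stop("no positive-class cases: sensitivity undefined")
  if (cm["tn"] + cm["fp"] == 0) stop("no negative-class cases: specificity undefined")
  unname((cm["tp"] / (cm["tp"] + cm["fn"]) + cm["tn"] / (cm["tn"] + cm["fp"])) / 2)
}

as_cm4 <- function(cm) {
  x <- as.numeric(cm)
  if (length(x) != 4 || any(x < 0)) stop("expected 4 non-negative counts [tn, fp, fn, tp]")
  if (!is.null(names(cm)) && all(c("tn", "fp", "fn", "tp") %in% names(cm))) {
    x <- as.numeric(cm[c("tn", "fp", "fn", "tp")])
  }
  names(x) <- c("tn", "fp", "fn", "tp")
  x
}

#' Rank-based AUC with half credit for ties
#'
#' The two-sample rank statistic: the fraction of (positive, negative)
#' pairs ranked concordantly by the score, with ties counted 1/2.
#'
#' @param scores Numeric scores, higher = more likely positive.
#' @param labels Positive-class indicator (logical, 0/1, or "high"/"low").
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  pos <- as_pos(labels)
  if (length(scores) != length(pos)) stop("scores and labels lengths differ")
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

as_pos <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(labels == 1)
  }
  x <- as.character(labels)
  if (!all(x %in% c("high", "low"))) stop("labels must be 'high'/'low', 0/1 or logical")
  x == "high"
}

#' AUC with a bootstrap confidence interval
#'
#' Point AUC from [auc_score()]; the confidence interval from percentile
#' bootstrap over resampled cases (1000 iterations by default). Resampling
#' is at the case level when a `case_id` grouping is supplied, so that
#' within-case correlation between spots is respected; otherwise rows are
#' resampled independently.
#'
#' @param scores,labels As in [auc_score()].
#' @param n_boot Number of bootstrap iterations (default 1000).
#' @param case_id Optional grouping vector; resampling draws whole groups.
#' @param conf Confidence level (default 0.95).
#' @return A tibble with columns `auc`, `ci_low`, `ci_high`, `n_boot`.
#' @export
auc_bootstrap_ci <- function(scores, labels, n_boot = 1000, case_id = NULL,
                             conf = 0.95) {
  pos <- as_pos(labels)
  point <- auc_score(scores, pos)
  groups <- if (is.null(case_id)) seq_along(scores) else case_id
  idx_by_group <- split(seq_along(scores), groups)
  g <- length(idx_by_group)
  boots <- vapply(seq_len(n_boot), function(i) {
    take <- sample.int(g, g, replace = TRUE)
    idx <- unlist(idx_by_group[take], use.names = FALSE)
    if (sum(pos[idx]) == 0 || sum(!pos[idx]) == 0) return(NA_real_)
    auc_score(scores[idx], pos[idx])
  }, numeric(1))
  boots <- boots[!is.na(boots)]
  alpha <- (1 - conf) / 2
  qs <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE, type = 7)
  tibble::tibble(auc = point, ci_low = qs[1], ci_high = qs[2], n_boot = n_boot)
}

#' Permutation test for the difference between two paired AUCs
#'
#' Compares two predictors scored on the same samples. The null is built
#' by independently swapping the two scores within each sample; the
#' two-sided p-value is the +1-smoothed fraction of permuted |dAUC| at
#' least as large as observed.
#'
#' @param scores_a,scores_b Paired score vectors (same samples, same order).
#' @param labels Positive-class indicator.
#' @param n_perm Number of permutations (default 1000).
#' @return A tibble with `auc_a`, `auc_b`, `delta`, `p_value`, `n_perm`.
#' @export
auc_permutation_test <- function(scores_a, scores_b, labels, n_perm = 1000) {
  if (length(scores_a) != length(scores_b)) {
    stop("scores_a and scores_b must be paired (equal length)")
  }
  pos <- as_pos(labels)
  if (length(pos) != length(scores_a)) stop("labels length must match the scores")
  auc_a <- auc_score(scores_a, pos)
  auc_b <- auc_score(scores_b, pos)
  observed <- abs(auc_a - auc_b)
  n <- length(pos)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    swap <- stats::runif(n) < 0.5
    a <- ifelse(swap, scores_b, scores_a)
    b <- ifelse(swap, scores_a, scores_b)
    if (abs(auc_score(a, pos) - auc_score(b, pos)) >= observed) exceed <- exceed + 1L
  }
  tibble::tibble(auc_a = auc_a, auc_b = auc_b, delta = auc_a - auc_b,
                 p_value = (exceed + 1) / (n_perm + 1), n_perm = n_perm)
}

#' Linearly weighted kappa over an ordered agreement matrix
#'
#' Chance-corrected agreement between two raters over k ordered categories.
#' Disagreement weights are the block distance in the confusion matrix
#' divided by the maximum block distance: `w_ij = |i - j| / (k - 1)`.
#' `kappa = 1 - sum(w * observed) / sum(w * expected)`, with the expected
#' matrix the outer product of the marginals (independence).
#'
#' @param m A square k x k count matrix (k >= 2); rows one rater, columns
#'   the other, categories in the same order.
#' @return Weighted kappa (1 = perfect agreement, 0 = chance level).
#' @export
weighted_kappa <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("agreement matrix must be square")
  k <- nrow(m)
  if (k < 2) stop("need at least 2 categories")
  if (any(m < 0) || sum(m) <= 0) stop("matrix must hold non-negative counts, total > 0")
  w <- abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  p <- m / sum(m)
  expected <- outer(rowSums(p), colSums(p))
  denom <- sum(w * expected)
  if (denom == 0) stop("degenerate marginals: expected disagreement is zero")
  1 - sum(w * p) / denom
}

#' Bin continuous risk scores into equal-width groups on \[0, 1\]
#'
#' Used to stratify the continuous ensemble score for Kaplan-Meier curves
#' (7 groups) and pathologist-comparison tables (5 groups, labelled
#' "0.0-0.2" ... "0.8-1.0"). Bins are left-open/right-closed except the
#' first, which includes 0; a score of exactly 1 falls in the top bin.
#'
#' @param scores Numeric scores in \[0, 1\].
#' @param n_bins Number of equal-width bins (default 7).
#' @return A factor with `n_bins` interval labels; bin edges in
#'   `attr(, "edges")`.
#' @export
bin_pcai <- function(scores, n_bins = 7) {
  if (any(scores < 0 | scores > 1, na.rm = TRUE)) stop("scores must lie in [0, 1]")
  edges <- seq(0, 1, length.out = n_bins + 1)
  labels <- sprintf("%.5g-%.5g", edges[-length(edges)], edges[-1])
  b <- cut(scores, breaks = edges, labels = labels, include.lowest = TRUE, right = TRUE)
  attr(b, "edges") <- edges
  b
}

#' Aggregate spot scores to a case score
#'
#' A case is represented by the maximum score over its assessable spots.
#'
#' @param scores A data frame with columns `case_id` and a score column.
#' @param score_col Name of the score column (default `"pcai"`).
#' @return A tibble with `case_id`, `case_score`, `n_spots`.
#' @export
case_score <- function(scores, score_col = "pcai") {
  if (!score_col %in% names(scores)) stop("no column '", score_col, "' in scores")
  keep <- !is.na(scores[[score_col]])
  dropped <- unique(scores$case_id[!keep])
  out <- scores[keep, ] |>
    dplyr::group_by(.data$case_id) |>
    dplyr::summarise(case_score = max(.data[[score_col]]), n_spots = dplyr::n(),
                     .groups = "drop")
  fully_dropped <- setdiff(dropped, out$case_id)
  if (length(fully_dropped) > 0) {
    message(length(fully_dropped), " case(s) had no assessable spot and were excluded")
  }
  out
}

#' Kaplan-Meier curves per risk group
#'
#' Product-limit survival estimate per group, for visualising risk
#' stratification: whenever a case suffers a bad outcome its group's curve
#' drops; event-free cases are right-censored at last follow-up.
#'
#' @param surv A data frame with columns `time_years`, `event` (logical or
#'   0/1), and `group`.
#' @return An object of class `km_curves`: a tibble of step-function points
#'   with columns `group`, `time`, `survival`, `n_risk`, `n_event`.
#' @export
km_curve <- function(surv) {
  if (!all(c("time_years", "event", "group") %in% names(surv))) {
    stop("surv needs columns time_years, event, group")
  }
  if (any(surv$time_years < 0)) stop("times must be >= 0")
  surv <- tibble::as_tibble(surv)
  empty <- table(surv$group) == 0
  if (any(empty)) warning("dropping empty group(s): ",
                          paste(names(empty)[empty], collapse = ", "))
  fit <- survival::survfit(
    survival::Surv(time_years, as.integer(event)) ~ group, data = surv
  )
  strata <- if (is.null(fit$strata)) {
    rep(as.character(surv$group[1]), length(fit$time))
  } else {
    rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  out <- tibble::tibble(
    group = strata, time = fit$time, survival = fit$surv,
    n_risk = fit$n.risk, n_event = fit$n.event
  )
  class(out) <- c("km_curves", class(out))
  out
}

#' Cox proportional-hazards summary for a continuous risk score
#'
#' Fits `Surv(time, event) ~ score` (optionally adjusted for covariates)
#' and reports the hazard ratio per `unit` of score change: with
#' `unit = 0.1` a score in \[0, 1\] is mapped onto a 0-10 range, so the HR
#' is "per 0.1 units".
#'
#' @param surv A data frame with columns `time_years`, `event`, the score
#'   column, and any adjustment covariates.
#' @param score_col Name of the score column.
#' @param unit Score change per hazard-ratio unit (default 0.1).
#' @param adjust Character vector of covariate column names (e.g.
#'   `c("age", "psa")`), or `NULL` for unadjusted.
#' @return An object of class `cox_hr`: a list with `hr`, `ci_low`,
#'   `ci_high`, `p_value`, `c_index`, `log_hr`, `se_log_hr`, `n`,
#'   `n_events`, plus the fitted `survival::coxph` object in `$fit`.
#' @export
cox_hr <- function(surv, score_col, unit = 0.1, adjust = NULL) {
  needed <- c("time_years", "event", score_col, adjust)
  missing_cols <- setdiff(needed, names(surv))
  if (length(missing_cols) > 0) stop("missing columns: ", paste(missing_cols, collapse = ", "))
  if (sum(surv$event) == 0) stop("no events: Cox model cannot be fitted")
  df <- tibble::as_tibble(surv)
  df$.score_scaled <- df[[score_col]] / unit
  rhs <- paste(c(".score_scaled", adjust), collapse = " + ")
  fml <- stats::as.formula(paste("survival::Surv(time_years, as.integer(event)) ~", rhs))
  fit <- tryCatch(
    survival::coxph(fml, data = df),
    error = function(e) stop("Cox fit failed: ", conditionMessage(e)),
    warning = function(w) {
      stop("Cox fit did not converge cleanly: ", conditionMessage(w))
    }
  )
  s <- summary(fit)
  co <- s$coefficients[".score_scaled", ]
  ci <- s$conf.int[".score_scaled", ]
  out <- list(
    hr = unname(co["exp(coef)"]),
    ci_low = unname(ci["lower .95"]), ci_high = unname(ci["upper .95"]),
    p_value = unname(co["Pr(>|z|)"]),
    c_index = unname(s$concordance["C"]),
    log_hr = unname(co["coef"]), se_log_hr = unname(co["se(coef)"]),
    n = s$n, n_events = s$nevent,
    unit = unit, adjust = adjust, fit = fit
  )
  class(out) <- "cox_hr"
  out
}

#' @export
print.cox_hr <- function(x, ...) {
  adj <- if (is.null(x$adjust)) "unadjusted" else paste("adjusted for", paste(x$adjust, collapse = ", "))
  cat(sprintf("Cox PH (%s): HR %.3f (%.3f-%.3f) per %g units, p = %.3g, C = %.3f\n",
              adj, x$hr, x$ci_low, x$ci_high, x$unit, x$p_value, x$c_index))
  invisible(x)
}

#' @export
tidy.cox_hr <- function(x, ...) {
  tibble::tibble(
    term = "score", estimate = x$log_hr, std.error = x$se_log_hr,
    hazard_ratio = x$hr, conf.low = x$ci_low, conf.high = x$ci_high,
    p.value = x$p_value
  )
}

#' @export
glance.cox_hr <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, c_index = x$c_index,
                 unit = x$unit, adjusted = !is.null(x$adjust))
}

#' Evaluate spot scores against cohort outcomes
#'
#' The full evaluation report for one set of spot scores: AUC with
#' bootstrap CI, confusion matrix at a 0.5 threshold, balanced accuracy,
#' Kaplan-Meier stratification by binned score, and unadjusted plus
#' age/PSA-adjusted Cox summaries. Spots whose case has an `undefined`
#' risk label are excluded from the binary metrics but kept for survival.
#'
#' @param scores A tibble with `spot_id`, `case_id`, and a `pcai` column.
#' @param cohort A cohort tibble (labels derived in test mode if absent).
#' @param threshold Score threshold for the binary confusion matrix.
#' @param n_boot Bootstrap iterations for the AUC CI.
#' @param n_bins Bins for the Kaplan-Meier stratification.
#' @return An `evaluation_report` list with elements `auc`, `confusion`,
#'   `balanced_accuracy`, `km`, `cox`, `cox_adjusted`, `n_binary`, `n_survival`.
#' @export
evaluate_scores <- function(scores, cohort, threshold = 0.5, n_boot = 1000,
                            n_bins = 7) {
  if (!"risk_label" %in% names(cohort)) {
    cohort <- assign_risk_label(cohort, mode = "test")
  }
  cs <- case_score(scores, "pcai")
  df <- dplyr::inner_join(cs, cohort, by = "case_id")

  bin_df <- df[df$risk_label %in% c("high", "low"), ]
  auc <- auc_bootstrap_ci(bin_df$case_score, bin_df$risk_label == "high",
                          n_boot = n_boot)
  cm <- confusion_matrix2(bin_df$risk_label == "high", bin_df$case_score > threshold)

  surv_df <- tibble::tibble(
    time_years = df$bad_outcome_time, event = df$bad_outcome,
    group = bin_pcai(df$case_score, n_bins), score = df$case_score,
    age = df$age, psa = df$psa
  )
  km <- km_curve(surv_df)
  cox <- cox_hr(surv_df, "score", unit = 0.1)
  cox_adj <- tryCatch(cox_hr(surv_df, "score", unit = 0.1, adjust = c("age", "psa")),
                      error = function(e) NULL)

  out <- list(
    auc = auc, confusion = cm, balanced_accuracy = balanced_accuracy(cm),
    km = km, cox = cox, cox_adjusted = cox_adj,
    n_binary = nrow(bin_df), n_survival = nrow(surv_df)
  )
  class(out) <- "evaluation_report"
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation on %d cases with defined risk (%d with survival data)\n",
              x$n_binary, x$n_survival))
  cat(sprintf("  AUC %.3f (%.3f-%.3f)\n", x$auc$auc, x$auc$ci_low, x$auc$ci_high))
  cat(sprintf("  Balanced accuracy %.3f; confusion [tn, fp, fn, tp] = [%s]\n",
              x$balanced_accuracy, paste(unclass(x$confusion), collapse = ", ")))
  print(x$cox)
  invisible(x)
}

#' @export
glance.evaluation_report <- function(x, ...) {
  tibble::tibble(
    auc = x$auc$auc, auc_ci_low = x$auc$ci_low, auc_ci_high = x$auc$ci_high,
    balanced_accuracy = x$balanced_accuracy,
    hr = x$cox$hr, c_index = x$cox$c_index,
    n_binary = x$n_binary, n_survival = x$n_survival
  )
}

#' Plot Kaplan-Meier curves
#'
#' @param object A `km_curves` object from [km_curve()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.km_curves <- function(object, ...) {
  start <- object |>
    dplyr::distinct(.data$group) |>
    dplyr::mutate(time = 0, survival = 1, n_risk = NA_integer_, n_event = 0L)
  df <- dplyr::bind_rows(start, object)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$survival, colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Years", y = "Recurrence-free survival", colour = "Group") +
    ggplot2::theme_minimal()
}

#' ROC curve data for a score
#'
#' @param scores Numeric scores.
#' @param labels Positive-class indicator.
#' @return A tibble with `threshold`, `tpr`, `fpr` (one row per distinct
#'   score plus the endpoints).
#' @export
roc_points <- function(scores, labels) {
  pos <- as_pos(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tibble::tibble(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(scores[pos] >= t), numeric(1)),
    fpr = vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  )
}

#' Plot a ROC curve
#'
#' @param scores,labels As in [roc_points()].
#' @return A ggplot object.
#' @export
plot_roc <- function(scores, labels) {
  df <- roc_points(scores, labels)
  ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "False positive rate", y = "True positive rate") +
    ggplot2::theme_minimal()
}
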