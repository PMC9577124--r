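#' Derive the composite bad-outcome endpoint for each case
#'
#' The endpoint is the composite "bad outcome": biochemical recurrence (BCR),
#' metastasis, or cancer-specific death, whichever comes first. A case with
#' none of the three events is censored at its last follow-up.
#'
#' @param cohort A data frame with one row per case. Required columns:
#'   `fu_years` (follow-up in years), logical event flags `bcr`, `met`,
#'   `cdeath` (NA allowed, treated as "event not observed" with a warning),
#'   and event times `t_bcr`, `t_met`, `t_cdeath` (years; must be present
#'   whenever the corresponding flag is `TRUE`).
#' @return The input tibble with two added columns: `bad_outcome` (logical)
#'   and `bad_outcome_time` (years; earliest event time if any event
#'   occurred, else `fu_years`).
#' @examples
#' cohort <- tibble::tibble(
#'   case_id = "c1", fu_years = 6, bcr = TRUE, t_bcr = 2,
#'   met = FALSE, t_met = NA_real_, cdeath = FALSE, t_cdeath = NA_real_
#' )
#' derive_bad_outcome(cohort)
#' @export
derive_bad_outcome <- function(cohort) {
  cohort <- tibble::as_tibble(cohort)
  required <- c("fu_years", "bcr", "met", "cdeath", "t_bcr", "t_met", "t_cdeath")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort is missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyNA(cohort$fu_years)) stop("fu_years must be present for every case")
  if (any(cohort$fu_years < 0)) stop("fu_years must be >= 0")

  flags <- cohort[c("bcr", "met", "cdeath")]
  times <- cohort[c("t_bcr", "t_met", "t_cdeath")]
  for (i in seq_along(flags)) {
    bad <- !is.na(flags[[i]]) & flags[[i]] & is.na(times[[i]])
    if (any(bad)) {
      stop("event flag '", names(flags)[i], "' is TRUE but time '",
           names(times)[i], "' is missing for case(s): ",
           paste(utils::head(cohort$case_id[bad], 5), collapse = ", "))
    }
  }
  n_na <- sum(is.na(flags$bcr)) + sum(is.na(flags$met)) + sum(is.na(flags$cdeath))
  if (n_na > 0) {
    warning(n_na, " missing event flag(s) treated as 'event not observed'")
  }

  occurred <- (!is.na(flags$bcr) & flags$bcr) |
    (!is.na(flags$met) & flags$met) |
    (!is.na(flags$cdeath) & flags$cdeath)

  # earliest time among events that actually occurred
  event_time <- purrr::pmap_dbl(
    list(flags$bcr, flags$met, flags$cdeath, times$t_bcr, times$t_met, times$t_cdeath),
    function(b, m, d, tb, tm, td) {
      ts <- c(if (isTRUE(b)) tb, if (isTRUE(m)) tm, if (isTRUE(d)) td)
      if (length(ts) == 0) NA_real_ else min(ts)
    }
  )
  if (any(event_time[occurred] < 0, na.rm = TRUE)) stop("event times must be >= 0")

  cohort$bad_outcome <- occurred
  cohort$bad_outcome_time <- ifelse(occurred, event_time, cohort$fu_years)
  cohort
}

#' Assign binary risk labels under the train or test rule
#'
#' Training rule: high risk if bad outcome within 3 years OR local spread
#' (any of pN/pV/pL); low risk if no bad outcome AND follow-up longer than
#' 5 years AND no local spread. Test rule drops the local-spread clauses:
#' high if bad outcome within 3 years; low if no bad outcome and follow-up
#' longer than 5 years. Cases matching neither rule are `undefined`.
#'
#' Boundary conventions: "within 3 years" is `<= 3`, "more than 5 years"
#' is `> 5`. A missing spread flag does not assert spread: the train
#' low-risk rule requires all *present* flags to be FALSE and at least one
#' flag to be present.
#'
#' @param cohort A data frame of cases; if `bad_outcome` /
#'   `bad_outcome_time` are absent they are derived via
#'   [derive_bad_outcome()]. The train rule additionally uses logical
#'   columns `pn`, `pv`, `pl` (NA allowed).
#' @param mode `"train"` or `"test"`.
#' @param horizon_high Years within which a bad outcome makes a case high
#'   risk (default 3).
#' @param horizon_low Follow-up (years) that must be exceeded for an
#'   event-free case to be low risk (default 5).
#' @return The input tibble with a `risk_label` factor column with levels
#'   `high`, `low`, `undefined`.
#' @export
assign_risk_label <- function(cohort, mode = c("train", "test"),
                              horizon_high = 3, horizon_low = 5) {
  mode <- match.arg(mode)
  cohort <- tibble::as_tibble(cohort)
  if (!all(c("bad_outcome", "bad_outcome_time") %in% names(cohort))) {
    cohort <- derive_bad_outcome(cohort)
  }

  early_bad <- cohort$bad_outcome & cohort$bad_outcome_time <= horizon_high
  long_clean <- !cohort$bad_outcome & cohort$fu_years > horizon_low

  if (mode == "train") {
    for (col in c("pn", "pv", "pl")) {
      if (!col %in% names(cohort)) {
        stop("train-mode labeling requires spread flag column '", col, "'")
      }
    }
    spread_any <- (!is.na(cohort$pn) & cohort$pn) |
      (!is.na(cohort$pv) & cohort$pv) |
      (!is.na(cohort$pl) & cohort$pl)
    n_flags <- (!is.na(cohort$pn)) + (!is.na(cohort$pv)) + (!is.na(cohort$pl))
    no_spread <- !spread_any & n_flags > 0
    high <- early_bad | spread_any
    low <- !high & long_clean & no_spread
  } else {
    high <- early_bad
    low <- long_clean
  }

  label <- rep("undefined", nrow(cohort))
  label[high] <- "high"
  label[low & !high] <- "low"
  cohort$risk_label <- factor(label, levels = c("high", "low", "undefined"))
  cohort
}

cohort_columns <- c(
  "case_id", "tma_id", "age", "psa", "isup", "pt", "pn", "pv", "pl",
  "fu_years", "bcr", "t_bcr", "met", "t_met", "cdeath", "t_cdeath"
)

#' Read a cohort table
#'
#' Reads a tab- or comma-separated cohort table with the canonical columns
#' `case_id, tma_id, age, psa, isup, pt, pn, pv, pl, fu_years, bcr, t_bcr,
#' met, t_met, cdeath, t_cdeath`. Empty cells become explicit `NA`, never
#' silent zeros. Round-trips byte-stably with [write_cohort()].
#'
#' @param path Path to a `.tsv` or `.csv` file.
#' @return A tibble with one row per case.
#' @export
read_cohort <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  types <- readr::cols(
    case_id = readr::col_character(), tma_id = readr::col_character(),
    age = readr::col_double(), psa = readr::col_double(),
    isup = readr::col_double(), pt = readr::col_double(),
    pn = readr::col_logical(), pv = readr::col_logical(),
    pl = readr::col_logical(), fu_years = readr::col_double(),
    bcr = readr::col_logical(), t_bcr = readr::col_double(),
    met = readr::col_logical(), t_met = readr::col_double(),
    cdeath = readr::col_logical(), t_cdeath = readr::col_double()
  )
  tab <- readr::read_delim(path, delim = delim, col_types = types,
                           na = c("", "NA"), progress = FALSE)
  missing_cols <- setdiff(cohort_columns, names(tab))
  if (length(missing_cols) > 0) {
    stop("cohort table is missing mandatory columns: ",
         paste(missing_cols, collapse = ", "))
  }
  tab[cohort_columns]
}

#' Write a cohort table
#'
#' @param cohort A cohort tibble (extra columns beyond the canonical set are
#'   dropped with a warning so the writer/reader round trip is stable).
#' @param path Output path; `.csv` writes comma-separated, anything else
#'   tab-separated.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  missing_cols <- setdiff(cohort_columns, names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort is missing mandatory columns: ", paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(cohort), cohort_columns)
  if (length(extra) > 0) {
    warning("dropping non-canonical columns on write: ", paste(extra, collapse = ", "))
  }
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(cohort[cohort_columns], path, delim = delim, na = "")
  invisible(path)
}

#' Read a spot manifest
#'
#' A spot manifest maps TMA spot images to cases: columns `spot_id`,
#' `case_id`, `tma_id`, `image_path`.
#'
#' @param path Path to a TSV file.
#' @return A tibble.
#' @export
read_spot_manifest <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  needed <- c("spot_id", "case_id", "tma_id", "image_path")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0) {
    stop("spot manifest is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  tab
}
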