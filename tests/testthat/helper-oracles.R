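# Published confusion matrices [tn, fp, fn, tp] from the motivating
# prostate-cancer study, with the balanced accuracies printed alongside
# them. Used as exact recomputation fixtures.
published_confusions <- function() {
  list(
    raw_pcai        = list(cm = c(tn = 514, fp = 197, fn = 109, tp = 288), ba = 0.724),
    raw_isup        = list(cm = c(tn = 659, fp = 52,  fn = 167, tp = 230), ba = 0.753),
    cleaned_pcai    = list(cm = c(tn = 513, fp = 121, fn = 56,  tp = 288), ba = 0.823),
    cleaned_isup    = list(cm = c(tn = 595, fp = 39,  fn = 129, tp = 215), ba = 0.782),
    cb_raw_pcai     = list(cm = c(tn = 76,  fp = 36,  fn = 22,  tp = 67),  ba = 0.716),
    cb_raw_path1    = list(cm = c(tn = 79,  fp = 33,  fn = 28,  tp = 61),  ba = 0.695),
    cb_raw_isup     = list(cm = c(tn = 106, fp = 6,   fn = 32,  tp = 57),  ba = 0.793),
    cb_cleaned_pcai = list(cm = c(tn = 76,  fp = 21,  fn = 9,   tp = 67),  ba = 0.833),
    cb_cleaned_path1 = list(cm = c(tn = 76, fp = 21,  fn = 15,  tp = 61),  ba = 0.793),
    cb_cleaned_isup = list(cm = c(tn = 94,  fp = 3,   fn = 23,  tp = 53),  ba = 0.833)
  )
}

# Published 7x7 inter-pathologist Gleason agreement matrix (case level):
# rows pathologist 2, columns pathologist 1, categories
# 3+3, 3+4, 4+3, 4+4, {4+5, 3+5}, {5+4, 5+3}, 5+5. Printed linearly
# weighted kappa: 0.29.
pathologist_agreement_matrix <- function() {
  matrix(c(
    52, 77, 23,  37,  9,  4,  2,
    18, 65, 67, 118, 51, 18, 14,
     1,  2, 10,  34, 17, 17, 18,
     0,  1,  0,  18,  9, 11, 16,
     1,  1,  0,   2,  4, 18, 22,
     0,  0,  0,   1,  1,  5, 18,
     0,  0,  0,   0,  1,  4, 21
  ), nrow = 7, byrow = TRUE)
}

# Exhaustive concordant-pair AUC: the definition, as an independent oracle
# for the rank-based implementation.
pairwise_auc_oracle <- function(scores, pos) {
  s_pos <- scores[pos]
  s_neg <- scores[!pos]
  total <- 0
  for (sp in s_pos) {
    total <- total + sum(sp > s_neg) + 0.5 * sum(sp == s_neg)
  }
  total / (length(s_pos) * length(s_neg))
}

# A deterministic small "spot": eosin-pink disc with n_dark dark blobs,
# for preprocessing tests that need realistic tissue/background structure.
toy_spot <- function(px = 64, n_dark = 12, seed = 42) {
  pcai:::with_seed(seed, {
    img <- array(stats::runif(px * px * 3, 0.92, 0.96), dim = c(px, px, 3))
    cx <- (px + 1) / 2
    d2 <- outer((seq_len(px) - cx)^2, (seq_len(px) - cx)^2, "+")
    disc <- d2 <= (0.45 * px)^2
    base <- c(0.85, 0.62, 0.78)
    for (ch in 1:3) {
      layer <- img[, , ch]
      layer[disc] <- base[ch]
      img[, , ch] <- layer
    }
    pos <- which(disc, arr.ind = TRUE)
    pick <- pos[sample.int(nrow(pos), n_dark), , drop = FALSE]
    for (i in seq_len(n_dark)) {
      r <- pick[i, 1]; cc <- pick[i, 2]
      img[r, cc, ] <- c(0.3, 0.2, 0.5)
    }
    img
  })
}

# A tiny labelled sample table for curation tests.
curation_samples <- function(tma_counts) {
  out <- list()
  i <- 0
  for (tma in names(tma_counts)) {
    n_high <- tma_counts[[tma]][1]
    n_low <- tma_counts[[tma]][2]
    lab <- c(rep("high", n_high), rep("low", n_low))
    ids <- sprintf("%s_c%02d", tma, seq_along(lab) + i)
    out[[tma]] <- tibble::tibble(
      spot_id = paste0("s_", ids), case_id = ids, tma_id = tma, risk_label = lab
    )
    i <- i + length(lab)
  }
  dplyr::bind_rows(out)
}
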