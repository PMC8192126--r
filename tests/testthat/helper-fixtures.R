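# Shared miniature dataset, built once per test run.
.fx_env <- new.env(parent = emptyenv())

get_fixtures <- function() {
  if (is.null(.fx_env$fx)) {
    .fx_env$fx <- make_fixtures(seed = 42, n_per_scenario = 6, m = 32)
  }
  .fx_env$fx
}

# random small haplotype matrix + positions for oracle checks
random_site_matrix <- function(nhap = 8, nsite = 12, L = 100) {
  pos <- sort(sample.int(L, nsite))
  h <- matrix(rbinom(nhap * nsite, 1, 0.3), nhap, nsite)
  list(haps = h, positions = pos, L = L)
}

# brute-force per-bin site scan (independent of bin_counts)
brute_bin_counts <- function(haps, positions, window_start, window_len, m) {
  out <- matrix(0L, nrow(haps), m)
  for (b in seq_len(m)) {
    lo <- window_start + (b - 1) * window_len / m
    hi <- window_start + b * window_len / m
    ii <- positions >= lo & positions < hi
    if (any(ii)) out[, b] <- as.integer(rowSums(haps[, ii, drop = FALSE]))
  }
  out
}

# brute-force confusion-matrix metrics (independent single pass)
brute_metrics <- function(probs, labels, thr = 0.5) {
  TP <- FP <- TN <- FN <- 0
  for (i in seq_along(probs)) {
    pos <- probs[i] > thr
    if (pos && labels[i] == 1) TP <- TP + 1
    if (pos && labels[i] == 0) FP <- FP + 1
    if (!pos && labels[i] == 0) TN <- TN + 1
    if (!pos && labels[i] == 1) FN <- FN + 1
  }
  mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       precision = if (TP + FP > 0) TP / (TP + FP) else NA_real_,
       mcc = if (mcc_den > 0) (TP * TN - FP * FN) / mcc_den else NA_real_)
}

# construct a site_frequencies object directly (for statistic oracles)
make_freqs <- function(A, B, C, n_donor_haps = 1e9) {
  structure(list(A = A, B = B, C = C, extra = list(),
                 n_donor_haps = n_donor_haps,
                 positions = seq_along(A)),
            class = "site_frequencies")
}
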