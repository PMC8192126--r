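#' Confusion counts at a probability threshold
#'
#' The positive class is AI (label 1); an item is called positive when its
#' predicted probability exceeds `threshold`.
#'
#' @param probs predicted Pr[AI] in `[0, 1]`.
#' @param labels binary truth (1 = AI).
#' @param threshold decision threshold (default 0.5).
#' @return named integer vector `c(TP, FP, TN, FN)`.
#' @export
confusion <- function(probs, labels, threshold = 0.5) {
  stopifnot(length(probs) == length(labels), all(labels %in% c(0, 1)))
  pos <- probs > threshold
  c(TP = sum(pos & labels == 1), FP = sum(pos & labels == 0),
    TN = sum(!pos & labels == 0), FN = sum(!pos & labels == 1))
}

#' Classification metrics from confusion counts
#'
#' Precision = TP/(TP+FP); NPV = TN/(TN+FN); TPR (recall) = TP/(TP+FN);
#' FPR = FP/(FP+TN); F1 = harmonic mean of precision and recall; MCC is the
#' Matthews correlation coefficient and `MCC_norm = (MCC+1)/2`, so 0.5 is
#' chance level. Metrics with zero denominators are `NA`, never
#' 0-by-convention.
#'
#' @param cc named counts from [confusion()].
#' @return named numeric vector.
#' @export
metrics <- function(cc) {
  TP <- as.numeric(cc[["TP"]]); FP <- as.numeric(cc[["FP"]])
  TN <- as.numeric(cc[["TN"]]); FN <- as.numeric(cc[["FN"]])
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  precision <- div(TP, TP + FP)
  npv <- div(TN, TN + FN)
  tpr <- div(TP, TP + FN)
  fpr <- div(FP, FP + TN)
  f1 <- if (is.na(precision) || is.na(tpr) || precision + tpr == 0) NA_real_
        else 2 * precision * tpr / (precision + tpr)
  mcc_den <- sqrt((TP + FP)) * sqrt((TP + FN)) * sqrt((TN + FP)) * sqrt((TN + FN))
  mcc <- if (mcc_den == 0) NA_real_ else (TP * TN - FP * FN) / mcc_den
  c(precision = precision, NPV = npv, TPR = tpr, FPR = fpr, F1 = f1,
    MCC = mcc, MCC_norm = if (is.na(mcc)) NA_real_ else (mcc + 1) / 2)
}

#' ROC, precision-recall and MCC-F1 curves
#'
#' Thresholds are taken at every distinct predicted probability (plus
#' sentinels below/above all predictions), giving exact curves; the sweep
#' traverses false-positive rates from 0 to 100%. The negative condition is
#' selectable by subsetting before the call (e.g. neutral only, sweep only,
#' both, DFE).
#'
#' @inheritParams confusion
#' @return data.frame with one row per threshold: `threshold`, `TPR`,
#'   `FPR`, `precision`, `F1`, `MCC`, `MCC_norm`; attribute `auc` holds the
#'   trapezoidal ROC AUC and `mccf1` the MCC-F1 summary index (1 minus the
#'   mean normalised distance from curve points to the perfect point (1,1)
#'   in MCC_norm-F1 space).
#' @export
curves <- function(probs, labels) {
  stopifnot(any(labels == 1), any(labels == 0))
  th <- c(-Inf, sort(unique(probs)))
  rows <- lapply(th, function(t) {
    mm <- metrics(confusion(probs, labels, t))
    c(threshold = t, mm)
  })
  d <- as.data.frame(do.call(rbind, rows))
  # ROC AUC by trapezoid over (FPR, TPR), sorted by FPR
  o <- order(d$FPR, d$TPR)
  fpr <- d$FPR[o]; tpr <- d$TPR[o]
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  ok <- !is.na(d$MCC_norm) & !is.na(d$F1)
  mccf1 <- if (any(ok)) {
    1 - mean(sqrt((1 - d$MCC_norm[ok])^2 + (1 - d$F1[ok])^2)) / sqrt(2)
  } else NA_real_
  attr(d, "auc") <- auc
  attr(d, "mccf1") <- mccf1
  d
}

#' Mean prediction binned by selection coefficient and onset time
#'
#' Bins the AI simulations' predicted probabilities by log10(s) and T_sel
#' and reports the per-cell mean prediction (empty cells `NA`).
#'
#' @param probs predictions, one per simulation.
#' @param params list of [selection_params()] parallel to `probs`.
#' @param s_bins,t_bins number of bins (or explicit break vectors).
#' @return list with `grid` (matrix s-bins x t-bins of mean predictions),
#'   `s_breaks`, `t_breaks`, `counts`.
#' @export
prediction_grid <- function(probs, params, s_bins = 5, t_bins = 5) {
  stopifnot(length(probs) == length(params))
  s <- vapply(params, function(p) p$s, 0)
  t_ <- vapply(params, function(p) p$T_sel, 0)
  sb <- if (length(s_bins) == 1) {
    seq(min(log10(s)), max(log10(s)), length.out = s_bins + 1)
  } else s_bins
  tb <- if (length(t_bins) == 1) {
    seq(min(t_), max(t_), length.out = t_bins + 1)
  } else t_bins
  si <- findInterval(log10(s), sb, rightmost.closed = TRUE, all.inside = TRUE)
  ti <- findInterval(t_, tb, rightmost.closed = TRUE, all.inside = TRUE)
  ns <- length(sb) - 1; nt <- length(tb) - 1
  grid <- matrix(NA_real_, ns, nt)
  counts <- matrix(0L, ns, nt)
  for (i in seq_len(ns)) {
    for (j in seq_len(nt)) {
      sel <- si == i & ti == j
      counts[i, j] <- sum(sel)
      if (any(sel)) grid[i, j] <- mean(probs[sel])
    }
  }
  list(grid = grid, s_breaks = sb, t_breaks = tb, counts = counts)
}
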