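#' Class ratios for calibration resampling
#'
#' @param neutral,sweep,ai non-negative weights; at least one positive.
#'   The conventional genome-wide setting is `1:0.1:0.02` (AI windows are
#'   rare), the even setting `1:1:1`.
#' @export
class_ratios <- function(neutral = 1, sweep = 0.1, ai = 0.02) {
  w <- c(neutral = neutral, sweep = sweep, ai = ai)
  stopifnot(all(w >= 0), any(w > 0))
  structure(list(weights = w), class = "class_ratios")
}

#' Resample a labelled dataset to target class ratios
#'
#' The class with the largest implied count is kept whole; other classes
#' are down-sampled without replacement, or up-sampled with replacement if
#' the target exceeds their size. Resampling uses R's RNG.
#'
#' @param scenarios character vector of scenario labels per item
#'   (`"neutral"`, `"sweep"`, `"ai"`; `"dfe"` items count as neutral
#'   weight).
#' @param ratios a [class_ratios()].
#' @return integer indices into the input defining the resampled dataset.
#' @export
resample_class_ratios <- function(scenarios, ratios) {
  stopifnot(inherits(ratios, "class_ratios"))
  cls <- ifelse(scenarios == "dfe", "neutral", scenarios)
  w <- ratios$weights
  present <- names(w)[w > 0]
  missing <- setdiff(present, unique(cls))
  if (length(missing) > 0) {
    stop("requested class absent from dataset: ", paste(missing, collapse = ", "))
  }
  counts <- table(factor(cls, levels = names(w)))
  # scale so the class needing the most items is kept whole
  scale_ <- min(counts[w > 0] / w[w > 0])
  target <- round(w * scale_)
  idx <- integer(0)
  for (cl in names(w)) {
    if (target[[cl]] == 0) next
    ii <- which(cls == cl)
    idx <- c(idx, if (target[[cl]] <= length(ii)) {
      sample(ii, target[[cl]])
    } else {
      sample(ii, target[[cl]], replace = TRUE)
    })
  }
  sort(idx)
}

#' Fit a probability calibrator
#'
#' Beta calibration fits the three-parameter monotone map
#' `p -> 1 / (1 + exp(-c) * (1-p)^b / p^a)` by logistic regression on the
#' features `log p` and `-log(1-p)`; non-negativity of `a` and `b`
#' (monotonicity) is enforced by refitting with the offending feature
#' dropped. Isotonic regression fits a monotone step function; Platt
#' scaling a two-parameter sigmoid on the raw score.
#'
#' @param method `"beta"`, `"isotonic"` or `"platt"`.
#' @param raw_scores classifier outputs in `[0, 1]`.
#' @param labels binary outcomes (1 = AI).
#' @param ratios optional [class_ratios()] recorded as the fit condition.
#' @param eps raw scores are clamped to `[eps, 1-eps]` before log
#'   transforms.
#' @return object of class `introscan_calibrator`.
#' @export
fit_calibrator <- function(method = c("beta", "isotonic", "platt"),
                           raw_scores, labels, ratios = NULL, eps = 1e-6) {
  method <- match.arg(method)
  stopifnot(length(raw_scores) == length(labels), all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2) stop("labels are degenerate (one class)")
  p <- pmin(pmax(raw_scores, eps), 1 - eps)
  fit <- switch(method,
    beta = {
      f1 <- log(p); f2 <- -log(1 - p)
      co <- stats::coef(stats::glm(labels ~ f1 + f2, family = stats::binomial()))
      a <- co[["f1"]]; b <- co[["f2"]]; cc <- co[["(Intercept)"]]
      if (a < 0) {
        co <- stats::coef(stats::glm(labels ~ f2, family = stats::binomial()))
        a <- 0; b <- co[["f2"]]; cc <- co[["(Intercept)"]]
      }
      if (b < 0) {
        co <- stats::coef(stats::glm(labels ~ f1, family = stats::binomial()))
        a <- co[["f1"]]; b <- 0; cc <- co[["(Intercept)"]]
        if (a < 0) { a <- 0; cc <- stats::qlogis(mean(labels)) }
      }
      list(a = unname(a), b = unname(b), c = unname(cc))
    },
    isotonic = {
      o <- order(p)
      iso <- stats::isoreg(p[o], labels[o])
      list(x = iso$x, yf = iso$yf)
    },
    platt = {
      co <- stats::coef(stats::glm(labels ~ p, family = stats::binomial()))
      list(intercept = co[[1]], slope = co[[2]])
    })
  structure(list(method = method, fit = fit, ratios = ratios, eps = eps),
            class = "introscan_calibrator")
}

#' Apply a calibrator to raw scores
#'
#' @param object an `introscan_calibrator`.
#' @param raw_scores scores in `[0, 1]`.
#' @param ... unused.
#' @return calibrated probabilities in `[0, 1]`.
#' @export
predict.introscan_calibrator <- function(object, raw_scores, ...) {
  p <- pmin(pmax(raw_scores, object$eps), 1 - object$eps)
  f <- object$fit
  switch(object$method,
    beta = stats::plogis(f$c + f$a * log(p) - f$b * log(1 - p)),
    isotonic = {
      y <- stats::approx(f$x, f$yf, xout = p, rule = 2, ties = "ordered")$y
      pmin(pmax(y, 0), 1)
    },
    platt = stats::plogis(f$intercept + f$slope * p))
}

#' Reliability table and residual diagnostic
#'
#' Partitions `[0, 1]` into `n_bins` equal bins of predicted probability
#' and reports per-bin mean prediction, empirical outcome frequency and
#' count (empty bins kept, count 0). Also returns per-bin residuals
#' (frequency minus mean prediction) and a Shapiro-Wilk statistic for the
#' normality of the residual sum diagnostic.
#'
#' @param calibrated calibrated probabilities.
#' @param labels binary outcomes.
#' @param n_bins number of bins (>= 2).
#' @return data.frame (`bin_lo`, `bin_hi`, `mean_pred`, `freq`, `count`,
#'   `residual`) with attributes `shapiro_W` and `shapiro_p`.
#' @export
reliability_table <- function(calibrated, labels, n_bins = 10) {
  stopifnot(n_bins >= 2)
  br <- seq(0, 1, length.out = n_bins + 1)
  bin <- findInterval(calibrated, br, rightmost.closed = TRUE, all.inside = TRUE)
  d <- data.frame(bin_lo = br[-length(br)], bin_hi = br[-1],
                  mean_pred = NA_real_, freq = NA_real_, count = 0L,
                  residual = NA_real_)
  for (b in seq_len(n_bins)) {
    ii <- bin == b
    d$count[b] <- sum(ii)
    if (any(ii)) {
      d$mean_pred[b] <- mean(calibrated[ii])
      d$freq[b] <- mean(labels[ii])
      d$residual[b] <- d$freq[b] - d$mean_pred[b]
    }
  }
  res <- d$residual[!is.na(d$residual)]
  if (length(res) >= 3 && stats::sd(res) > 0) {
    sw <- stats::shapiro.test(res)
    attr(d, "shapiro_W") <- unname(sw$statistic)
    attr(d, "shapiro_p") <- sw$p.value
  } else {
    attr(d, "shapiro_W") <- NA_real_
    attr(d, "shapiro_p") <- NA_real_
  }
  d
}

#' Fit the default calibration for a trained classifier
#'
#' Convenience wrapper: resamples the (score, scenario) set to the target
#' ratios and fits the chosen calibrator on AI-vs-rest labels.
#'
#' @param raw_scores classifier outputs for a labelled dataset.
#' @param scenarios scenario labels parallel to `raw_scores`.
#' @param ratios a [class_ratios()].
#' @param method calibrator family.
#' @export
calibrate_classifier <- function(raw_scores, scenarios,
                                 ratios = class_ratios(),
                                 method = "beta") {
  idx <- resample_class_ratios(scenarios, ratios)
  fit_calibrator(method, raw_scores[idx],
                 as.integer(scenarios[idx] == "ai"), ratios = ratios)
}
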