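#' Selection parameters for one simulated region
#'
#' @param scenario one of `"neutral"`, `"sweep"`, `"ai"`, `"dfe"`.
#' @param s selection coefficient (unscaled; the simulator multiplies by Q).
#' @param T_mut time the focal mutation is introduced, generations before
#'   present.
#' @param T_sel time selection begins acting on it (`T_sel <= T_mut`).
#' @param pulse index of the donor-to-recipient pulse carrying the allele
#'   (AI only; 1-based into the model's donor pulse table).
#' @param final_af final beneficial allele frequency in the recipient sample
#'   (filled in by [simulate_region()]).
#' @export
selection_params <- function(scenario, s = NA_real_, T_mut = NA_real_,
                             T_sel = NA_real_, pulse = NA_integer_,
                             final_af = NA_real_) {
  scenario <- match.arg(scenario, c("neutral", "sweep", "ai", "dfe"))
  if (scenario %in% c("sweep", "ai")) {
    stopifnot(is.finite(s), s > 0, is.finite(T_mut), is.finite(T_sel),
              T_sel <= T_mut)
  }
  structure(list(scenario = scenario, s = s, T_mut = T_mut, T_sel = T_sel,
                 pulse = pulse, final_af = final_af),
            class = "selection_params")
}

#' Draw selection parameters for a scenario
#'
#' The selection coefficient is log-uniform on `s_range`. Mutation and
#' selection-onset times are uniform, decoupled (allowing soft sweeps), and
#' constrained by scenario:
#' \itemize{
#'   \item sweep: both times between 1 kya and the recipient/outgroup split,
#'     with `T_sel <= T_mut`;
#'   \item AI: `T_mut` between (pulse time + 1 kya) and the creation of the
#'     donor population; `T_sel` between 1 kya and the pulse time. For models
#'     with several donor pulses, draws are balanced across pulses.
#' }
#'
#' @param scenario `"sweep"` or `"ai"`.
#' @param model a [demographic_model()] (unscaled).
#' @param s_range length-2 numeric, `0 < lo < hi <= 0.1`.
#' @param n number of draws.
#' @return a list of [selection_params()] (length `n`).
#' @export
draw_selection_params <- function(scenario, model, s_range = c(1e-4, 0.1),
                                  n = 1) {
  scenario <- match.arg(scenario, c("sweep", "ai"))
  stopifnot(length(s_range) == 2, s_range[1] > 0, s_range[2] <= 0.1,
            s_range[1] < s_range[2], n >= 1)
  kya <- 1000 / model$generation_time
  s <- 10^stats::runif(n, log10(s_range[1]), log10(s_range[2]))
  out <- vector("list", n)
  if (scenario == "sweep") {
    hi <- .role_creation_time(model, "recipient")
    stopifnot(is.finite(hi), hi > kya)
    T_mut <- stats::runif(n, kya, hi)
    T_sel <- stats::runif(n, kya, T_mut)
    for (i in seq_len(n)) {
      out[[i]] <- selection_params("sweep", s[i], T_mut[i], T_sel[i])
    }
  } else {
    pulses <- .donor_pulses(model)
    if (nrow(pulses) == 0) stop("model has no donor-to-recipient pulse")
    donor_hi <- .role_creation_time(model, "donor")
    if (!is.finite(donor_hi)) donor_hi <- max(model$splits$time)
    # balance draws across pulses
    idx <- rep_len(sample(nrow(pulses)), n)
    for (i in seq_len(n)) {
      tp <- pulses$time[idx[i]]
      stopifnot(donor_hi > tp + kya)
      T_mut <- stats::runif(1, tp + kya, donor_hi)
      T_sel <- stats::runif(1, kya, tp)
      out[[i]] <- selection_params("ai", s[i], T_mut, T_sel, pulse = idx[i])
    }
  }
  out
}

#' Distribution of fitness effects configuration
#'
#' Two mutation classes: neutral (probability `p_neutral`) and deleterious.
#' Deleterious selection coefficients follow a reflected gamma distribution
#' (all `s < 0`) with the given shape and expected value; the dominance
#' coefficient is the fixed value `0.5 / (1 - 7071.07 * E[s])`, making
#' deleterious mutations effectively recessive.
#'
#' @param p_neutral proportion of neutral mutations.
#' @param shape gamma shape parameter.
#' @param mean_s expected value of the (negative) selection coefficient.
#' @export
dfe_config <- function(p_neutral = 0.3, shape = 0.186,
                       mean_s = -0.01314833) {
  stopifnot(p_neutral >= 0, p_neutral <= 1, shape > 0, mean_s < 0)
  structure(list(
    p_neutral = p_neutral, p_deleterious = 1 - p_neutral,
    shape = shape, mean_s = mean_s,
    h = 0.5 / (1 - 7071.07 * mean_s)
  ), class = "dfe_config")
}

#' Draw mutation classes and fitness effects from a DFE
#'
#' @param cfg a [dfe_config()].
#' @param n number of mutations to draw.
#' @return data.frame with columns `class` ("neutral"/"deleterious"), `s`
#'   (0 for neutral, negative otherwise) and `h` (the fixed dominance for
#'   deleterious mutations, `NA` for neutral ones).
#' @export
draw_dfe_mutation <- function(cfg, n = 1) {
  stopifnot(inherits(cfg, "dfe_config"), n >= 1)
  del <- stats::runif(n) < cfg$p_deleterious
  s <- numeric(n)
  scale <- abs(cfg$mean_s) / cfg$shape
  s[del] <- -stats::rgamma(sum(del), shape = cfg$shape, scale = scale)
  data.frame(class = ifelse(del, "deleterious", "neutral"),
             s = s, h = ifelse(del, cfg$h, NA_real_),
             stringsAsFactors = FALSE)
}
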