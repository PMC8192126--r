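#' Generate a miniature labelled dataset
#'
#' Produces, in well under a minute, a small three-scenario dataset under a
#' strongly rescaled version of the single-pulse out-of-Africa model (small
#' panels, Q = 50, strong selection), sufficient to exercise every module
#' without any download. Bit-identical for a fixed seed.
#'
#' @param seed integer seed.
#' @param n_per_scenario regions per scenario.
#' @param m number of encoding bins.
#' @param phased encode as phased haplotypes.
#' @return list with `results` (list of [simulation_result()]),
#'   `matrices` (list of [resized_matrix()]), `scenarios` (labels),
#'   `labels` (binary AI indicator), `model`, and `m`.
#' @export
make_fixtures <- function(seed = 1, n_per_scenario = 6, m = 32,
                          phased = TRUE) {
  set.seed(seed)
  model <- model_preset("A1", n_donor = 4, n_recipient = 8, n_outgroup = 8)
  res <- c(
    simulate_scenario(model, "neutral", n_per_scenario, Q = 50),
    simulate_scenario(model, "sweep", n_per_scenario, Q = 50,
                      s_range = c(0.03, 0.1), af_cutoff = 0.25),
    simulate_scenario(model, "ai", n_per_scenario, Q = 50,
                      s_range = c(0.03, 0.1), af_cutoff = 0.25)
  )
  scen <- vapply(res, function(r) r$params$scenario, "")
  mats <- lapply(res, encode_matrix, m = m, phased = phased)
  list(results = res, matrices = mats, scenarios = scen,
       labels = as.integer(scen == "ai"), model = model, m = m)
}
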