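#' Read a HapMap-format genetic map
#'
#' Expects whitespace-separated text with columns
#' `Chromosome Position(bp) Rate(cM/Mb) Map(cM)` (header optional).
#'
#' @param path path to the map file.
#' @return data.frame with columns `chrom`, `pos`, `rate` (cM/Mb).
#' @export
read_genetic_map <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("[A-Za-z]", sub("^\\S+", "", first)) ||
    grepl("^\\s*[Cc]hr", first)
  d <- utils::read.table(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(d) < 3) stop("genetic map needs at least 3 columns")
  d <- d[, 1:3]
  names(d) <- c("chrom", "pos", "rate")
  stopifnot(is.numeric(d$pos), is.numeric(d$rate), all(d$rate >= 0))
  d
}

#' Draw a random map chunk of a given length
#'
#' Picks a uniformly random interval of length `L` from the physical span of
#' the map and returns its piecewise-constant recombination rates with
#' coordinates shifted to `[0, L)`.
#'
#' @param map data.frame from [read_genetic_map()] (one chromosome at a
#'   time; if several, one is chosen with probability proportional to span).
#' @param L chunk length in bp.
#' @return data.frame with columns `start`, `end`, `rate` (cM/Mb) tiling
#'   `[0, L)`; class `"genetic_map_chunk"`.
#' @export
sample_map_chunk <- function(map, L) {
  sp <- split(map, map$chrom)
  spans <- vapply(sp, function(m) max(m$pos) - min(m$pos), 0)
  ok <- spans >= L
  if (!any(ok)) stop("no chromosome in the map spans ", L, " bp")
  sp <- sp[ok]; spans <- spans[ok]
  m <- sp[[sample.int(length(sp), 1, prob = spans)]]
  m <- m[order(m$pos), ]
  start <- stats::runif(1, min(m$pos), max(m$pos) - L)
  breaks <- sort(unique(c(start, start + L, m$pos[m$pos > start & m$pos < start + L])))
  seg <- data.frame(start = utils::head(breaks, -1), end = utils::tail(breaks, -1))
  # rate applying in [pos_i, pos_{i+1}) is the rate recorded at pos_i
  seg$rate <- m$rate[findInterval(seg$start, m$pos)]
  seg$start <- seg$start - start
  seg$end <- seg$end - start
  class(seg) <- c("genetic_map_chunk", class(seg))
  seg
}

# piecewise map -> (phys breakpoints, cumulative Morgans), rates scaled by Q
.map_to_cum <- function(chunk, L, rec_flat, Q) {
  if (is.null(chunk)) {
    return(list(phys = c(0, L), cumM = c(0, rec_flat * L)))  # rec_flat pre-scaled
  }
  stopifnot(inherits(chunk, "genetic_map_chunk"))
  morgans_per_bp <- chunk$rate * 1e-8 * Q
  cum <- cumsum((chunk$end - chunk$start) * morgans_per_bp)
  list(phys = c(chunk$start[1], chunk$end), cumM = c(0, cum))
}

#' Construct a simulation result
#'
#' Container for one simulated region: 0/1 haplotype matrix (rows =
#' haplotypes grouped by panel in the model's declared block order), integer
#' bp positions, per-haplotype population labels, the selection parameters
#' and the focal-site position.
#'
#' @param haps integer matrix, haplotypes x segregating sites, values 0/1.
#' @param positions integer bp positions, strictly increasing, in `[1, L]`.
#' @param L region length in bp.
#' @param pop character vector of population (panel) labels, one per row.
#' @param params a [selection_params()].
#' @param selected_pos bp position of the focal selected site (NA for
#'   neutral/DFE scenarios).
#' @param seed the integer seed this simulation was run with.
#' @param attempts rejection-sampling attempt counts (diagnostics).
#' @param panels data.frame with columns `panel` and `role` describing the
#'   population blocks (in block order).
#' @export
simulation_result <- function(haps, positions, L, pop, params,
                              selected_pos = NA_integer_, seed = NA_integer_,
                              attempts = c(intro = 0, end = 0),
                              panels = NULL) {
  stopifnot(is.matrix(haps), nrow(haps) == length(pop),
            ncol(haps) == length(positions))
  if (length(positions) > 1) stopifnot(all(diff(positions) > 0))
  stopifnot(all(positions >= 1), all(positions <= L))
  stopifnot(all(haps %in% c(0L, 1L)))
  structure(list(haps = haps, positions = as.integer(positions), L = L,
                 pop = pop, params = params, selected_pos = selected_pos,
                 seed = seed, attempts = attempts, panels = panels),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %s: %d haplotypes x %d sites, L=%g bp\n",
              x$params$scenario, nrow(x$haps), ncol(x$haps), x$L))
  if (!is.na(x$params$final_af)) {
    cat(sprintf("  final beneficial AF in recipient sample: %.3f\n",
                x$params$final_af))
  }
  invisible(x)
}

#' Simulate one region under a demographic model
#'
#' Runs the forward Wright-Fisher engine for the full model history (burn-in
#' from the root population plays the role of recapitation: all sampled
#' lineages share a common ancestor and ancestral variation is at
#' mutation-drift equilibrium). For sweep and AI scenarios the focal
#' beneficial mutation is introduced as a single copy at the region midpoint
#' at `T_mut`; simulation state is checkpointed before introduction (and
#' again after successful transfer to the recipient, for AI) and restored on
#' loss rather than restarted, conditioning on the allele segregating at
#' frequency >= `min_freq` in the recipient at present and being present in
#' the recipient sample. Higher frequency cutoffs are applied afterwards by
#' [post_filter_af()].
#'
#' @param model a [demographic_model()] with natural (unscaled) parameter values.
#' @param params a [selection_params()]; a bare scenario string is accepted
#'   for `"neutral"`/`"dfe"`.
#' @param seed integer seed; all randomness in this simulation flows from it.
#' @param Q scaling factor passed to [scale_model()].
#' @param map optional `genetic_map_chunk` (see [sample_map_chunk()]);
#'   default is the model's flat recombination rate.
#' @param dfe optional [dfe_config()]; implied by scenario `"dfe"`.
#' @param min_freq in-simulation rejection threshold on the recipient
#'   beneficial allele frequency at present.
#' @param max_attempts cap on checkpoint restores before giving up with an
#'   error (signals a near-impossible parameter draw).
#' @param burnin_factor burn-in length as a multiple of the (scaled) root
#'   population size.
#' @return a [simulation_result()].
#' @export
simulate_region <- function(model, params, seed, Q = 1, map = NULL,
                            dfe = NULL, min_freq = 0.01, max_attempts = 2000,
                            burnin_factor = 10) {
  if (is.character(params)) params <- selection_params(params)
  stopifnot(inherits(model, "demographic_model"),
            inherits(params, "selection_params"))
  scen <- params$scenario
  if (scen == "dfe" && is.null(dfe)) dfe <- dfe_config()
  m <- scale_model(model, Q)

  pop_idx <- function(nm) match(nm, m$pops$name) - 1L
  events <- list()
  for (i in seq_len(nrow(m$splits))) {
    events[[length(events) + 1]] <- list(
      type = 0L, time = as.integer(round(m$splits$time[i])),
      pop = pop_idx(m$splits$child[i]), other = pop_idx(m$splits$parent[i]),
      N = max(2L, as.integer(round(m$splits$N[i]))))
  }
  pulse_times_scaled <- integer(0)
  if (!is.null(m$pulses)) {
    for (i in seq_len(nrow(m$pulses))) {
      tt <- as.integer(round(m$pulses$time[i]))
      events[[length(events) + 1]] <- list(
        type = 1L, time = tt,
        pop = pop_idx(m$pulses$dest[i]), other = pop_idx(m$pulses$source[i]),
        frac = m$pulses$frac[i])
      pulse_times_scaled[i] <- tt
    }
  }
  if (!is.null(m$size_changes)) {
    for (i in seq_len(nrow(m$size_changes))) {
      events[[length(events) + 1]] <- list(
        type = 2L, time = as.integer(round(m$size_changes$time[i])),
        pop = pop_idx(m$size_changes$pop[i]),
        N = max(2L, as.integer(round(m$size_changes$N[i]))))
    }
  }
  for (i in seq_len(nrow(m$panels))) {
    events[[length(events) + 1]] <- list(
      type = 3L, time = as.integer(round(m$panels$time[i])),
      pop = pop_idx(m$panels$pop[i]),
      n_ind = as.integer(m$panels$n_ind[i]), panel = i - 1L)
  }

  focal <- NULL
  if (scen %in% c("sweep", "ai")) {
    rec_pop <- pop_idx(.panel_role(model, "recipient")$pop)
    T_mut <- max(1L, as.integer(round(params$T_mut / m$Q)))
    T_sel <- max(1L, as.integer(round(params$T_sel / m$Q)))
    T_pulse <- -1L
    if (scen == "ai") {
      dp <- .donor_pulses(model)
      pi_ <- if (is.na(params$pulse)) 1L else params$pulse
      T_pulse <- as.integer(round(dp$time[pi_] / m$Q))
      T_mut <- max(T_pulse + 1L, T_mut)
      T_sel <- min(max(1L, T_sel), max(1L, T_pulse - 1L))
      intro_pop <- pop_idx(.panel_role(model, "donor")$pop)
    } else {
      intro_pop <- rec_pop
      T_sel <- min(T_sel, T_mut)
    }
    focal <- list(
      pos = m$L / 2, s = params$s * m$Q, h = 0.5,
      intro_pop = intro_pop, sel_pop = rec_pop,
      T_mut = T_mut, T_sel = T_sel, T_pulse_cond = T_pulse,
      min_freq = min_freq, max_attempts = as.integer(max_attempts),
      recipient_panel = which(model$panels$role == "recipient") - 1L)
  }

  dfe_cfg <- NULL
  if (!is.null(dfe)) {
    stopifnot(inherits(dfe, "dfe_config"))
    dfe_cfg <- list(p_del = dfe$p_deleterious, shape = dfe$shape,
                    mean_abs = abs(dfe$mean_s), h = dfe$h, s_multiplier = m$Q)
  }

  mp <- .map_to_cum(map, m$L, m$rec, m$Q)
  root_i <- pop_idx(m$root)
  N_scaled <- pmax(2L, as.integer(round(m$pops$N)))
  cfg <- list(
    L = m$L, mu = m$mu,
    map_phys = mp$phys, map_cumM = mp$cumM,
    pop_N = N_scaled, root_pop = root_i,
    events = events,
    burnin = as.integer(round(burnin_factor * N_scaled[root_i + 1])),
    scenario = match(scen, c("neutral", "sweep", "ai", "dfe")) - 1L,
    focal = focal, dfe = dfe_cfg,
    prune_interval = 64L,
    seed = as.double(seed))
  res <- .wf_simulate(cfg)
  if (!isTRUE(res$success)) {
    stop(structure(class = c("introscan_sim_failure", "error", "condition"),
                   list(message = sprintf(
                     "rejection sampling exceeded %d attempts (intro=%d, end=%d)",
                     max_attempts, res$attempts_intro, res$attempts_end),
                     call = sys.call())))
  }
  params$final_af <- res$focal_sample_freq
  sel_bp <- if (scen %in% c("sweep", "ai")) {
    if (is.na(res$focal_bp)) as.integer(floor(m$L / 2) + 1) else res$focal_bp
  } else NA_integer_
  simulation_result(
    haps = res$haps, positions = res$positions, L = m$L,
    pop = model$panels$panel[res$panel + 1L],
    params = params, selected_pos = sel_bp, seed = seed,
    attempts = c(intro = res$attempts_intro, end = res$attempts_end),
    panels = model$panels[, c("panel", "role")])
}

#' Post-simulation beneficial allele frequency filter
#'
#' Keeps sweep/AI results whose final beneficial allele frequency in the
#' recipient sample is at least `cutoff`; neutral and DFE results pass
#' unchanged. Order-preserving and idempotent. Note that this filtering
#' changes the retained distribution of (s, T_sel) relative to the draws.
#'
#' @param results list of [simulation_result()].
#' @param cutoff frequency cutoff in `[0, 1]` (0.05 and 0.25 are the
#'   conventional settings).
#' @return the retained sublist.
#' @export
post_filter_af <- function(results, cutoff) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  keep <- vapply(results, function(r) {
    if (!r$params$scenario %in% c("sweep", "ai")) return(TRUE)
    isTRUE(r$params$final_af >= cutoff)
  }, logical(1))
  results[keep]
}

#' Simulate a labelled set of regions for one scenario
#'
#' Draws selection parameters per replicate, simulates, and applies the
#' beneficial-allele-frequency post-filter, repeating until `n` regions are
#' accepted. Per-replicate engine seeds are derived from R's RNG, so the
#' whole set is reproducible from one `set.seed()`.
#'
#' @inheritParams simulate_region
#' @param scenario scenario label.
#' @param n number of accepted regions to return.
#' @param s_range selection coefficient range for sweep/AI draws.
#' @param af_cutoff post-filter cutoff ([post_filter_af()]).
#' @param max_sims cap on total simulation attempts.
#' @param quiet suppress progress output.
#' @return list of `n` [simulation_result()]s.
#' @export
simulate_scenario <- function(model, scenario, n, Q = 1,
                              s_range = c(1e-4, 0.1), af_cutoff = 0,
                              map = NULL, dfe = NULL, min_freq = 0.01,
                              max_attempts = 2000, burnin_factor = 10,
                              max_sims = 50 * n, quiet = TRUE) {
  out <- vector("list", n)
  got <- 0L
  tries <- 0L
  while (got < n) {
    tries <- tries + 1L
    if (tries > max_sims) {
      stop("exceeded ", max_sims, " simulation attempts for scenario ", scenario)
    }
    params <- if (scenario %in% c("sweep", "ai")) {
      draw_selection_params(scenario, model, s_range)[[1]]
    } else {
      selection_params(scenario)
    }
    seed <- sample.int(.Machine$integer.max, 1)
    r <- tryCatch(
      simulate_region(model, params, seed = seed, Q = Q, map = map, dfe = dfe,
                      min_freq = min_freq, max_attempts = max_attempts,
                      burnin_factor = burnin_factor),
      introscan_sim_failure = function(e) NULL)
    if (is.null(r)) next
    if (length(post_filter_af(list(r), af_cutoff)) == 0) next
    got <- got + 1L
    out[[got]] <- r
    if (!quiet && got %% 25 == 0) {
      message(scenario, ": ", got, "/", n, " (", tries, " tries)")
    }
  }
  out
}

#' Mean pairwise nucleotide diversity of a simulated region
#'
#' @param result a [simulation_result()].
#' @return average pairwise differences per site.
#' @export
pairwise_diversity <- function(result) {
  n <- nrow(result$haps)
  c_ <- colSums(result$haps)
  sum(c_ * (n - c_)) / choose(n, 2) / result$L
}
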