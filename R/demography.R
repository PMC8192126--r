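#' Demographic models
#'
#' A demographic model names a set of populations with diploid sizes, a
#' population tree (splits, backwards in time), admixture pulses, and a
#' sampling specification assigning each output panel (non-donor archaic,
#' donor, recipient, unadmixed outgroup) to a population and sampling time.
#' All times are in generations before present at natural (unscaled) values; apply
#' [scale_model()] to obtain a rescaled model for faster forward simulation.
#'
#' @param name model identifier.
#' @param generation_time generation time in years (used to convert the
#'   1 kya bounds on selection times into generations).
#' @param pops data.frame with columns `name` (character) and `N` (diploid
#'   size at creation).
#' @param root name of the root population (present from the start of the
#'   simulation, including burn-in).
#' @param splits data.frame with columns `child`, `parent`, `time`, `N`
#'   (size of the child at creation). Times strictly positive.
#' @param pulses data.frame with columns `source`, `dest`, `time`, `frac`.
#'   For models with several pulses from the donor into the recipient the
#'   row order defines the pulse index used by AI parameter draws.
#' @param size_changes optional data.frame with columns `pop`, `time`, `N`.
#' @param panels data.frame with columns `panel` (label), `pop`, `time`
#'   (sampling time, 0 = present), `n_ind` (diploid individuals) and `role`
#'   (one of "archaic", "donor", "recipient", "outgroup"). Row order is the
#'   column-block order of the encoded genotype matrix.
#' @param mu neutral mutation rate per site per generation.
#' @param rec recombination rate per site per generation (flat default;
#'   a genetic map can be supplied to [simulate_region()] instead).
#' @param L region length in bp.
#' @return an object of class `demographic_model`.
#' @export
demographic_model <- function(name, generation_time, pops, root, splits,
                              pulses = NULL, size_changes = NULL, panels,
                              mu = 1.29e-8, rec = 1e-8, L = 1e5) {
  stopifnot(is.data.frame(pops), all(c("name", "N") %in% names(pops)))
  stopifnot(root %in% pops$name)
  stopifnot(all(c("child", "parent", "time", "N") %in% names(splits)))
  stopifnot(all(splits$time > 0))
  if (!is.null(pulses)) {
    stopifnot(all(c("source", "dest", "time", "frac") %in% names(pulses)))
    stopifnot(all(pulses$time > 0), all(pulses$frac > 0 & pulses$frac < 1))
  }
  stopifnot(all(c("panel", "pop", "time", "n_ind", "role") %in% names(panels)))
  stopifnot(all(panels$pop %in% pops$name))
  stopifnot(all(panels$n_ind >= 1))
  if (sum(panels$role == "recipient") != 1L) {
    stop("model must declare exactly one recipient panel")
  }
  for (r in c("donor", "outgroup")) {
    if (sum(panels$role == r) > 1L) {
      stop("model must declare at most one ", r, " panel")
    }
    if (sum(panels$role == r) == 0L && nrow(splits) > 0L) {
      stop("multi-population model must declare a ", r, " panel")
    }
  }
  # pulse times must predate the relevant splits
  if (!is.null(pulses)) {
    for (i in seq_len(nrow(pulses))) {
      for (p in c(pulses$source[i], pulses$dest[i])) {
        ct <- .creation_time(splits, root, p)
        if (is.finite(ct) && pulses$time[i] >= ct) {
          stop("pulse at time ", pulses$time[i], " predates creation of '", p, "'")
        }
      }
    }
  }
  structure(list(
    name = name, generation_time = generation_time,
    pops = pops, root = root, splits = splits,
    pulses = pulses, size_changes = size_changes, panels = panels,
    mu = mu, rec = rec, L = L, Q = 1
  ), class = "demographic_model")
}

# time at which `pop` comes into existence (Inf for the root)
.creation_time <- function(splits, root, pop) {
  if (pop == root) return(Inf)
  i <- match(pop, splits$child)
  if (is.na(i)) stop("population '", pop, "' has no split and is not the root")
  splits$time[i]
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("<demographic_model>", x$name,
      sprintf("(Q=%g, L=%g bp, mu=%g, rec=%g)\n", x$Q, x$L, x$mu, x$rec))
  cat(" populations:", paste(sprintf("%s(N=%g)", x$pops$name, x$pops$N),
                             collapse = ", "), "\n")
  cat(" panels:", paste(sprintf("%s[%s,n=%d]", x$panels$panel, x$panels$role,
                                x$panels$n_ind), collapse = " "), "\n")
  invisible(x)
}

#' Rescale a demographic model by a factor Q
#'
#' Divides population sizes and event times by `Q` and multiplies the
#' mutation rate, recombination rate (and, at simulation time, the selection
#' coefficient) by `Q`, so that the compound parameters theta = 4*N*mu,
#' rho = 4*N*r and N*s are preserved. Sizes and times are kept real-valued
#' here; rounding to integers happens only inside the simulator, so the
#' invariance is exact at this level.
#'
#' @param model a [demographic_model()].
#' @param Q scaling factor, >= 1. `Q = 1` returns the model unchanged.
#' @return the rescaled model, with `Q` recorded as the cumulative factor.
#' @export
scale_model <- function(model, Q) {
  stopifnot(inherits(model, "demographic_model"), Q >= 1)
  if (Q == 1) return(model)
  if (any(model$pops$N / Q < 2) ||
      (!is.null(model$size_changes) && any(model$size_changes$N / Q < 2))) {
    stop("Q = ", Q, " would reduce a population below 2 diploids")
  }
  m <- model
  m$pops$N <- m$pops$N / Q
  m$splits$time <- m$splits$time / Q
  m$splits$N <- m$splits$N / Q
  if (!is.null(m$pulses)) m$pulses$time <- m$pulses$time / Q
  if (!is.null(m$size_changes)) {
    m$size_changes$time <- m$size_changes$time / Q
    m$size_changes$N <- m$size_changes$N / Q
  }
  m$panels$time <- m$panels$time / Q
  m$mu <- m$mu * Q
  m$rec <- m$rec * Q
  m$Q <- m$Q * Q
  m
}

#' Named demographic model presets
#'
#' Presets are editable composites of published human/archaic histories, with
#' every value visible in this one function:
#' \describe{
#'   \item{`"A1"`}{out-of-Africa with a single Neanderthal pulse into the
#'     European recipient; African outgroup.}
#'   \item{`"A2"`}{as A1 plus an unsampled archaic-African ghost pulse into
#'     the outgroup.}
#'   \item{`"B"`}{four-population Papuan model: Denisovan donor with two
#'     pulses into the Melanesian recipient, Neanderthal as the sampled
#'     non-donor archaic, African outgroup.}
#'   \item{`"const"`}{single constant-size population (diagnostics: neutral
#'     diversity checks).}
#' }
#'
#' @param name preset name.
#' @param n_donor,n_recipient,n_outgroup diploid sample sizes for the three
#'   panels (desk-scale defaults; full-scale panels are far larger).
#' @param N diploid size for the `"const"` preset.
#' @return a [demographic_model()].
#' @export
model_preset <- function(name = c("A1", "A2", "B", "const"),
                         n_donor = 4, n_recipient = 16, n_outgroup = 16,
                         N = 10000) {
  name <- match.arg(name)
  if (name == "const") {
    return(demographic_model(
      name = "const", generation_time = 25,
      pops = data.frame(name = "pop0", N = N),
      root = "pop0",
      splits = data.frame(child = character(), parent = character(),
                          time = numeric(), N = numeric()),
      panels = data.frame(panel = "pop0", pop = "pop0", time = 0,
                          n_ind = n_recipient, role = "recipient",
                          stringsAsFactors = FALSE)
    ))
  }
  if (name %in% c("A1", "A2")) {
    pulses <- data.frame(source = "nea", dest = "eur", time = 2000,
                         frac = 0.03, stringsAsFactors = FALSE)
    splits <- data.frame(
      child = c("nea", "eur"), parent = c("afr", "afr"),
      time = c(16000, 2800), N = c(2500, 2000), stringsAsFactors = FALSE)
    pops <- data.frame(name = c("afr", "nea", "eur"),
                       N = c(10000, 2500, 2000), stringsAsFactors = FALSE)
    if (name == "A2") {
      pops <- rbind(pops, data.frame(name = "arc_afr", N = 2500))
      splits <- rbind(splits, data.frame(child = "arc_afr", parent = "afr",
                                         time = 18000, N = 2500))
      pulses <- rbind(pulses, data.frame(source = "arc_afr", dest = "afr",
                                         time = 1800, frac = 0.02))
    }
    return(demographic_model(
      name = name, generation_time = 25,
      pops = pops, root = "afr", splits = splits,
      pulses = pulses,
      panels = data.frame(
        panel = c("nea", "eur", "afr"),
        pop = c("nea", "eur", "afr"),
        time = c(2200, 0, 0),
        n_ind = c(n_donor, n_recipient, n_outgroup),
        role = c("donor", "recipient", "outgroup"),
        stringsAsFactors = FALSE)
    ))
  }
  # Model B: two Denisovan pulses into Melanesians, Neanderthal sampled but
  # not the donor.
  demographic_model(
    name = "B", generation_time = 25,
    pops = data.frame(name = c("afr", "nea", "den", "mel"),
                      N = c(10000, 2500, 2500, 2000), stringsAsFactors = FALSE),
    root = "afr",
    splits = data.frame(
      child = c("nea", "den", "mel"), parent = c("afr", "nea", "afr"),
      time = c(16000, 12000, 2400), N = c(2500, 2500, 2000),
      stringsAsFactors = FALSE),
    pulses = data.frame(
      source = c("den", "den", "nea"), dest = c("mel", "mel", "mel"),
      time = c(1600, 1200, 2000), frac = c(0.02, 0.02, 0.025),
      stringsAsFactors = FALSE),
    panels = data.frame(
      panel = c("nea", "den", "mel", "afr"),
      pop = c("nea", "den", "mel", "afr"),
      time = c(2200, 2500, 0, 0),
      n_ind = c(max(1, n_donor %/% 2), n_donor, n_recipient, n_outgroup),
      role = c("archaic", "donor", "recipient", "outgroup"),
      stringsAsFactors = FALSE)
  )
}

# --- internal helpers -------------------------------------------------------

.panel_role <- function(model, role) {
  model$panels[model$panels$role == role, , drop = FALSE]
}

# donor pulses into the recipient, in declared order
.donor_pulses <- function(model) {
  donor_pop <- .panel_role(model, "donor")$pop
  rec_pop <- .panel_role(model, "recipient")$pop
  p <- model$pulses
  p[p$source == donor_pop & p$dest == rec_pop, , drop = FALSE]
}

# split (creation) time of the population backing a role's panel
.role_creation_time <- function(model, role) {
  pop <- .panel_role(model, role)$pop
  .creation_time(model$splits, model$root, pop)
}
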