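#' Per-site panel allele frequencies
#'
#' Computes, for each segregating site, the frequency of a consistently
#' polarised allele in the outgroup (A), recipient (B) and donor (C) panels
#' (plus any additional panel). By default the polarising allele is the
#' donor-consensus allele (the allele carried by the majority of donor
#' haplotypes), since true ancestral states are generally unavailable;
#' derived-allele polarisation can be used instead when the 0/1 coding is
#' already ancestral/derived (as for simulated data).
#'
#' @param x a [simulation_result()] or [haplotype_panel()].
#' @param polarise `"derived"` (use the 0/1 coding as-is; allele 1 is
#'   derived in simulations) or `"donor"` (frequencies of the donor
#'   consensus allele).
#' @return object of class `site_frequencies`: list of per-panel frequency
#'   vectors (`A` outgroup, `B` recipient, `C` donor, plus extra panels by
#'   label) and `positions`.
#' @export
site_frequencies <- function(x, polarise = c("derived", "donor")) {
  polarise <- match.arg(polarise)
  if (inherits(x, "simulation_result")) x <- as_haplotype_panel(x)
  stopifnot(inherits(x, "haplotype_panel"))
  roles <- stats::setNames(x$panels$role, x$panels$panel)
  h <- x$haps
  pfreq <- function(p) {
    sub <- h[x$pop == p, , drop = FALSE]
    colSums(sub, na.rm = TRUE) / colSums(!is.na(sub))
  }
  freqs <- lapply(names(roles), pfreq)
  names(freqs) <- names(roles)
  donor <- names(roles)[roles == "donor"]
  if (polarise == "donor" && length(donor) == 1) {
    flip <- freqs[[donor]] < 0.5
    freqs <- lapply(freqs, function(f) ifelse(flip, 1 - f, f))
  }
  out <- list(
    A = freqs[[names(roles)[roles == "outgroup"]]],
    B = freqs[[names(roles)[roles == "recipient"]]],
    C = if (length(donor) == 1) freqs[[donor]] else NULL,
    extra = freqs[setdiff(names(roles), names(roles)[roles %in%
      c("outgroup", "recipient", "donor")])],
    n_donor_haps = if (length(donor) == 1) sum(x$pop == donor) else NA_integer_,
    positions = x$positions)
  class(out) <- "site_frequencies"
  out
}

# "= y" (typically y = 1, fixation in the donor) is tested with a tolerance
# of half a haplotype count, since panel frequencies are rational with
# denominator = number of donor haplotypes
.eq_freq <- function(f, y, n_haps) {
  tol <- if (is.finite(n_haps) && n_haps > 0) 0.5 / n_haps else 1e-9
  abs(f - y) <= tol
}

#' U statistic: count of archaic-allele-sharing sites
#'
#' Number of sites with frequency < `w` in the outgroup A, > `x` in the
#' recipient B, and equal to `y` in the donor C (to within half a haplotype
#' count). `U(1%, 20%, 100%)` counts sites nearly absent from the outgroup,
#' common in the recipient, and fixed in the donor — the classic signature
#' of introgressed haplotypes at high frequency.
#'
#' @param freqs a [site_frequencies()].
#' @param w,x,y thresholds in `[0, 1]`.
#' @return integer count.
#' @export
stat_U <- function(freqs, w = 0.01, x = 0.2, y = 1.0) {
  stopifnot(inherits(freqs, "site_frequencies"), !is.null(freqs$C))
  ok <- freqs$A < w & freqs$B > x & .eq_freq(freqs$C, y, freqs$n_donor_haps)
  sum(ok, na.rm = TRUE)
}

#' Q95 statistic: upper quantile of recipient frequencies at archaic sites
#'
#' The 95th percentile (linear interpolation between order statistics) of
#' recipient-panel frequencies over sites with outgroup frequency < `w` and
#' donor frequency equal to `y`. Returns `NA` when no site qualifies.
#'
#' @inheritParams stat_U
#' @param prob quantile level (0.95).
#' @export
stat_Q95 <- function(freqs, w = 0.01, y = 1.0, prob = 0.95) {
  stopifnot(inherits(freqs, "site_frequencies"), !is.null(freqs$C))
  ok <- freqs$A < w & .eq_freq(freqs$C, y, freqs$n_donor_haps)
  b <- freqs$B[ok & !is.na(ok)]
  if (length(b) == 0) return(NA_real_)
  unname(stats::quantile(b, prob, type = 7))
}

#' f_d statistic
#'
#' Four-taxon introgression-fraction estimator. With per-site frequencies
#' `p1` (sister of the recipient, here the unadmixed outgroup panel), `p2`
#' (recipient), `p3` (donor) and `pO` (deep outgroup, ancestral allele
#' frequency 0 when alleles are polarised ancestral/derived):
#' numerator = sum((1-p1) p2 p3 (1-pO) - p1 (1-p2) p3 (1-pO)); the
#' denominator is the same expression with p2 and p3 both replaced by
#' pD = max(p2, p3) site-wise. Returns `NA` when the denominator is 0.
#'
#' @param p1,p2,p3,pO numeric frequency vectors of equal length. `pO`
#'   defaults to 0 at every site (derived-allele polarisation).
#' @export
stat_fd <- function(p1, p2, p3, pO = 0) {
  n <- length(p1)
  stopifnot(length(p2) == n, length(p3) == n)
  if (length(pO) == 1) pO <- rep(pO, n)
  abba <- (1 - p1) * p2 * p3 * (1 - pO)
  baba <- p1 * (1 - p2) * p3 * (1 - pO)
  pD <- pmax(p2, p3)
  abbaD <- (1 - p1) * pD * pD * (1 - pO)
  babaD <- p1 * (1 - pD) * pD * (1 - pO)
  den <- sum(abbaD - babaD, na.rm = TRUE)
  if (den == 0) return(NA_real_)
  sum(abba - baba, na.rm = TRUE) / den
}

#' f_d from a site_frequencies object
#'
#' Uses the unadmixed outgroup panel as P1, the recipient as P2 and the
#' donor as P3, with the ancestral allele as the deep outgroup (`pO = 0`).
#'
#' @param freqs a [site_frequencies()] (derived polarisation recommended).
#' @export
stat_fd_panels <- function(freqs) {
  stopifnot(inherits(freqs, "site_frequencies"), !is.null(freqs$C))
  stat_fd(freqs$A, freqs$B, freqs$C, 0)
}

#' Empirical upper-tail p-value against a simulated null
#'
#' `p = (1 + #\{null >= observed\}) / (1 + #null)`.
#'
#' @param observed scalar statistic.
#' @param null_values statistic under the neutral null (non-empty).
#' @export
empirical_pvalue <- function(observed, null_values) {
  null_values <- null_values[!is.na(null_values)]
  stopifnot(length(null_values) > 0)
  (1 + sum(null_values >= observed)) / (1 + length(null_values))
}

#' Summary-statistic table for a set of windows or simulations
#'
#' @param results list of [simulation_result()]s (or haplotype panels).
#' @param w,x,y thresholds for [stat_U()] / [stat_Q95()].
#' @param polarise passed to [site_frequencies()].
#' @return data.frame with columns `U`, `Q95`, `fd` (one row per input).
#' @export
sumstat_table <- function(results, w = 0.01, x = 0.2, y = 1.0,
                          polarise = "derived") {
  rows <- lapply(results, function(r) {
    fr <- site_frequencies(r, polarise)
    data.frame(U = stat_U(fr, w, x, y), Q95 = stat_Q95(fr, w, y),
               fd = stat_fd_panels(fr))
  })
  do.call(rbind, rows)
}
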