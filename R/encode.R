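#' Haplotype panel for one genomic window
#'
#' The common input container for the encoder, built either from a
#' [simulation_result()] or from an empirical VCF window ([load_window()]).
#' Alleles are 0/1 (`NA` = missing genotype call); rows are haplotypes, with
#' consecutive rows of one individual linked by `pairing` for unphased
#' collapsing.
#'
#' @param haps 0/1/`NA` matrix, haplotypes x sites.
#' @param positions integer bp positions, ascending.
#' @param pop population (panel) label per row.
#' @param phased logical; if `FALSE`, the encoder sums minor-allele counts
#'   within individuals.
#' @param pairing integer individual index per row; must partition rows into
#'   groups (pairs for diploids) when unphased collapsing is requested.
#' @param panels data.frame with columns `panel`, `role` giving the block
#'   order and the donor/recipient/outgroup/archaic roles.
#' @export
haplotype_panel <- function(haps, positions, pop, phased = TRUE,
                            pairing = NULL, panels = NULL) {
  stopifnot(is.matrix(haps), nrow(haps) == length(pop),
            ncol(haps) == length(positions))
  if (length(positions) > 1 && is.unsorted(positions, strictly = FALSE)) {
    stop("positions must be sorted ascending")
  }
  if (is.null(pairing)) pairing <- rep(seq_len(nrow(haps) / 2), each = 2)
  stopifnot(length(pairing) == nrow(haps))
  structure(list(haps = haps, positions = positions, pop = pop,
                 phased = phased, pairing = pairing, panels = panels),
            class = "haplotype_panel")
}

#' @rdname haplotype_panel
#' @param x a [simulation_result()].
#' @export
as_haplotype_panel <- function(x, phased = TRUE) {
  stopifnot(inherits(x, "simulation_result"))
  haplotype_panel(x$haps, x$positions, x$pop, phased = phased,
                  panels = x$panels)
}

#' Polarise alleles to minor-allele coding
#'
#' Pools all individuals across panels; per site, the allele with pooled
#' frequency > 0.5 becomes 0 (major) and the other becomes 1 (minor). At a
#' pooled frequency of exactly 0.5 the major allele is chosen at random
#' (driven by R's RNG, hence deterministic under `set.seed`). Missing calls
#' stay `NA` and are excluded from frequency denominators.
#'
#' @param panel a [haplotype_panel()].
#' @return list with `haps` (minor-coded matrix) and `maf` (pooled
#'   minor-allele frequency per site).
#' @export
polarise_minor <- function(panel) {
  h <- panel$haps
  called <- colSums(!is.na(h))
  if (any(called == 0)) {
    stop("all-missing site at position ",
         panel$positions[which(called == 0)[1]])
  }
  f1 <- colSums(h, na.rm = TRUE) / called   # frequency of allele "1"
  flip <- f1 > 0.5
  ties <- f1 == 0.5
  if (any(ties)) flip[ties] <- stats::runif(sum(ties)) < 0.5
  if (any(flip)) h[, flip] <- 1L - h[, flip]
  maf <- ifelse(flip, 1 - f1, f1)
  list(haps = h, maf = as.numeric(maf))
}

#' Filter sites by minor allele frequency and drop the selected site
#'
#' Retains sites with pooled MAF strictly greater than `maf`, and removes
#' the site at `selected_pos` (if present) so the classifier never sees the
#' focal mutation itself.
#'
#' @param haps minor-coded matrix (haplotypes x sites).
#' @param positions bp positions per column.
#' @param maf per-site pooled minor allele frequencies (same length).
#' @param maf_min MAF cutoff in `[0, 0.5]`; sites with MAF <= cutoff are
#'   removed.
#' @param selected_pos optional bp position to drop.
#' @return list with filtered `haps`, `positions`, `maf`.
#' @export
filter_sites <- function(haps, positions, maf, maf_min = 0.05,
                         selected_pos = NULL) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, length(maf) == length(positions))
  keep <- maf > maf_min
  if (!is.null(selected_pos) && !is.na(selected_pos)) {
    keep <- keep & positions != selected_pos
  }
  list(haps = haps[, keep, drop = FALSE], positions = positions[keep],
       maf = maf[keep])
}

#' Bin minor-allele counts along the window
#'
#' Partitions `[window_start, window_start + window_len)` into `m` equal
#' bins and counts each haplotype's minor alleles per bin. Unlike
#' interpolation-based image resizing, no site is discarded: row sums equal
#' the haplotypes' total minor-allele counts, preserving the local density
#' of segregating sites.
#'
#' @param haps minor-coded matrix (haplotypes x sites); `NA` counts as 0.
#' @param positions bp position per column, all within the window.
#' @param window_start window start coordinate (same convention as
#'   `positions`).
#' @param window_len window length in bp.
#' @param m number of bins.
#' @return integer count matrix, haplotypes x m bins.
#' @export
bin_counts <- function(haps, positions, window_start, window_len, m) {
  stopifnot(m >= 1)
  if (length(positions) == 0) {
    return(matrix(0L, nrow(haps), m))
  }
  rel <- positions - window_start
  if (any(rel < 0 | rel >= window_len)) {
    stop("position outside window: ",
         positions[which(rel < 0 | rel >= window_len)[1]])
  }
  bin <- floor(rel * m / window_len)    # 0-based bin index
  h <- haps
  h[is.na(h)] <- 0L
  counts <- matrix(0L, nrow(h), m)
  agg <- rowsum(t(h), group = bin)      # sites x haps -> bins x haps
  counts[, as.integer(rownames(agg)) + 1L] <- t(agg)
  storage.mode(counts) <- "integer"
  counts
}

#' Collapse phased haplotype counts into unphased individual counts
#'
#' @param counts haplotypes x bins matrix from [bin_counts()].
#' @param pairing integer individual index per row; every row must belong to
#'   exactly one individual.
#' @return individuals x bins matrix (rows ordered by first occurrence).
#' @export
collapse_unphased <- function(counts, pairing) {
  stopifnot(length(pairing) == nrow(counts))
  if (anyNA(pairing)) stop("unpaired haplotype row")
  grp <- match(pairing, unique(pairing))
  out <- rowsum(counts, group = grp, reorder = FALSE)
  dimnames(out) <- NULL
  storage.mode(out) <- "integer"
  out
}

#' Order columns by similarity to the donor's mean minor-allele density
#'
#' Similarity is the Euclidean distance between a column (one haplotype or
#' individual, as per-bin counts) and the donor population's average per-bin
#' minor-allele density; smaller distance sorts first (leftmost). Ties keep
#' their input order.
#'
#' @param block bins x columns matrix (one population's submatrix).
#' @param donor_mean_density numeric vector of length `nrow(block)`.
#' @return integer column permutation.
#' @export
sort_by_donor_similarity <- function(block, donor_mean_density) {
  stopifnot(length(donor_mean_density) == nrow(block))
  d <- sqrt(colSums((block - donor_mean_density)^2))
  order(d, seq_along(d))
}

#' Resized, population-blocked, similarity-sorted input matrix
#'
#' @param mat bins x columns count matrix.
#' @param blocks named list mapping panel label to its column index range.
#' @param bin_width bin width in bp.
#' @param phased logical.
#' @export
resized_matrix <- function(mat, blocks, bin_width, phased) {
  stopifnot(all(mat >= 0))
  structure(list(mat = mat, blocks = blocks, bin_width = bin_width,
                 phased = phased),
            class = "resized_matrix")
}

#' @export
print.resized_matrix <- function(x, ...) {
  cat(sprintf("<resized_matrix> %d bins x %d columns (%s), bin width %g bp\n",
              nrow(x$mat), ncol(x$mat),
              if (x$phased) "haplotypes" else "individuals", x$bin_width))
  cat(" blocks:", paste(sprintf("%s[%d:%d]", names(x$blocks),
                                vapply(x$blocks, min, 0L),
                                vapply(x$blocks, max, 0L)), collapse = " "), "\n")
  invisible(x)
}

#' Assemble per-population count blocks into the classifier input
#'
#' Blocks are concatenated left-to-right in the order: non-donor archaic (if
#' any), donor, recipient, unadmixed outgroup. Every block is internally
#' sorted by [sort_by_donor_similarity()] against the donor block's mean
#' per-bin density.
#'
#' @param blocks named list of bins x columns matrices, one per panel.
#' @param roles named character vector mapping panel label to role.
#' @param bin_width bin width in bp.
#' @param phased logical.
#' @return a [resized_matrix()].
#' @export
assemble_input <- function(blocks, roles, bin_width, phased) {
  m <- unique(vapply(blocks, nrow, 0L))
  if (length(m) != 1) stop("blocks disagree on the number of bins")
  ord <- names(roles)[order(match(roles, c("archaic", "donor", "recipient",
                                           "outgroup")))]
  stopifnot(all(ord %in% names(blocks)))
  donor <- names(roles)[roles == "donor"]
  donor_mean <- rowMeans(blocks[[donor]])
  sorted <- lapply(blocks[ord], function(b) {
    b[, sort_by_donor_similarity(b, donor_mean), drop = FALSE]
  })
  widths <- vapply(sorted, ncol, 0L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  idx <- Map(seq, starts, ends)
  names(idx) <- ord
  resized_matrix(do.call(cbind, sorted), idx, bin_width, phased)
}

#' Encode a window into the classifier's input matrix
#'
#' Full encoding path: minor-allele polarisation, MAF filtering, dropping
#' the focal selected site, binning into `m` bins, optional unphased
#' collapsing, per-population similarity sorting and block assembly.
#'
#' @param x a [simulation_result()] or [haplotype_panel()].
#' @param m number of bins (256 reported; 32/64/128 accepted).
#' @param phased treat data as phased haplotypes (`TRUE`) or collapse to
#'   unphased individuals (`FALSE`).
#' @param maf_min pooled minor-allele-frequency cutoff.
#' @param window_start,window_len window coordinates; default the full
#'   region `[1, L]` for simulated data.
#' @param selected_pos bp position of the focal selected site to drop;
#'   defaults to the simulation result's recorded site.
#' @return a [resized_matrix()].
#' @export
encode_matrix <- function(x, m = 256, phased = TRUE, maf_min = 0.05,
                          window_start = NULL, window_len = NULL,
                          selected_pos = NULL) {
  panel <- if (inherits(x, "simulation_result")) as_haplotype_panel(x, phased)
           else x
  stopifnot(inherits(panel, "haplotype_panel"))
  if (is.null(panel$panels)) stop("panel roles unknown; cannot assemble blocks")
  if (is.null(window_start)) window_start <- 1
  if (is.null(window_len)) {
    window_len <- if (inherits(x, "simulation_result")) x$L
                  else max(panel$positions) - window_start + 1
  }
  sel <- if (!is.null(selected_pos)) selected_pos
         else if (inherits(x, "simulation_result")) x$selected_pos
         else NULL
  pol <- polarise_minor(panel)
  fl <- filter_sites(pol$haps, panel$positions, pol$maf, maf_min, sel)
  counts <- bin_counts(fl$haps, fl$positions, window_start, window_len, m)
  pops <- panel$pop
  if (!phased) {
    counts <- collapse_unphased(counts, panel$pairing)
    pops <- panel$pop[!duplicated(panel$pairing)]
  }
  labs <- unique(panel$panels$panel)
  blocks <- lapply(labs, function(p) t(counts[pops == p, , drop = FALSE]))
  names(blocks) <- labs
  roles <- stats::setNames(panel$panels$role, panel$panels$panel)[labs]
  assemble_input(blocks, roles, bin_width = window_len / m, phased = phased)
}
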