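#' Sliding genome windows
#'
#' Windows of `size` bp starting at 1, 1+step, ... (1-based inclusive
#' coordinates, matching reported genome-scan intervals); windows extending
#' past the chromosome end are omitted.
#'
#' @param chrom_length chromosome length in bp.
#' @param size window size (100 kbp).
#' @param step step between window starts (20 kbp); `size` must be a
#'   multiple of `step`.
#' @return data.frame with columns `start`, `end`.
#' @export
iter_windows <- function(chrom_length, size = 1e5, step = 2e4) {
  stopifnot(size %% step == 0)
  starts <- seq(1, by = step, length.out = max(0, floor((chrom_length - size) / step) + 1))
  starts <- starts[starts + size - 1 <= chrom_length]
  data.frame(start = starts, end = starts + size - 1)
}

#' Load one genomic window from a VCF set as a haplotype panel
#'
#' Intersects sites across the set's files within the window, applies the
#' site filters (pooled sample minor-allele frequency >= `freq_min` over
#' called alleles; fraction of missing genotype calls <= `missing_max`),
#' and returns `NULL` when fewer than `min_seg` segregating sites survive.
#'
#' @param vset a [open_vcf_set()].
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive window coordinates.
#' @param freq_min minimum pooled minor allele frequency.
#' @param missing_max maximum fraction of missing genotype calls per site.
#' @param min_seg minimum surviving segregating sites.
#' @return a [haplotype_panel()] or `NULL`.
#' @export
load_window <- function(vset, chrom, start, end, freq_min = 0.05,
                        missing_max = 0.10, min_seg = 20) {
  stopifnot(inherits(vset, "vcf_set"))
  common <- intersect_sites(vset)
  common <- common[common$chrom == chrom & common$pos >= start &
                     common$pos <= end, , drop = FALSE]
  if (nrow(common) == 0) return(NULL)
  blocks <- list()
  pop <- character(0)
  for (pn in names(vset$panels)) {
    p <- vset$panels[[pn]]
    ii <- match(paste(common$chrom, common$pos), paste(p$chrom, p$pos))
    gt <- p$gt[ii, , drop = FALSE]
    hap <- matrix(NA_integer_, nrow = 2 * ncol(gt), ncol = nrow(gt))
    for (s in seq_len(ncol(gt))) {
      hap[c(2 * s - 1, 2 * s), ] <- .parse_gt(gt[, s])
    }
    bad <- !(hap %in% c(0L, 1L, NA_integer_))
    if (any(bad)) {
      stop("malformed genotype at position ",
           common$pos[ceiling(which(bad)[1] / nrow(hap))])
    }
    blocks[[pn]] <- hap
    pop <- c(pop, rep(pn, nrow(hap)))
  }
  h <- do.call(rbind, blocks)
  called <- colSums(!is.na(h))
  miss_frac <- 1 - called / nrow(h)
  f1 <- colSums(h, na.rm = TRUE) / pmax(called, 1)
  maf <- pmin(f1, 1 - f1)
  seg <- maf > 0
  keep <- called > 0 & maf >= freq_min & miss_frac <= missing_max & seg
  if (sum(keep) < min_seg) return(NULL)
  h <- h[, keep, drop = FALSE]
  panels_df <- data.frame(panel = names(vset$panels),
                          role = unname(vset$roles),
                          stringsAsFactors = FALSE)
  haplotype_panel(h, common$pos[keep], pop, phased = vset$phased,
                  panels = panels_df)
}
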