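#' Write simulated regions to a VCF file
#'
#' Concatenates one or more simulated regions onto a synthetic chromosome
#' (region i occupies `[(i-1)*L + 1, i*L]`) and writes a diploid VCF with
#' phased genotypes. All regions must share the same panel structure; sample
#' names are `<panel>_<j>`. Alleles are written as REF=A (ancestral, 0) and
#' ALT=T (derived, 1).
#'
#' @param results a [simulation_result()] or list of them.
#' @param path output path (plain text `.vcf`).
#' @param chrom chromosome name.
#' @param panel optional panel label: write only that panel's samples
#'   (used to build per-panel VCF sets).
#' @return invisibly, a data.frame describing the window of each region
#'   (`chrom`, `start`, `end`, `scenario`).
#' @export
write_vcf <- function(results, path, chrom = "1", panel = NULL) {
  if (inherits(results, "simulation_result")) results <- list(results)
  r1 <- results[[1]]
  keep <- if (is.null(panel)) rep(TRUE, length(r1$pop)) else r1$pop == panel
  pops <- r1$pop[keep]
  ind <- rep(seq_len(sum(keep) / 2), each = 2)
  sample_names <- paste0(pops[!duplicated(ind)], "_",
                         stats::ave(ind[!duplicated(ind)],
                                    pops[!duplicated(ind)], FUN = seq_along))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", chrom,
            as.integer(r1$L * length(results))),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t")), con)
  meta <- NULL
  for (i in seq_along(results)) {
    r <- results[[i]]
    stopifnot(identical(r$pop, r1$pop), r$L == r1$L)
    off <- (i - 1) * r1$L
    h <- r$haps[keep, , drop = FALSE]
    if (ncol(h) > 0) {
      gt <- matrix(paste(h[seq(1, nrow(h), 2), , drop = FALSE],
                         h[seq(2, nrow(h), 2), , drop = FALSE], sep = "|"),
                   nrow = nrow(h) / 2)
      lines <- vapply(seq_along(r$positions), function(s) {
        paste(c(chrom, r$positions[s] + off, ".", "A", "T", ".", "PASS", ".",
                "GT", gt[, s]), collapse = "\t")
      }, "")
      writeLines(lines, con)
    }
    meta <- rbind(meta, data.frame(
      chrom = chrom, start = off + 1, end = off + r1$L,
      scenario = r$params$scenario, stringsAsFactors = FALSE))
  }
  invisible(meta)
}

#' Open a set of per-panel VCF files
#'
#' Reads each file fully into memory (desk-scale datasets) with
#' `VariantAnnotation::readVcf`, recording genotypes, positions and panel
#' roles. Multi-allelic records are dropped (with a message reporting the
#' count).
#'
#' @param files named character vector: panel label -> VCF path. Panel
#'   order defines the block order of encoded matrices.
#' @param roles named character vector: panel label -> role (`"archaic"`,
#'   `"donor"`, `"recipient"`, `"outgroup"`).
#' @param phased logical: treat genotypes as phased haplotypes.
#' @return object of class `vcf_set`.
#' @export
open_vcf_set <- function(files, roles, phased = TRUE) {
  stopifnot(length(files) >= 1, !is.null(names(files)),
            all(names(files) %in% names(roles)))
  panels <- lapply(names(files), function(pn) {
    v <- VariantAnnotation::readVcf(files[[pn]])
    alt <- VariantAnnotation::alt(v)
    multi <- S4Vectors::elementNROWS(alt) > 1
    if (any(multi)) {
      message("dropping ", sum(multi), " multi-allelic records in ", files[[pn]])
      v <- v[!multi]
    }
    rr <- SummarizedExperiment::rowRanges(v)
    gt <- VariantAnnotation::geno(v)$GT
    list(panel = pn,
         chrom = as.character(GenomicRanges::seqnames(rr)),
         pos = GenomicRanges::start(rr),
         gt = gt,
         samples = colnames(gt))
  })
  names(panels) <- names(files)
  structure(list(panels = panels,
                 roles = roles[names(files)], phased = phased),
            class = "vcf_set")
}

#' Locus-wise intersection of the VCFs in a set
#'
#' Only positions present in every file of the set are retained (the
#' standard pre-processing when panels come from separately called VCFs).
#'
#' @param vset a [open_vcf_set()].
#' @return data.frame with columns `chrom`, `pos`, sorted.
#' @export
intersect_sites <- function(vset) {
  stopifnot(inherits(vset, "vcf_set"))
  keys <- lapply(vset$panels, function(p) paste(p$chrom, p$pos))
  chroms <- lapply(vset$panels, function(p) unique(p$chrom))
  common_chrom_names <- Reduce(intersect, chroms)
  if (length(common_chrom_names) == 0 && length(unique(unlist(chroms))) > 0) {
    stop("no shared contigs; contig naming mismatch (",
         paste(unique(unlist(chroms)), collapse = ", "), ")")
  }
  common <- Reduce(intersect, keys)
  if (length(common) == 0) {
    return(data.frame(chrom = character(), pos = integer()))
  }
  parts <- strsplit(common, " ", fixed = TRUE)
  d <- data.frame(chrom = vapply(parts, `[`, "", 1),
                  pos = as.integer(vapply(parts, `[`, "", 2)),
                  stringsAsFactors = FALSE)
  d[order(d$chrom, d$pos), , drop = FALSE]
}

# parse GT strings into a 2-row (haplotype) integer matrix block
.parse_gt <- function(gt_strings) {
  sp <- strsplit(gt_strings, "[|/]")
  a1 <- suppressWarnings(as.integer(vapply(sp, `[`, "", 1)))
  a2 <- suppressWarnings(as.integer(vapply(sp, function(x) {
    if (length(x) >= 2) x[2] else x[1]   # haploid calls doubled
  }, "")))
  rbind(a1, a2)
}
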