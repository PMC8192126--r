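#' Scan a genome for adaptive introgression
#'
#' Applies the trained classifier (and optionally a calibrator) to every
#' sliding window of a VCF set. Windows rejected by [load_window()] (too
#' few segregating sites) are recorded with a reject reason and `NA`
#' scores.
#'
#' @param net a trained `introscan_cnn`.
#' @param vset a [open_vcf_set()].
#' @param chrom chromosome to scan.
#' @param chrom_length its length in bp.
#' @param calibrator optional `introscan_calibrator`.
#' @param m number of bins (must match training).
#' @param size,step window size and step in bp.
#' @param freq_min,missing_max,min_seg site/window filters
#'   ([load_window()]).
#' @return data.frame (`chrom`, `start`, `end`, `raw`, `calibrated`,
#'   `status`), sorted by position; class `window_predictions`.
#' @export
scan_genome <- function(net, vset, chrom, chrom_length, calibrator = NULL,
                        m = net$input_shape[1], size = 1e5, step = 2e4,
                        freq_min = 0.05, missing_max = 0.10, min_seg = 20) {
  wins <- iter_windows(chrom_length, size, step)
  if (nrow(wins) == 0) {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), raw = numeric(),
                      calibrated = numeric(), status = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("window_predictions", class(out))
    return(out)
  }
  out <- data.frame(chrom = rep(chrom, nrow(wins)), start = wins$start,
                    end = wins$end, raw = NA_real_, calibrated = NA_real_,
                    status = "ok", stringsAsFactors = FALSE)
  mats <- vector("list", nrow(wins))
  for (i in seq_len(nrow(wins))) {
    panel <- load_window(vset, chrom, wins$start[i], wins$end[i],
                         freq_min, missing_max, min_seg)
    if (is.null(panel)) {
      out$status[i] <- "too_few_sites"
      next
    }
    enc <- encode_matrix(panel, m = m, phased = vset$phased,
                         window_start = wins$start[i], window_len = size)
    if (any(dim(enc$mat) != net$input_shape)) {
      stop("panel size mismatch with training configuration: window ",
           wins$start[i], " encodes to ", paste(dim(enc$mat), collapse = "x"))
    }
    mats[[i]] <- enc$mat
  }
  ok <- !vapply(mats, is.null, TRUE)
  if (any(ok)) {
    arr <- array(0, c(net$input_shape, sum(ok)))
    kk <- which(ok)
    for (j in seq_along(kk)) arr[, , j] <- mats[[kk[j]]]
    p <- predict(net, arr)
    out$raw[ok] <- p
    out$calibrated[ok] <- if (is.null(calibrator)) p
                          else predict(calibrator, p)
  }
  out <- out[order(out$chrom, out$start), ]
  class(out) <- c("window_predictions", class(out))
  out
}

#' Top-ranked regions of a genome scan
#'
#' Takes the `n` highest-scoring windows (calibrated score; ties broken by
#' position for determinism) and, if `merge = TRUE`, merges overlapping or
#' adjacent windows into regions before reporting.
#'
#' @param predictions output of [scan_genome()] (or any data.frame with
#'   `chrom`, `start`, `end`, `calibrated`).
#' @param n number of windows to rank.
#' @param merge merge overlapping/adjacent windows.
#' @return data.frame (`chrom`, `start`, `end`, `score` = best window
#'   score in the region), ordered by chrom, start.
#' @export
top_regions <- function(predictions, n = 30, merge = TRUE) {
  d <- predictions[!is.na(predictions$calibrated), , drop = FALSE]
  stopifnot(nrow(d) > 0)
  o <- order(-d$calibrated, d$chrom, d$start)
  d <- d[o[seq_len(min(n, nrow(d)))], , drop = FALSE]
  d <- d[order(d$chrom, d$start), , drop = FALSE]
  if (!merge || nrow(d) == 1) {
    return(data.frame(chrom = d$chrom, start = d$start, end = d$end,
                      score = d$calibrated, stringsAsFactors = FALSE))
  }
  out <- NULL
  cur <- d[1, ]
  for (i in seq_len(nrow(d))[-1]) {
    if (d$chrom[i] == cur$chrom && d$start[i] <= cur$end + 1) {
      cur$end <- max(cur$end, d$end[i])
      cur$calibrated <- max(cur$calibrated, d$calibrated[i])
    } else {
      out <- rbind(out, cur)
      cur <- d[i, ]
    }
  }
  out <- rbind(out, cur)
  data.frame(chrom = out$chrom, start = out$start, end = out$end,
             score = out$calibrated, stringsAsFactors = FALSE)
}

#' Annotate regions with genes from a GFF3 file
#'
#' Reports genes (rows with `type == "gene"`, restricted to
#' `source == "ensembl_havana"` when that source is present) that intersect
#' each region or its `flank` bp flanking regions. Each gene is reported
#' only once, at the first region it matches.
#'
#' @param regions data.frame with `chrom`, `start`, `end`.
#' @param gff3 path to a GFF3 file.
#' @param flank flanking distance in bp.
#' @return `regions` with an added `genes` column (`;`-separated names).
#' @export
annotate_genes <- function(regions, gff3, flank = 1e5) {
  lines <- readLines(gff3)
  body <- !grepl("^#", lines) & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9)) {
    stop("malformed GFF3 line ", which(body)[which(nf != 9)[1]])
  }
  g <- rtracklayer::import(gff3)
  md <- S4Vectors::mcols(g)
  is_gene <- as.character(md$type) == "gene"
  if ("source" %in% names(md) &&
      any(as.character(md$source) == "ensembl_havana")) {
    is_gene <- is_gene & as.character(md$source) == "ensembl_havana"
  }
  g <- g[is_gene]
  md <- S4Vectors::mcols(g)
  nm <- if ("Name" %in% names(md) && !all(is.na(md$Name))) {
    as.character(md$Name)
  } else if ("ID" %in% names(md)) as.character(md$ID) else rep(NA, length(g))
  gd <- data.frame(chrom = as.character(GenomicRanges::seqnames(g)),
                   start = GenomicRanges::start(g),
                   end = GenomicRanges::end(g),
                   name = nm, stringsAsFactors = FALSE)
  seen <- character(0)
  regions$genes <- ""
  for (i in seq_len(nrow(regions))) {
    hit <- gd$chrom == regions$chrom[i] &
      gd$start <= regions$end[i] + flank &
      gd$end >= regions$start[i] - flank
    nms <- setdiff(unique(gd$name[hit]), seen)
    seen <- c(seen, nms)
    regions$genes[i] <- paste(nms, collapse = ";")
  }
  regions
}

#' Write window predictions to a TSV file
#'
#' Display coordinates are 1-based inclusive; a machine-readable half-open
#' variant (`start0`, `end0`) is included alongside.
#'
#' @param predictions output of [scan_genome()].
#' @param path output path.
#' @export
write_predictions <- function(predictions, path) {
  d <- as.data.frame(predictions)
  d$start0 <- d$start - 1
  d$end0 <- d$end
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
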