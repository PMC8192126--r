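# hand-built toy VCF writer for filter fixtures
write_toy_vcf <- function(path, chrom, pos, gts, samples) {
  lines <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=1000000>", chrom),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  for (i in seq_along(pos)) {
    lines <- c(lines, paste(c(chrom, pos[i], ".", "A", "T", ".", "PASS", ".",
                              "GT", gts[i, ]), collapse = "\t"))
  }
  writeLines(lines, path)
  path
}

test_that("iter_windows tiles the chromosome as reported", {
  w <- iter_windows(300000, 1e5, 2e4)
  expect_equal(nrow(w), 11)
  expect_equal(w$start[1], 1)
  expect_equal(w$start[11], 200001)
  expect_equal(w$end[11], 300000)
  expect_true(all(w$start %% 20000 == 1))
  expect_true(all(w$end - w$start + 1 == 1e5))
  # chromosome shorter than one window
  expect_equal(nrow(iter_windows(99999, 1e5, 2e4)), 0)
  # every base covered at most size/step times
  cover <- integer(300000)
  for (i in seq_len(nrow(w))) {
    cover[w$start[i]:w$end[i]] <- cover[w$start[i]:w$end[i]] + 1L
  }
  expect_lte(max(cover), 5)
})

test_that("intersect_sites keeps only positions present in every file", {
  d <- tempfile(); dir.create(d)
  # files share exactly 7 positions
  common <- c(10, 20, 30, 40, 50, 60, 70)
  p1 <- sort(c(common, 15, 25))
  p2 <- sort(c(common, 35))
  g1 <- matrix("0|1", length(p1), 2)
  g2 <- matrix("0|0", length(p2), 2)
  f1 <- write_toy_vcf(file.path(d, "a.vcf"), "1", p1, g1, c("a_1", "a_2"))
  f2 <- write_toy_vcf(file.path(d, "b.vcf"), "1", p2, g2, c("b_1", "b_2"))
  vset <- open_vcf_set(c(A = f1, B = f2),
                       c(A = "donor", B = "recipient"))
  sites <- intersect_sites(vset)
  expect_equal(sites$pos, common)
  # identical files: identity
  vset2 <- open_vcf_set(c(A = f1, B = f1), c(A = "donor", B = "recipient"))
  expect_equal(intersect_sites(vset2)$pos, p1)
  # contig naming mismatch is an explicit error
  f3 <- write_toy_vcf(file.path(d, "c.vcf"), "chr1", p1, g1, c("c_1", "c_2"))
  vset3 <- open_vcf_set(c(A = f1, B = f3), c(A = "donor", B = "recipient"))
  expect_error(intersect_sites(vset3), "contig")
})

test_that("load_window applies frequency, missingness and min_seg filters", {
  d <- tempfile(); dir.create(d)
  # 25 sites over 10 diploids (20 haplotypes)
  pos <- seq(1000, 25000, by = 1000)
  n_s <- 10
  gt <- matrix("0|0", 25, n_s)
  # sites 1..19: clean, MAF 0.3
  for (i in 1:19) gt[i, 1:6] <- "0|1"
  # 3 sites fail the frequency filter (singleton: MAF 0.05 < freq_min? 1/20=0.05 -> kept by >=; make 0 copies? use monomorphic)
  for (i in 20:22) gt[i, ] <- "0|0"
  # 3 sites fail missingness (3/10 genotypes missing)
  for (i in 23:25) { gt[i, 1:3] <- "./."; gt[i, 4:9] <- "0|1" }
  f <- write_toy_vcf(file.path(d, "p.vcf"), "1", pos, gt,
                     paste0("s_", 1:n_s))
  vset <- open_vcf_set(c(eur = f), c(eur = "recipient"))
  # 19 surviving sites < 20 -> NULL
  expect_null(load_window(vset, "1", 1, 100000, min_seg = 20))
  pan <- load_window(vset, "1", 1, 100000, min_seg = 19)
  expect_s3_class(pan, "haplotype_panel")
  expect_equal(ncol(pan$haps), 19)
  expect_equal(nrow(pan$haps), 20)
  # clean data with all MAF >= 5%: all sites retained
  pan2 <- load_window(vset, "1", 1, 100000, min_seg = 1)
  expect_equal(length(pan2$positions), 19)
})

test_that("an 11% missing site is removed at the 10% threshold", {
  d <- tempfile(); dir.create(d)
  gt <- matrix("0|1", 2, 9)
  gt[2, 1] <- "./."       # 1/9 = 11% missing
  f <- write_toy_vcf(file.path(d, "m.vcf"), "1", c(100, 200), gt,
                     paste0("s_", 1:9))
  vset <- open_vcf_set(c(p = f), c(p = "recipient"))
  pan <- load_window(vset, "1", 1, 1000, min_seg = 1)
  expect_equal(pan$positions, 100)
})

test_that("simulation -> VCF -> load_window -> encode round-trips exactly", {
  fx <- get_fixtures()
  r <- fx$results[fx$scenarios == "ai"][[1]]
  d <- tempfile(); dir.create(d)
  files <- c(nea = file.path(d, "nea.vcf"), eur = file.path(d, "eur.vcf"),
             afr = file.path(d, "afr.vcf"))
  for (pn in names(files)) write_vcf(r, files[[pn]], panel = pn)
  vset <- open_vcf_set(files, c(nea = "donor", eur = "recipient",
                                afr = "outgroup"))
  pan <- load_window(vset, "1", 1, r$L, freq_min = 0, min_seg = 1)
  # site-for-site equality of the untruncated panel
  expect_equal(pan$positions, r$positions)
  # rows arrive grouped by panel in block order; regroup to compare
  expect_equal(pan$haps[order(match(pan$pop, unique(r$pop))), ],
               unname(r$haps[order(match(r$pop, unique(r$pop))), ]))
  # full encoding path equality (same polarisation RNG state)
  set.seed(7)
  direct <- encode_matrix(r, m = 32)
  set.seed(7)
  via_vcf <- encode_matrix(pan, m = 32, window_start = 1, window_len = r$L,
                           selected_pos = r$selected_pos)
  expect_equal(via_vcf$mat, direct$mat)
  expect_equal(via_vcf$blocks, direct$blocks)
})
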