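test_that("top_regions merges adjacent windows into intervals", {
  pred <- data.frame(
    chrom = "2",
    start = c(160160001, 160180001, 165000001),
    end = c(160160001, 160180001, 165000001) + 1e5 - 1,
    calibrated = c(0.9, 0.95, 0.5))
  top <- top_regions(pred, n = 2)
  expect_equal(nrow(top), 1)
  expect_equal(top$start, 160160001)
  expect_equal(top$end, 160280000)
  # n larger than the table returns everything
  top3 <- top_regions(pred, n = 10)
  expect_equal(nrow(top3), 2)
  # no merging when disabled
  expect_equal(nrow(top_regions(pred, n = 2, merge = FALSE)), 2)
})

test_that("top_regions ranks by calibrated score with positional ties", {
  pred <- data.frame(
    chrom = "1", start = c(1, 1e6, 2e6), end = c(1, 1e6, 2e6) + 99999,
    calibrated = c(0.2, 0.8, NA))
  top <- top_regions(pred, n = 1)
  expect_equal(top$start, 1e6)
})

test_that("annotate_genes respects the flanking rule and dedupes", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    paste("1", "ensembl_havana", "gene", 250000, 260000, ".", "+", ".",
          "ID=gene:g1;Name=NEAR", sep = "\t"),
    paste("1", "ensembl_havana", "gene", 450000, 460000, ".", "+", ".",
          "ID=gene:g2;Name=FAR", sep = "\t"),
    paste("1", "havana", "gene", 150000, 155000, ".", "+", ".",
          "ID=gene:g3;Name=OTHERSRC", sep = "\t"),
    paste("1", "ensembl_havana", "gene", 95000, 105000, ".", "+", ".",
          "ID=gene:g4;Name=SPAN", sep = "\t")), gff)
  regions <- data.frame(chrom = "1", start = c(1, 100001),
                        end = c(100000, 200000))
  ann <- annotate_genes(regions, gff, flank = 1e5)
  # NEAR is 50 kb downstream of region 2 (within flank); FAR is 250 kb away
  expect_true(grepl("NEAR", ann$genes[2]))
  expect_false(any(grepl("FAR", ann$genes)))
  # non-ensembl_havana source excluded
  expect_false(any(grepl("OTHERSRC", ann$genes)))
  # SPAN overlaps both regions but is reported once
  expect_equal(sum(grepl("SPAN", ann$genes)), 1)
  expect_true(grepl("SPAN", ann$genes[1]))
})

test_that("malformed GFF3 lines are rejected with their line number", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "1\tensembl_havana\tgene\t100\t200",   # 5 fields
               ""), gff)
  expect_error(annotate_genes(data.frame(chrom = "1", start = 1, end = 10),
                              gff), "line 2")
})

test_that("scan_genome scores windows and round-trips with predict", {
  fx <- get_fixtures()
  set.seed(1234)
  net <- build_model(model_config(m = fx$m, k = 2, filters = 4),
                     dim(fx$matrices[[1]]$mat))
  # genome of three fixture regions; middle one is AI
  regions <- list(fx$results[fx$scenarios == "neutral"][[1]],
                  fx$results[fx$scenarios == "ai"][[1]],
                  fx$results[fx$scenarios == "neutral"][[2]])
  d <- tempfile(); dir.create(d)
  files <- c(nea = file.path(d, "nea.vcf"), eur = file.path(d, "eur.vcf"),
             afr = file.path(d, "afr.vcf"))
  for (pn in names(files)) write_vcf(regions, files[[pn]], panel = pn)
  vset <- open_vcf_set(files, c(nea = "donor", eur = "recipient",
                                afr = "outgroup"))
  pred <- scan_genome(net, vset, "1", 3e5, min_seg = 5)
  expect_s3_class(pred, "window_predictions")
  expect_equal(nrow(pred), 11)
  expect_true(all(diff(pred$start) > 0))        # sorted by position
  ok <- pred$status == "ok"
  expect_true(all(pred$raw[ok] >= 0 & pred$raw[ok] <= 1))
  # the aligned middle window equals direct prediction on its encoding
  w2 <- which(pred$start == 100001)
  pan <- load_window(vset, "1", 100001, 200000, min_seg = 5)
  set.seed(99)
  enc <- encode_matrix(pan, m = fx$m, window_start = 100001,
                       window_len = 1e5)
  # polarisation has no ties here in expectation; compare predictions
  expect_equal(pred$raw[w2], predict(net, enc$mat), tolerance = 1e-9)
  # calibrated ranking equals raw ranking under a monotone calibrator
  set.seed(41)
  raw <- pred$raw[ok]
  y <- as.integer(seq_along(raw) %% 2 == 0)
  cal <- fit_calibrator("beta", raw, y)
  pred2 <- scan_genome(net, vset, "1", 3e5, calibrator = cal, min_seg = 5)
  ok2 <- pred2$status == "ok"
  # monotone calibration: calibrated scores are non-decreasing in raw order
  expect_true(all(diff(pred2$calibrated[ok2][order(pred2$raw[ok2])]) >= -1e-12))
  # empty chromosome gives an empty table
  expect_equal(nrow(scan_genome(net, vset, "1", 5e4)), 0)
})

test_that("write_predictions emits both coordinate conventions", {
  pred <- data.frame(chrom = "1", start = 1, end = 100000,
                     raw = 0.5, calibrated = 0.4, status = "ok")
  f <- tempfile(fileext = ".tsv")
  write_predictions(pred, f)
  d <- read.delim(f)
  expect_equal(d$start0, 0)
  expect_equal(d$end0, 100000)
})
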