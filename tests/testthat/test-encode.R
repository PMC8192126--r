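test_that("polarise_minor encodes pooled-major alleles as 0", {
  # 4 haplotypes: site 1 has alt freq 0.75 -> coded allele flips
  h <- matrix(c(1, 1, 1, 0,
                0, 0, 0, 0,
                1, 0, 0, 0), nrow = 4)
  pan <- haplotype_panel(h, c(10L, 20L, 30L), rep("p", 4),
                         panels = data.frame(panel = "p", role = "recipient"))
  pol <- polarise_minor(pan)
  expect_equal(pol$haps[, 1], c(0, 0, 0, 1))   # alt was major -> flipped
  expect_equal(pol$maf[1], 0.25)
  expect_equal(pol$haps[, 2], rep(0, 4))       # monomorphic -> all zeros
  expect_equal(pol$haps[, 3], c(1, 0, 0, 0))   # minor already 1
})

test_that("polarisation ties are resolved by seed, deterministically", {
  h <- matrix(c(1, 1, 0, 0), nrow = 4)         # exact 0.5
  pan <- haplotype_panel(h, 5L, rep("p", 4),
                         panels = data.frame(panel = "p", role = "recipient"))
  draws <- vapply(1:20, function(s) {
    set.seed(s)
    polarise_minor(pan)$haps[1, 1]
  }, 0)
  expect_setequal(unique(draws), c(0, 1))      # both polarisations occur
  set.seed(11)
  a <- polarise_minor(pan)$haps
  set.seed(11)
  b <- polarise_minor(pan)$haps
  expect_identical(a, b)
})

test_that("all-missing sites are an error", {
  h <- matrix(NA_integer_, 2, 1)
  pan <- haplotype_panel(h, 7L, c("p", "p"),
                         panels = data.frame(panel = "p", role = "recipient"))
  expect_error(polarise_minor(pan), "all-missing site at position 7")
})

test_that("filter_sites applies the MAF rule and drops the selected site", {
  h <- matrix(0L, 2, 3)
  fl <- filter_sites(h, c(10L, 20L, 30L), c(0.02, 0.10, 0.50), 0.05)
  expect_equal(fl$positions, c(20L, 30L))
  # selected_pos absent leaves the matrix unchanged by that clause
  fl2 <- filter_sites(h, c(10L, 20L, 30L), c(0.1, 0.1, 0.1), 0.05,
                      selected_pos = 999L)
  expect_equal(fl2$positions, c(10L, 20L, 30L))
  fl3 <- filter_sites(h, c(10L, 20L, 30L), c(0.1, 0.1, 0.1), 0.05,
                      selected_pos = 20L)
  expect_equal(fl3$positions, c(10L, 30L))
  # maf_min = 0 removes only invariant sites
  fl4 <- filter_sites(h, c(10L, 20L, 30L), c(0, 0.01, 0.5), 0)
  expect_equal(fl4$positions, c(20L, 30L))
})

test_that("bin_counts matches hand counts and the brute-force oracle", {
  h <- matrix(1L, 1, 3)
  expect_equal(bin_counts(h, c(10, 45, 90), 0, 100, 2),
               matrix(c(2L, 1L), 1))
  # no segregating sites -> all-zero matrix
  expect_equal(bin_counts(matrix(0L, 3, 0), integer(0), 0, 100, 4),
               matrix(0L, 3, 4))
  # positions outside the window are an error
  expect_error(bin_counts(h, c(10, 45, 100), 0, 100, 2), "outside window")
  # oracle equivalence on >= 100 random fixtures
  set.seed(21)
  for (i in 1:100) {
    f <- random_site_matrix(nhap = sample(2:10, 1), nsite = sample(1:30, 1),
                            L = 100)
    m <- sample(1:16, 1)
    got <- bin_counts(f$haps, f$positions, 1, f$L, m)
    want <- brute_bin_counts(f$haps, f$positions, 1, f$L, m)
    expect_identical(got, want)
    # row sums preserved (no sites discarded)
    expect_equal(rowSums(got), rowSums(f$haps))
  }
})

test_that("one-site-per-bin binning reproduces the unbinned matrix", {
  set.seed(22)
  f <- random_site_matrix(nhap = 5, nsite = 6, L = 60)
  # bins aligned so each site falls in a distinct bin
  got <- bin_counts(f$haps, f$positions, 1, f$L, 60)
  expect_equal(rowSums(got), rowSums(f$haps))
  expect_true(all(got %in% 0:1))
})

test_that("collapse_unphased sums chromosome rows per individual", {
  cnt <- rbind(c(2L, 1L), c(0L, 3L))
  expect_equal(collapse_unphased(cnt, c(1, 1)), matrix(c(2L, 4L), 1))
  # haploid pairing is the identity
  expect_equal(collapse_unphased(cnt, c(1, 2)), cnt)
  expect_error(collapse_unphased(cnt, c(1, NA)), "unpaired")
  # diploid entries bounded by twice the per-bin site count
  set.seed(23)
  f <- random_site_matrix(8, 20, 100)
  b <- bin_counts(f$haps, f$positions, 1, 100, 5)
  cl <- collapse_unphased(b, rep(1:4, each = 2))
  expect_true(all(cl <= 2 * max(b)))
  expect_equal(sum(cl), sum(b))
})

test_that("sort_by_donor_similarity orders by distance, stably", {
  block <- cbind(A = c(2, 0), B = c(0, 2))
  expect_equal(sort_by_donor_similarity(block, c(2, 0)), c(1, 2))
  expect_equal(sort_by_donor_similarity(block, c(0, 2)), c(2, 1))
  # identical columns keep input order
  same <- matrix(1, 3, 4)
  expect_equal(sort_by_donor_similarity(same, c(9, 9, 9)), 1:4)
  # brute-force oracle: permutation is distance-ascending
  set.seed(24)
  for (i in 1:100) {
    b <- matrix(rpois(6 * 5, 2), 6, 5)
    mu <- rowMeans(b)
    perm <- sort_by_donor_similarity(b, mu)
    d <- sqrt(colSums((b - mu)^2))
    expect_true(all(diff(d[perm]) >= -1e-12))
  }
})

test_that("assemble_input orders blocks archaic | donor | recipient | outgroup", {
  m <- 4
  blocks <- list(afr = matrix(1, m, 3), nea = matrix(2, m, 2),
                 eur = matrix(3, m, 3))
  roles <- c(afr = "outgroup", nea = "donor", eur = "recipient")
  rm_ <- assemble_input(blocks, roles, 10, TRUE)
  expect_equal(names(rm_$blocks), c("nea", "eur", "afr"))
  expect_equal(rm_$blocks$nea, 1:2)
  expect_equal(rm_$blocks$afr, 6:8)
  # non-donor archaic goes left of the donor
  blocks$den <- matrix(4, m, 2)
  roles <- c(roles, den = "donor")
  roles["nea"] <- "archaic"
  rm2 <- assemble_input(blocks, roles, 10, TRUE)
  expect_equal(names(rm2$blocks), c("nea", "den", "eur", "afr"))
  expect_error(assemble_input(list(a = matrix(1, 3, 2), b = matrix(1, 4, 2)),
                              c(a = "donor", b = "recipient"), 10, TRUE),
               "disagree")
})

test_that("encoding conserves total minor-allele counts", {
  fx <- get_fixtures()
  for (i in seq_along(fx$results)) {
    r <- fx$results[[i]]
    set.seed(1000 + i)
    pol <- polarise_minor(as_haplotype_panel(r))
    fl <- filter_sites(pol$haps, r$positions, pol$maf, 0.05, r$selected_pos)
    set.seed(1000 + i)
    enc <- encode_matrix(r, m = fx$m)
    expect_identical(sum(enc$mat), sum(fl$haps))
  }
})

test_that("encoding is invariant to within-population input order", {
  fx <- get_fixtures()
  r <- fx$results[[1]]
  set.seed(31)
  enc1 <- encode_matrix(r, m = 32)
  # permute haplotype pairs within each population
  perm <- unlist(lapply(unique(r$pop), function(p) {
    ii <- which(r$pop == p)
    pairs <- split(ii, rep(seq_len(length(ii) / 2), each = 2))
    unlist(sample(pairs))
  }))
  r2 <- r
  r2$haps <- r$haps[perm, ]
  r2$pop <- r$pop[perm]
  set.seed(31)
  enc2 <- encode_matrix(r2, m = 32)
  # identical up to stable tie-breaking: same column multiset per block and
  # the same sorted distance profile against the donor mean
  for (b in names(enc1$blocks)) {
    b1 <- enc1$mat[, enc1$blocks[[b]], drop = FALSE]
    b2 <- enc2$mat[, enc2$blocks[[b]], drop = FALSE]
    expect_equal(b1[, order(apply(b1, 2, paste, collapse = ","))],
                 b2[, order(apply(b2, 2, paste, collapse = ","))])
  }
  mu <- rowMeans(enc1$mat[, enc1$blocks$nea, drop = FALSE])
  d1 <- sqrt(colSums((enc1$mat - mu)^2))
  d2 <- sqrt(colSums((enc2$mat - mu)^2))
  expect_equal(d1, d2)
})

test_that("matrix entries fit in 8 bits at reporting scale", {
  fx <- get_fixtures()
  for (mt in fx$matrices) expect_lt(max(mt$mat), 256)
})

test_that("unphased encoding halves the recipient/outgroup columns", {
  fx <- get_fixtures()
  r <- fx$results[[1]]
  set.seed(41); e_ph <- encode_matrix(r, m = 32, phased = TRUE)
  set.seed(41); e_un <- encode_matrix(r, m = 32, phased = FALSE)
  expect_equal(ncol(e_un$mat), ncol(e_ph$mat) / 2)
  expect_identical(sum(e_un$mat), sum(e_ph$mat))
})
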