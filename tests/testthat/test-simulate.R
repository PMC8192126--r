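test_that("scale_model preserves theta, rho and Ns exactly", {
  m <- model_preset("A1")
  s <- scale_model(m, 10)
  expect_equal(s$pops$N[1], 1000)                    # 10000 / 10
  expect_equal(s$splits$time[s$splits$child == "eur"], 280)
  expect_equal(s$mu, 1.29e-7)
  # Q = 1 identity
  expect_identical(scale_model(m, 1), m)
  # invariance across random Q, 1e-9 relative
  set.seed(1)
  for (Q in c(2, 5, 10, 13.7, 20)) {
    sq <- scale_model(m, Q)
    expect_equal(4 * sq$pops$N * sq$mu, 4 * m$pops$N * m$mu,
                 tolerance = 1e-9)
    expect_equal(4 * sq$pops$N * sq$rec, 4 * m$pops$N * m$rec,
                 tolerance = 1e-9)
    s_unscaled <- 0.02
    expect_equal(sq$pops$N * (s_unscaled * sq$Q), m$pops$N * s_unscaled,
                 tolerance = 1e-9)
  }
  # direct rho arithmetic: 4*1000*1e-7 == 4*10000*1e-8
  s10 <- scale_model(m, 10)
  expect_equal(4 * (10000 / 10) * (1e-8 * 10), 4 * 10000 * 1e-8)
  expect_error(scale_model(m, 1e5), "below 2 diploids")
})

test_that("draw_selection_params respects scenario constraints", {
  m <- model_preset("A1")
  kya <- 1000 / m$generation_time
  set.seed(2)
  ps <- draw_selection_params("sweep", m, c(1e-4, 0.1), n = 200)
  for (p in ps) {
    expect_lte(p$T_sel, p$T_mut)
    expect_gte(p$T_sel, kya)
    expect_lt(p$T_mut, 2800)           # recipient/outgroup split
  }
  pa <- draw_selection_params("ai", m, c(1e-3, 0.1), n = 200)
  for (p in pa) {
    expect_gte(p$s, 1e-3)
    expect_gt(p$T_mut, 2000 + kya)     # pulse + 1 kya
    expect_lt(p$T_mut, 16000)          # donor creation
    expect_lt(p$T_sel, 2000)
    expect_gte(p$T_sel, kya)
  }
})

test_that("selection coefficients are log-uniform (KS test)", {
  m <- model_preset("A1")
  set.seed(3)
  ps <- draw_selection_params("sweep", m, c(1e-4, 0.1), n = 10000)
  ls <- log10(vapply(ps, function(p) p$s, 0))
  ks <- suppressWarnings(ks.test(ls, "punif", -4, -1))
  expect_gt(ks$p.value, 0.01)
})

test_that("model B AI draws balance the two donor pulses", {
  m <- model_preset("B")
  set.seed(4)
  ps <- draw_selection_params("ai", m, c(1e-3, 0.1), n = 100)
  pulses <- vapply(ps, function(p) p$pulse, 0L)
  expect_setequal(unique(pulses), c(1L, 2L))
  expect_equal(sum(pulses == 1), 50)
})

test_that("DFE draws match the configured mixture", {
  cfg <- dfe_config()
  expect_equal(cfg$h, 0.5 / (1 - 7071.07 * -0.01314833))
  set.seed(5)
  d <- draw_dfe_mutation(cfg, 1e5)
  frac_del <- mean(d$class == "deleterious")
  se <- sqrt(0.7 * 0.3 / 1e5)
  expect_lt(abs(frac_del - 0.7), 3 * se)
  sdel <- d$s[d$class == "deleterious"]
  expect_true(all(sdel < 0))
  se_mean <- sd(sdel) / sqrt(length(sdel))
  expect_lt(abs(mean(sdel) - -0.01314833), 3 * se_mean)
  expect_equal(length(unique(d$h[d$class == "deleterious"])), 1)
  expect_true(all(d$s[d$class == "neutral"] == 0))
})

test_that("neutral regions have no selected site and reproduce per seed", {
  m <- model_preset("A1", n_donor = 2, n_recipient = 4, n_outgroup = 4)
  r1 <- simulate_region(m, "neutral", seed = 99, Q = 50)
  r2 <- simulate_region(m, "neutral", seed = 99, Q = 50)
  expect_true(is.na(r1$selected_pos))
  expect_identical(r1$haps, r2$haps)
  expect_identical(r1$positions, r2$positions)
  r3 <- simulate_region(m, "neutral", seed = 100, Q = 50)
  expect_false(identical(r1$haps, r3$haps))
  # positions strictly increasing within [1, L]
  expect_true(all(diff(r1$positions) > 0))
  expect_true(all(r1$positions >= 1 & r1$positions <= r1$L))
  # every sample assigned to one declared panel
  expect_setequal(unique(r1$pop), m$panels$panel)
})

test_that("rejection sampling conditions on the beneficial allele", {
  fx <- get_fixtures()
  sel <- fx$results[fx$scenarios %in% c("sweep", "ai")]
  for (r in sel) {
    expect_gte(r$params$final_af, 0.25)      # fixture af_cutoff
    # beneficial allele present in the recipient sample (never lost)
    expect_gt(r$params$final_af, 0)
  }
  ai <- fx$results[fx$scenarios == "ai"][[1]]
  expect_false(is.na(ai$selected_pos))
})

test_that("post_filter_af keeps neutral results and filters by frequency", {
  fake <- function(scen, af) {
    structure(list(params = list(scenario = scen, final_af = af)),
              class = "simulation_result")
  }
  rs <- list(fake("ai", 0.30), fake("ai", 0.10), fake("neutral", NA),
             fake("sweep", 0.26), fake("sweep", 0.24))
  out <- post_filter_af(rs, 0.25)
  expect_length(out, 3)
  expect_identical(out[[1]]$params$final_af, 0.30)
  # order-preserving and idempotent
  expect_identical(post_filter_af(out, 0.25), out)
  # vacuous filter is the identity
  expect_identical(post_filter_af(rs, 0), rs)
})

test_that("neutral diversity matches the coalescent expectation 4*N*mu", {
  m <- model_preset("const", N = 100, n_recipient = 8)
  set.seed(6)
  pis <- vapply(1:120, function(i) {
    pairwise_diversity(simulate_region(m, "neutral",
                                       seed = sample.int(1e9, 1)))
  }, 0)
  expected <- 4 * 100 * 1.29e-8
  # within Monte-Carlo error of the coalescent expectation
  se <- sd(pis) / sqrt(length(pis))
  expect_lt(abs(mean(pis) - expected), 4 * se)
})

test_that("impossible parameter draws fail explicitly", {
  m <- model_preset("A1", n_donor = 2, n_recipient = 4, n_outgroup = 4)
  # a strongly deleterious 'beneficial' allele cannot reach the condition
  p <- selection_params("sweep", s = 1e-4, T_mut = 50, T_sel = 45)
  expect_error(
    simulate_region(m, p, seed = 1, Q = 50, min_freq = 0.9,
                    max_attempts = 3),
    class = "introscan_sim_failure")
})

test_that("genetic map chunks parse and drive the simulator", {
  map_txt <- c("Chromosome Position(bp) Rate(cM/Mb) Map(cM)",
               paste("chr1", seq(0, 3e6, by = 5e5),
                     c(0.5, 2, 0.1, 4, 1, 3, 0.2), 0))
  f <- tempfile(fileext = ".txt")
  writeLines(map_txt, f)
  gm <- read_genetic_map(f)
  expect_named(gm, c("chrom", "pos", "rate"))
  set.seed(7)
  ch <- sample_map_chunk(gm, 1e5)
  expect_s3_class(ch, "genetic_map_chunk")
  expect_equal(ch$start[1], 0)
  expect_equal(ch$end[nrow(ch)], 1e5)
  expect_true(all(ch$end > ch$start))
  m <- model_preset("const", N = 50, n_recipient = 4)
  r <- simulate_region(m, "neutral", seed = 3, map = ch)
  expect_s3_class(r, "simulation_result")
})
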