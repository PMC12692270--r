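# Per-gene driver statistics: impact scores, permutation and recurrence
# tests, background rate, FDR.

test_that("combined_impact follows the stated combination rules", {
  v <- make_variants(
    sample_id = sprintf("S%d", 1:6),
    gene = "G",
    consequence = c("missense", "missense", "nonsense", "missense", "splice_site", "other"),
    sift = c(0, 1, NA, 0.2, NA, NA),
    polyphen = c(1, 0, NA, NA, NA, NA))
  expect_equal(combined_impact(v),
               c(1,     # sift=0, polyphen=1: both maximally damaging
                 0,     # sift=1, polyphen=0: both benign
                 1,     # unscored nonsense: presumed LoF
                 0.8,   # only sift present: 1 - 0.2
                 1,     # unscored splice site
                 0.5))  # unscored other: uninformative
  expect_error(combined_impact(make_variants("S1", "G", consequence = "synonymous")),
               class = "splitsig_usage_error")
})

test_that("impact bias p is 1 when every impact in the cohort is identical", {
  sheet <- make_sheet(3, 3)
  v <- make_impact_variants(sample_id = c("M01", "M02", "N01", "N02", "M03", "N03"),
                            gene = c("G1", "G1", "B1", "B2", "B3", "B4"),
                            impact = 0.5, sheet = sheet)
  res <- impact_bias_test(v, "G1", driver_config(n_null_draws = 200, seed = 1))
  expect_equal(res$p, 1)
  expect_equal(res$statistic, 0.5)
})

test_that("impact bias achieves the add-one floor when observed beats every draw", {
  # gene with two impact-1.0 variants against a pool of eight zeros:
  # every possible draw has mean 0 < 1, so p = 1/(1 + N); exhaustive
  # enumeration over all C(8,2) draws confirms no null mean can reach 1
  sheet <- make_sheet(5, 5)
  ids <- sheet$sample_id
  v <- dplyr::bind_rows(
    make_impact_variants(ids[1:2], "HOT", impact = 1, sheet = sheet),
    make_impact_variants(ids[c(3:10, 1)][1:8], paste0("BG", 1:8), impact = 0, sheet = sheet))
  n_draws <- 500
  res <- impact_bias_test(v, "HOT", driver_config(n_null_draws = n_draws, seed = 3))
  expect_equal(res$p, 1 / (1 + n_draws))

  pool <- rep(0, 8)
  exhaustive_means <- combn(8, 2, function(i) mean(pool[i]))
  expect_true(all(exhaustive_means < res$statistic))
})

test_that("impact bias Monte-Carlo p matches exhaustive draw enumeration on small pools", {
  # pools of <= 10 background variants, k <= 3: enumerate all C(n, k) draws
  # and compare the exact tail (with the same >= tie rule) to the add-one MC p
  sheet <- make_sheet(6, 6)
  ids <- sheet$sample_id
  set.seed(99)
  cases <- list(list(k = 2, pool = round(runif(8), 2)),
                list(k = 3, pool = round(runif(10), 2)),
                list(k = 2, pool = c(0.1, 0.4, 0.4, 0.9, 0.7, 0.2, 0.55)))
  n_draws <- 20000
  for (cs in cases) {
    gene_imp <- c(0.9, 0.6, 0.8)[seq_len(cs$k)]
    v <- dplyr::bind_rows(
      make_impact_variants(ids[seq_len(cs$k)], "TARGET", impact = gene_imp, sheet = sheet),
      make_impact_variants(rep(ids, length.out = length(cs$pool)),
                           paste0("BG", seq_along(cs$pool)),
                           impact = cs$pool, sheet = sheet))
    res <- impact_bias_test(v, "TARGET",
                            driver_config(n_null_draws = n_draws, seed = 17))
    exact_means <- combn(length(cs$pool), cs$k, function(i) mean(cs$pool[i]))
    exact_p <- mean(exact_means >= res$statistic)
    expect_lt(abs(res$p - exact_p), 2 / sqrt(n_draws) + 1 / n_draws)
  }
})

test_that("impact bias is invariant to the row order of the input", {
  sheet <- make_sheet(5, 5)
  set.seed(5)
  v <- make_impact_variants(sample(sheet$sample_id, 30, replace = TRUE),
                            gene = sample(c("G1", "G2", "G3", "G4"), 30, replace = TRUE),
                            impact = round(runif(30), 3),
                            genomic_pos = sample.int(1e6, 30), sheet = sheet)
  cfg <- driver_config(n_null_draws = 300, seed = 11)
  ref <- impact_bias_test(v, "G1", cfg)
  shuffled <- v[sample.int(nrow(v)), ]
  expect_equal(impact_bias_test(shuffled, "G1", cfg), ref)
})

test_that("adding a maximally damaging variant never worsens the impact-bias p", {
  sheet <- make_sheet(5, 5)
  set.seed(21)
  v <- make_impact_variants(sample(sheet$sample_id, 40, replace = TRUE),
                            gene = sample(paste0("G", 1:5), 40, replace = TRUE),
                            impact = round(runif(40), 3), sheet = sheet)
  cfg <- driver_config(n_null_draws = 2000, seed = 2)
  before <- impact_bias_test(v, "G1", cfg)
  extra <- make_impact_variants("M01", "G1", impact = 1, sheet = sheet)
  after <- impact_bias_test(dplyr::bind_rows(v, extra), "G1", cfg)
  expect_lte(after$p, before$p + 2 / sqrt(cfg$n_null_draws))
})

test_that("recurrence test matches an independent exact binomial-tail oracle", {
  sheet <- make_sheet(5, 5)
  model <- tibble::tibble(gene = "G", coding_length_bp = 1000L,
                          protein_length_aa = 333L)
  v <- make_impact_variants(c("M01", "M02", "N01"), "G", impact = 0.5, sheet = sheet)
  res <- recurrence_test(v, "G", model, background_rate = 1e-4, n_samples = 10)
  oracle <- binom_upper_tail_oracle(3, 10 * 1000, 1e-4)
  expect_equal(res$n_variants, 3)
  expect_lt(abs(res$p - oracle) / oracle, 1e-12)

  # randomised configurations, n*L <= 1e5
  set.seed(31)
  for (i in 1:10) {
    L <- sample(100:5000, 1)
    n <- sample(2:20, 1)
    while (n * L > 1e5) n <- max(2, n %/% 2)
    rate <- runif(1, 1e-6, 1e-3)
    k <- sample(1:6, 1)
    m <- tibble::tibble(gene = "G", coding_length_bp = L, protein_length_aa = 10L)
    vv <- make_impact_variants(rep("M01", k), "G", impact = 0.5, sheet = sheet)
    got <- recurrence_test(vv, "G", m, rate, n)$p
    want <- binom_upper_tail_oracle(k, n * L, rate)
    expect_lt(abs(got - want) / want, 1e-12)
  }
})

test_that("recurrence test closed forms: k = 0, saturated counts, degenerate rate", {
  sheet <- make_sheet(1, 1)
  m <- tibble::tibble(gene = "G", coding_length_bp = 1L, protein_length_aa = 1L)
  none <- make_impact_variants(character(), "G", impact = numeric(), sheet = sheet)
  expect_equal(recurrence_test(none, "G", m, 1e-4, 10)$p, 1)

  # every base of every sample mutated: p = rate^(n*L); n*L = 2, rate = 0.5
  both <- make_impact_variants(c("M01", "N01"), "G", impact = 0.5, sheet = sheet)
  expect_equal(recurrence_test(both, "G", m, 0.5, 2)$p, 0.25)

  expect_error(recurrence_test(both, "G", m, 0, 2),
               class = "splitsig_usage_error")
})

test_that("background rate estimation is the stated arithmetic", {
  sheet <- make_sheet(5, 5)
  models <- tibble::tibble(gene = c("G1", "G2"),
                           coding_length_bp = c(1500000L, 500000L),
                           protein_length_aa = c(10L, 10L))
  v <- make_impact_variants(rep(sheet$sample_id, 2), rep(c("G1", "G2"), each = 10),
                            impact = 0.5, sheet = sheet)
  # 20 variants / (10 samples * 2 Mb)
  expect_equal(estimate_background_rate(v, models, 10), 1e-6)
  # empty exclusion is a no-op
  expect_equal(estimate_background_rate(v, models, 10, exclude = character()),
               estimate_background_rate(v, models, 10))
  # excluding the only mutated genes leaves rate 0 over the remaining length
  models2 <- dplyr::bind_rows(models,
                              tibble::tibble(gene = "G3", coding_length_bp = 1000L,
                                             protein_length_aa = 10L))
  expect_equal(estimate_background_rate(v, models2, 10, exclude = c("G1", "G2")), 0)
  expect_error(estimate_background_rate(v, models, 10, exclude = c("G1", "G2")),
               class = "splitsig_usage_error")
})

test_that("bh_fdr equals the brute-force step-up definition", {
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.3, 5)), rep(0.3, 5))
  expect_error(bh_fdr(c(0.5, 0)), class = "splitsig_range_error")
  expect_error(bh_fdr(c(0.5, 1.2)), class = "splitsig_range_error")

  set.seed(77)
  for (i in 1:1000) {
    p <- runif(sample(1:12, 1))
    expect_equal(bh_fdr(p), bh_oracle(p))
  }
})

test_that("driver scan computes q across tested genes and respects subtype partition", {
  sheet <- make_sheet(5, 5)
  set.seed(13)
  v <- make_impact_variants(sample(sheet$sample_id, 60, replace = TRUE),
                            gene = sample(paste0("G", 1:6), 60, replace = TRUE),
                            impact = round(runif(60), 3), sheet = sheet)
  cfg <- driver_config(n_null_draws = 300, seed = 4)
  scan_all <- run_driver_scan(v, sheet, config = cfg)
  expect_equal(scan_all$results$q, bh_oracle(scan_all$results$p))

  # scanning one subtype ignores the other subtype's variants entirely
  scan_m <- run_driver_scan(v, sheet, config = cfg, subtype = "morphoeic")
  v_noise <- v
  v_noise[v_noise$subtype == "nodular", "sift"] <- 0       # mangle nodular scores
  v_noise[v_noise$subtype == "nodular", "polyphen"] <- 1
  scan_m2 <- run_driver_scan(v_noise, sheet, config = cfg, subtype = "morphoeic")
  expect_equal(scan_m2$results, scan_m$results)

  # single eligible gene (others have one variant each, background only):
  # q equals p
  v1 <- dplyr::bind_rows(
    make_impact_variants(c("M01", "M02"), "ONLY", impact = c(0.9, 0.8), sheet = sheet),
    make_impact_variants(c("N01", "N02", "M03"), paste0("BG", 1:3),
                         impact = c(0.2, 0.5, 0.7), sheet = sheet))
  scan1 <- run_driver_scan(v1, sheet, config = cfg)
  expect_equal(scan1$results$gene, "ONLY")
  expect_equal(scan1$results$q, scan1$results$p)
})

test_that("a planted high-rate high-impact driver ranks first in the scan", {
  cat_genes <- simulate_gene_catalogue()
  len <- cat_genes$coding_length_bp[cat_genes$gene == "GENE050"]
  cfg <- simulation_config(
    background_rate = 3e-5,
    drivers = list(driver_spec("GENE050", c("morphoeic", "nodular"),
                               rate_multiplier = 10, impact_shift = 0.5)),
    seed = 303)
  sim <- simulate_cohort(cfg)
  scan <- run_driver_scan(sim$variants, sim$sheet, sim$models,
                          driver_config(n_null_draws = 2000, seed = 8))
  best <- scan$results$gene[which.min(scan$results$q)]
  expect_equal(best, "GENE050")
})

test_that("scan records skipped genes with reasons instead of failing", {
  sheet <- make_sheet(2, 2)
  v <- make_impact_variants(c("M01", "M01", "M02", "N01"),
                            gene = c("A", "A", "B", "C"),
                            impact = 0.5, sheet = sheet)
  scan <- run_driver_scan(v, sheet, config = driver_config(n_null_draws = 200, seed = 1))
  expect_setequal(scan$skipped$gene, c("B", "C"))
  expect_equal(unique(scan$skipped$reason), "too_few_variants")
  expect_equal(scan$results$gene, "A")
})
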