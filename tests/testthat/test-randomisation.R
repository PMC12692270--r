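# Candidate selection and the cohort-split randomisation comparison test.

# convenience: wrap per-gene results into a minimal driver_scan
fake_scan <- function(genes, p, subtype, method = "impact_bias",
                      cfg = driver_config(n_null_draws = 200, seed = 1)) {
  q <- if (length(p)) bh_fdr(p) else numeric(0)
  structure(list(results = tibble::tibble(gene = genes, n_variants = 2L,
                                          n_mutated_samples = 2L,
                                          statistic = 0.5, p = p, q = q),
                 skipped = tibble::tibble(gene = character(), reason = character()),
                 config = within_method(cfg, method), subtype = subtype,
                 n_samples = 10L, background_rate = NULL),
            class = "driver_scan")
}
within_method <- function(cfg, method) { cfg$method <- method; cfg }

test_that("candidate rule: significant in one subtype, not the other", {
  a <- fake_scan(c("G1", "G2", "G3"), c(0.03, 0.03, 0.30), "morphoeic")
  # hand-set q to probe exact boundary behaviour
  a$results$q <- c(0.03, 0.03, 0.30)
  b <- fake_scan(c("G1", "G2"), c(0.5, 0.08), "nodular")
  b$results$q <- c(0.50, 0.08)
  cand <- select_candidates(a, b)
  # G1: q_a=0.03 < 0.05, q_b=0.50 > 0.1 -> candidate
  # G2: q_b=0.08 fails q_nonsig -> not a candidate
  # G3: not significant anywhere
  expect_equal(cand$gene, "G1")
  expect_equal(cand$candidate_subtype, "morphoeic")
})

test_that("genes untested in the other subtype follow the permissive/strict switch", {
  a <- fake_scan("G1", 0.01, "morphoeic")
  b <- fake_scan(character(), numeric(), "nodular")
  expect_equal(select_candidates(a, b)$gene, "G1")
  expect_equal(nrow(select_candidates(a, b, strict = TRUE)), 0)
})

test_that("a gene is never a candidate for both subtypes", {
  a <- fake_scan(c("G1", "G2"), c(0.01, 0.2), "morphoeic")
  b <- fake_scan(c("G1", "G2"), c(0.01, 0.9), "nodular")
  a$results$q <- c(0.01, 0.2); b$results$q <- c(0.01, 0.9)
  cand <- select_candidates(a, b)
  expect_equal(anyDuplicated(cand$gene), 0)
  expect_false("G1" %in% cand$gene)  # significant in both: specific to neither
})

test_that("enumerate_splits yields every ordered balanced split exactly once", {
  expect_length(enumerate_splits(sprintf("S%d", 1:4), c(2, 2)), 6)
  expect_length(enumerate_splits(sprintf("S%d", 1:6), c(3, 3)), 20)
  expect_length(enumerate_splits(sprintf("S%d", 1:2), c(1, 1)), 2)
  sp <- enumerate_splits(c("A", "B", "C"), c(1, 2))
  expect_equal(sort(purrr::map_chr(sp, ~ .x$group1)), c("A", "B", "C"))
  # complements are distinct splits (group identity matters)
  sp22 <- enumerate_splits(sprintf("S%d", 1:4), c(2, 2))
  g1 <- purrr::map_chr(sp22, ~ paste(.x$group1, collapse = ","))
  expect_equal(anyDuplicated(g1), 0)
  expect_error(enumerate_splits(sprintf("S%d", 1:40), c(20, 20)),
               class = "splitsig_usage_error")
  expect_error(enumerate_splits(sprintf("S%d", 1:5), c(2, 2)),
               class = "splitsig_usage_error")
})

test_that("two-tail formula: extreme observation gives 2/(n_iter+1), constant null gives 1", {
  sheet <- make_sheet(3, 3)
  # subtype-exclusive gene: 4 high-impact variants in 3 morphoeic samples,
  # uniform background elsewhere
  set.seed(42)
  v <- dplyr::bind_rows(
    make_impact_variants(c("M01", "M02", "M03", "M01"), "DRV", impact = 1,
                         genomic_pos = 1:4, sheet = sheet),
    make_impact_variants(rep(sheet$sample_id, 3), paste0("BG", 1:18),
                         impact = round(runif(18, 0, 0.4), 2),
                         genomic_pos = 101:118, sheet = sheet))
  cand <- tibble::tibble(gene = "DRV", candidate_subtype = "morphoeic")
  cfg <- driver_config(n_null_draws = 500, seed = 5)
  rt <- randomisation_test(v, sheet, cand, config = cfg,
                           rand_config = randomisation_config(n_iter = 100, seed = 9))
  res <- tidy(rt)
  if (all(rt$results$null_sigs[[1]] < res$observed_sig)) {
    expect_equal(res$two_tail_p, 2 / 101)
    expect_true(res$specific)
  }
  expect_gte(res$two_tail_p, 2 / 101)

  # degenerate constant null: gene with identical impact everywhere ties in
  # every split, so both tails saturate and the capped p is 1
  v2 <- make_impact_variants(rep(sheet$sample_id, each = 2),
                             gene = rep(c("G1", "G2"), 6),
                             impact = 0.5, genomic_pos = 1:12, sheet = sheet)
  rt2 <- randomisation_test(v2, sheet,
                            tibble::tibble(gene = "G1", candidate_subtype = "morphoeic"),
                            config = driver_config(n_null_draws = 200, seed = 5,
                                                   min_variants = 2L),
                            rand_config = randomisation_config(n_iter = 50, seed = 9))
  expect_equal(tidy(rt2)$two_tail_p, 1)
  expect_false(tidy(rt2)$specific)
})

test_that("exact mode equals an independent brute-force enumeration oracle on 3v3", {
  sheet <- make_sheet(3, 3)
  set.seed(7)
  v <- dplyr::bind_rows(
    make_impact_variants(c("M01", "M02", "N01"), "CAND", impact = c(0.95, 0.9, 0.85),
                         genomic_pos = 1:3, sheet = sheet),
    make_impact_variants(rep(sheet$sample_id, 4), paste0("BG", 1:24),
                         impact = round(runif(24), 2),
                         genomic_pos = 101:124, sheet = sheet))
  cfg <- driver_config(n_null_draws = 400, seed = 3)
  rcfg <- randomisation_config(n_iter = 20, seed = 6)
  rt <- randomisation_test(v, sheet,
                           tibble::tibble(gene = "CAND", candidate_subtype = "morphoeic"),
                           config = cfg, rand_config = rcfg, mode = "exact")
  res <- tidy(rt)
  expect_equal(res$n_iter, 20)  # C(6,3) ordered splits

  # brute-force oracle: loop over all 20 group-1 subsets independently,
  # recompute the gene's -log10 p inside each with the same engine seeds
  ids <- sort(sheet$sample_id)
  combos <- combn(6, 3, simplify = FALSE)
  obs_scan <- run_driver_scan(v, sheet, config = cfg, subtype = "morphoeic")
  obs <- -log10(obs_scan$results$p[obs_scan$results$gene == "CAND"])
  nulls <- purrr::map_dbl(seq_along(combos), function(ci) {
    g1 <- ids[combos[[ci]]]
    vv <- dplyr::filter(v, sample_id %in% g1)
    k <- sum(vv$gene == "CAND")
    if (k < cfg$min_variants) return(0)
    cfg_i <- cfg
    cfg_i$seed <- derive_seed(rcfg$seed, 1, ci, 10001)
    -log10(impact_bias_test(vv, "CAND", cfg_i)$p)
  })
  p_oracle <- min(1, 2 * (min(sum(nulls <= obs), sum(nulls >= obs)) + 1) / 21)
  expect_equal(res$two_tail_p, p_oracle)
  expect_equal(res$observed_sig, obs)
  expect_equal(sort(rt$results$null_sigs[[1]]), sort(nulls))
})

test_that("relabelling the subtypes swaps candidates and preserves two-tail p", {
  cat_len <- simulate_gene_catalogue()$coding_length_bp[50]
  cfg_sim <- simulation_config(
    background_rate = 3e-5,
    drivers = list(driver_spec("GENE050", "morphoeic",
                               rate_multiplier = 8, impact_shift = 0.5)),
    seed = 61)
  sim <- simulate_cohort(cfg_sim)
  sheet_sw <- dplyr::mutate(sim$sheet,
                            subtype = ifelse(subtype == "morphoeic", "nodular", "morphoeic"))
  v_sw <- dplyr::select(sim$variants, -subtype) |>
    dplyr::left_join(sheet_sw, by = "sample_id")
  cfg <- driver_config(n_null_draws = 1000, seed = 2)
  cand <- tibble::tibble(gene = "GENE050", candidate_subtype = "morphoeic")
  cand_sw <- tibble::tibble(gene = "GENE050", candidate_subtype = "nodular")
  rt <- randomisation_test(sim$variants, sim$sheet, cand, sim$models, cfg,
                           randomisation_config(n_iter = 40, seed = 3))
  rt_sw <- randomisation_test(v_sw, sheet_sw, cand_sw, sim$models, cfg,
                              randomisation_config(n_iter = 40, seed = 3))
  expect_equal(tidy(rt_sw)$two_tail_p, tidy(rt)$two_tail_p)
  expect_equal(tidy(rt_sw)$observed_sig, tidy(rt)$observed_sig)
})

test_that("randomisation results are reproducible given the seed", {
  sheet <- make_sheet(3, 3)
  set.seed(8)
  v <- dplyr::bind_rows(
    make_impact_variants(c("M01", "M02"), "CAND", impact = 0.9,
                         genomic_pos = 1:2, sheet = sheet),
    make_impact_variants(rep(sheet$sample_id, 2), paste0("BG", 1:12),
                         impact = round(runif(12), 2),
                         genomic_pos = 101:112, sheet = sheet))
  cand <- tibble::tibble(gene = "CAND", candidate_subtype = "morphoeic")
  args <- list(v, sheet, cand, NULL, driver_config(n_null_draws = 200, seed = 1),
               randomisation_config(n_iter = 25, seed = 12))
  expect_equal(do.call(randomisation_test, args)$results,
               do.call(randomisation_test, args)$results)
})
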