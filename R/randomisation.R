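# Subtype-specificity by cohort-split randomisation.
#
# Candidate genes (significant in one subtype, not the other) are tested
# against an empirical null built by repeatedly relabelling the pooled cohort
# into two random balanced groups and recording the candidate's significance
# in the group that stands in for its subtype. A candidate whose true-label
# significance sits in the tails of that null is declared subtype-specific.

#' Candidate-selection rule
#'
#' A gene is a subtype-A candidate when it is significant in subtype A
#' (`q < q_sig`) but not in subtype B (`q > q_nonsig`, or untested there under
#' the permissive reading).
#'
#' @param q_sig Significance threshold in the candidate subtype (default 0.05).
#' @param q_nonsig Non-significance threshold in the other subtype
#'   (default 0.1).
#' @return A `candidate_rule` list.
#' @export
candidate_rule <- function(q_sig = 0.05, q_nonsig = 0.1) {
  if (!(q_sig > 0 && q_sig <= q_nonsig && q_nonsig < 1)) {
    abort_range("need 0 < q_sig <= q_nonsig < 1")
  }
  structure(list(q_sig = q_sig, q_nonsig = q_nonsig), class = "candidate_rule")
}

#' Configuration of the randomisation comparison test
#'
#' @param n_iter Number of random cohort splits (default 100).
#' @param seed Integer master seed.
#' @param alpha Two-tail significance level for declaring specificity
#'   (default 0.05).
#' @return A `randomisation_config` list.
#' @export
randomisation_config <- function(n_iter = 100L, seed = 1L, alpha = 0.05) {
  if (n_iter < 1) abort_usage("n_iter must be >= 1")
  if (alpha <= 0 || alpha >= 1) abort_range("alpha must lie in (0, 1)")
  structure(list(n_iter = as.integer(n_iter), seed = as.integer(seed),
                 alpha = alpha),
            class = "randomisation_config")
}

#' Select subtype-specific driver candidates from two scans
#'
#' @param scan_a,scan_b `driver_scan` objects for the two subtypes (run with
#'   the same method); their `subtype` fields name the labels.
#' @param rule A [candidate_rule()].
#' @param strict When `TRUE`, a gene skipped/untested in the other subtype is
#'   *not* a candidate (it must have been tested there with `q > q_nonsig`);
#'   the default permissive reading counts untested as non-significant.
#' @return Tibble: `gene`, `candidate_subtype`, `q_candidate`, `q_other`
#'   (`NA` when untested in the other subtype).
#' @export
select_candidates <- function(scan_a, scan_b, rule = candidate_rule(),
                              strict = FALSE) {
  if (!inherits(scan_a, "driver_scan") || !inherits(scan_b, "driver_scan")) {
    abort_usage("select_candidates expects two driver_scan objects")
  }
  if (scan_a$config$method != scan_b$config$method) {
    abort_usage("the two scans use different methods ({scan_a$config$method} vs {scan_b$config$method})")
  }
  one_side <- function(self, other) {
    qs <- setNames(other$results$q, other$results$gene)
    self$results %>%
      filter(.data$q < rule$q_sig) %>%
      mutate(q_other = unname(qs[.data$gene])) %>%
      filter(if (strict) !is.na(.data$q_other) & .data$q_other > rule$q_nonsig
             else is.na(.data$q_other) | .data$q_other > rule$q_nonsig) %>%
      transmute_candidates(self$subtype)
  }
  bind_rows(one_side(scan_a, scan_b), one_side(scan_b, scan_a))
}

transmute_candidates <- function(df, subtype) {
  tibble(gene = df$gene,
         candidate_subtype = rep(subtype %||% NA_character_, nrow(df)),
         q_candidate = df$q,
         q_other = df$q_other)
}

#' Enumerate all balanced splits of a cohort
#'
#' Yields every assignment of the samples into an ordered pair of groups of
#' the given sizes. Group identity matters (group 1 stands in for the
#' candidate subtype), so for equal sizes a split and its complement are both
#' produced.
#'
#' @param sample_ids Character vector of sample ids.
#' @param group_sizes Integer pair summing to `length(sample_ids)`.
#' @return List of splits, each a list with `group1` and `group2` id vectors.
#' @export
enumerate_splits <- function(sample_ids, group_sizes) {
  n <- length(sample_ids)
  if (sum(group_sizes) != n) {
    abort_usage("group sizes ({paste(group_sizes, collapse = '+')}) must sum to the cohort size ({n})")
  }
  n_splits <- choose(n, group_sizes[1])
  if (n_splits > 1e5) {
    abort_usage("C({n}, {group_sizes[1]}) = {n_splits} splits exceed the enumeration bound 1e5; use Monte-Carlo mode")
  }
  sample_ids <- sort(sample_ids)
  combos <- utils::combn(n, group_sizes[1], simplify = FALSE)
  purrr::map(combos, function(idx) {
    list(group1 = sample_ids[idx], group2 = sample_ids[-idx])
  })
}

# Significance (-log10 p) of one gene inside one split group, under the same
# method and eligibility rules as the true-label scan. Degenerate situations
# (too few variants in the group, empty/short background pool) record p = 1,
# i.e. significance 0 -- a split must never abort the run.
split_significance <- function(variants, gene, method, min_variants,
                               n_null_draws, seed, models, n_group) {
  gvars <- filter(variants, .data$gene == !!gene)
  k <- nrow(gvars)
  if (k < min_variants) return(0)
  if (method == "impact_bias") {
    pool <- filter(variants, .data$gene != !!gene)
    if (nrow(pool) < max(1, k)) return(0)
    mc <- impact_bias_mc(combined_impact(gvars), combined_impact(pool),
                         n_null_draws, seed)
    -log10(mc$p)
  } else {
    rate <- estimate_background_rate(variants, models, n_group)
    if (rate <= 0) return(0)
    res <- recurrence_test(variants, gene, models, rate, n_group)
    -log10(res$p)
  }
}

#' Randomisation comparison test for subtype-specific drivers
#'
#' For each candidate gene, the full cohort is repeatedly split at random
#' into two groups sized like the true subtypes (group 1 taking the size of
#' the candidate's subtype). The gene's significance (-log10 of the raw
#' per-gene p, same method as the true scan) is computed in group 1 of every
#' split, giving an empirical null of `n_iter` values. The observed
#' significance from the true-label scan is then placed in that null:
#' `two_tail_p = min(1, 2 * (min(#below-or-equal, #above-or-equal) + 1) /
#' (n_iter + 1))`, and the gene is declared specific when `two_tail_p <
#' alpha`. In `mode = "exact"` every balanced split is enumerated instead of
#' sampled and `n_iter` becomes the number of splits.
#'
#' @param variants Variant tibble for the full pooled cohort.
#' @param sheet Sample sheet (defines the subtype group sizes).
#' @param candidates Tibble from [select_candidates()] (columns `gene`,
#'   `candidate_subtype`).
#' @param models Gene-model tibble (needed for the recurrence method).
#' @param config A [driver_config()] — the per-gene engine used both for the
#'   true scans and inside splits.
#' @param rand_config A [randomisation_config()].
#' @param mode `"monte_carlo"` (default) or `"exact"` (exhaustive splits;
#'   bounded at 1e5 splits).
#' @return A `randomisation_result`: list with `results` tibble (`gene`,
#'   `candidate_subtype`, `observed_sig`, `null_mean`, `null_sd`,
#'   `two_tail_p`, `specific`, and a `null_sigs` list-column), plus the
#'   configurations used. Supports [tidy()], [glance()] and [autoplot()].
#' @export
randomisation_test <- function(variants, sheet, candidates, models = NULL,
                               config = driver_config(),
                               rand_config = randomisation_config(),
                               mode = c("monte_carlo", "exact")) {
  mode <- arg_match(mode)
  validate_sample_sheet(sheet)
  if (nrow(candidates) == 0) abort_usage("no candidates to test")
  variants <- canonical_variant_order(filter(variants, is_nonsynonymous(.data$consequence)))
  all_samples <- sort(sheet$sample_id)
  subtypes <- sort(unique(candidates$candidate_subtype))

  res <- purrr::map(subtypes, function(s) {
    genes <- sort(candidates$gene[candidates$candidate_subtype == s])
    n1 <- sum(sheet$subtype == s)
    if (n1 == 0) abort_consistency("candidate subtype '{s}' has no samples in the sheet")

    # observed significance from the true-label scan of subtype s
    scan_s <- run_driver_scan(variants, sheet, models, config, subtype = s)
    obs <- setNames(rep(0, length(genes)), genes)
    hit <- intersect(genes, scan_s$results$gene)
    obs[hit] <- -log10(scan_s$results$p[match(hit, scan_s$results$gene)])

    splits <- if (mode == "exact") {
      enumerate_splits(all_samples, c(n1, length(all_samples) - n1))
    } else {
      s_idx <- match(s, subtypes)
      purrr::map(seq_len(rand_config$n_iter), function(it) {
        g1 <- withr::with_seed(derive_seed(rand_config$seed, s_idx, it),
                               sample(all_samples, n1))
        list(group1 = g1, group2 = setdiff(all_samples, g1))
      })
    }
    n_iter <- length(splits)

    null_sigs <- purrr::imap(splits, function(sp, it) {
      split_vars <- filter(variants, .data$sample_id %in% sp$group1)
      vapply(seq_along(genes), function(gi) {
        split_significance(split_vars, genes[gi], config$method,
                           config$min_variants, config$n_null_draws,
                           derive_seed(rand_config$seed, match(s, subtypes), it, 10000 + gi),
                           models, n1)
      }, numeric(1))
    })
    null_mat <- do.call(rbind, null_sigs)  # n_iter x n_genes

    purrr::map(seq_along(genes), function(gi) {
      nulls <- null_mat[, gi]
      n_le <- sum(nulls <= obs[gi])
      n_ge <- sum(nulls >= obs[gi])
      p2 <- min(1, 2 * (min(n_le, n_ge) + 1) / (n_iter + 1))
      tibble(gene = genes[gi],
             candidate_subtype = s,
             observed_sig = unname(obs[gi]),
             null_mean = mean(nulls),
             null_sd = stats::sd(nulls),
             two_tail_p = p2,
             specific = p2 < rand_config$alpha,
             null_sigs = list(unname(nulls)),
             n_iter = n_iter)
    }) %>% bind_rows()
  }) %>% bind_rows()

  structure(list(results = res, config = config, rand_config = rand_config,
                 mode = mode),
            class = "randomisation_result")
}

#' @exportS3Method generics::tidy
tidy.randomisation_result <- function(x, ...) {
  select(x$results, -"null_sigs")
}

#' @exportS3Method generics::glance
glance.randomisation_result <- function(x, ...) {
  tibble(n_candidates = nrow(x$results),
         n_specific = sum(x$results$specific),
         n_iter = if (nrow(x$results) > 0) x$results$n_iter[1] else x$rand_config$n_iter,
         alpha = x$rand_config$alpha,
         mode = x$mode,
         method = x$config$method)
}

#' @export
print.randomisation_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<randomisation_result> %s/%s: %d candidate(s), %d specific at two-tail alpha=%g (%d splits)\n",
              g$method, g$mode, g$n_candidates, g$n_specific, g$alpha, g$n_iter))
  print(tidy(x))
  invisible(x)
}

#' Null-distribution plot for a randomisation test
#'
#' @param object A `randomisation_result`.
#' @param ... Unused.
#' @return A ggplot: histogram of the split-null significances per candidate
#'   with the observed true-label significance as a vertical line.
#' @exportS3Method ggplot2::autoplot
autoplot.randomisation_result <- function(object, ...) {
  long <- object$results %>%
    select("gene", "candidate_subtype", "observed_sig", "null_sigs") %>%
    tidyr::unnest("null_sigs")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$null_sigs)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$observed_sig),
                        colour = "firebrick", linewidth = 1) +
    ggplot2::facet_wrap(~ gene + candidate_subtype, scales = "free") +
    ggplot2::labs(x = expression(-log[10](p) ~ "in random split group"),
                  y = "splits",
                  title = "Randomisation null vs observed significance") +
    ggplot2::theme_minimal()
}
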