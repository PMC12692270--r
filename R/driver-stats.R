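# Per-gene driver significance.
#
# Two self-contained significance engines stand behind the scan:
#   * impact_bias   — a functional-impact-bias permutation test: is the mean
#                     predicted damage of a gene's nonsynonymous variants
#                     higher than random draws from the cohort-wide pool?
#                     (the FM-bias idea behind tools such as OncodriveFM)
#   * recurrence    — a length-aware binomial recurrence test against a
#                     cohort background mutation rate (the core signal that
#                     covariate-rich tools such as MutSigCV formalise)

#' Configuration for the per-gene driver tests
#'
#' @param method `"impact_bias"` (functional-impact-bias permutation test) or
#'   `"recurrence"` (binomial recurrence against a background rate).
#' @param n_null_draws Monte-Carlo null size for the impact-bias test.
#' @param seed Integer master seed; all resampling is reproducible given it.
#' @param q_threshold FDR threshold used to call a gene significant
#'   (default 0.1).
#' @param p_threshold Raw-p threshold used to flag "highlighted" genes in
#'   scan summaries (default 0.02).
#' @param min_variants Minimum nonsynonymous variants for a gene to be tested
#'   (default 2: a single variant cannot show bias).
#' @return A `driver_config` list.
#' @export
driver_config <- function(method = c("impact_bias", "recurrence"),
                          n_null_draws = 10000L,
                          seed = 1L,
                          q_threshold = 0.1,
                          p_threshold = 0.02,
                          min_variants = 2L) {
  method <- arg_match(method)
  if (n_null_draws < 100) abort_usage("n_null_draws must be >= 100")
  for (thr in c(q_threshold, p_threshold)) {
    if (!is.numeric(thr) || thr <= 0 || thr >= 1) {
      abort_range("thresholds must lie in (0, 1)")
    }
  }
  if (min_variants < 1) abort_usage("min_variants must be >= 1")
  structure(list(method = method,
                 n_null_draws = as.integer(n_null_draws),
                 seed = as.integer(seed),
                 q_threshold = q_threshold,
                 p_threshold = p_threshold,
                 min_variants = as.integer(min_variants)),
            class = "driver_config")
}

#' Combined functional-impact score of nonsynonymous variants
#'
#' Maps each variant's SIFT and PolyPhen predictions to a single damage score
#' in \[0, 1\]: the mean of the available components, where SIFT contributes
#' `1 - sift` (SIFT is low for damaging variants) and PolyPhen contributes
#' `polyphen` directly. Variants with neither score fall back to a
#' consequence-based prior: nonsense and splice-site variants are scored 1
#' (presumed loss of function), anything else 0.5 (uninformative).
#'
#' @param variants Variant tibble; every row must be nonsynonymous.
#' @return Numeric vector of impact scores, one per row.
#' @export
combined_impact <- function(variants) {
  if (any(!is_nonsynonymous(variants$consequence))) {
    abort_usage("combined_impact is undefined for synonymous variants")
  }
  sift_part <- 1 - variants$sift
  poly_part <- variants$polyphen
  n_avail <- (!is.na(sift_part)) + (!is.na(poly_part))
  score_sum <- dplyr::coalesce(sift_part, 0) + dplyr::coalesce(poly_part, 0)
  fallback <- ifelse(variants$consequence %in% c("nonsense", "splice_site"), 1, 0.5)
  ifelse(n_avail > 0, score_sum / pmax(n_avail, 1), fallback)
}

# Shared Monte-Carlo core: observed mean impact of a target set of variants
# against means of seeded draws (without replacement) from a background pool.
# Draws are generated as a k x n_draws index matrix; when k is small relative
# to the pool, with-replacement draws are taken and the rare columns carrying
# duplicates redrawn (rejection), which keeps the whole null in colMeans()
# instead of an R-level loop.
impact_bias_mc <- function(target_impacts, pool_impacts, n_draws, seed) {
  k <- length(target_impacts)
  np <- length(pool_impacts)
  if (np == 0) abort_usage("background pool is empty")
  if (np < k) {
    abort_usage("background pool ({np} variants) smaller than the target set ({k}); cannot draw without replacement")
  }
  observed <- mean(target_impacts)
  null_means <- withr::with_seed(seed, {
    if (k == np) {
      rep(mean(pool_impacts), n_draws)
    } else if (2 * k <= np) {
      has_dup <- function(mm) {
        d <- rep(FALSE, ncol(mm))
        for (i in seq_len(nrow(mm) - 1)) {
          for (j in (i + 1):nrow(mm)) d <- d | (mm[i, ] == mm[j, ])
        }
        d
      }
      m <- matrix(sample.int(np, k * n_draws, replace = TRUE), nrow = k)
      bad <- which(has_dup(m))
      while (length(bad) > 0) {
        m[, bad] <- sample.int(np, k * length(bad), replace = TRUE)
        bad <- bad[has_dup(m[, bad, drop = FALSE])]
      }
      colMeans(matrix(pool_impacts[m], nrow = k))
    } else {
      vapply(seq_len(n_draws),
             function(i) mean(pool_impacts[sample.int(np, k)]),
             numeric(1))
    }
  })
  # add-one empirical p: never zero, ties count as at-least-as-extreme
  p <- (1 + sum(null_means >= observed)) / (1 + n_draws)
  list(statistic = observed, p = p)
}

#' Functional-impact-bias test for one gene
#'
#' Tests whether the mean combined impact of a gene's nonsynonymous variants
#' exceeds what draws of the same size from the rest of the cohort's
#' nonsynonymous variants achieve. The null is built by `n_null_draws` seeded
#' draws without replacement from the cohort pool excluding the gene; the
#' reported p is the add-one empirical upper tail, so `p >= 1/(n_null_draws+1)`
#' and ties count as at least as extreme.
#'
#' @param variants Variant tibble (a whole cohort or one subtype's slice).
#' @param gene Gene symbol to test.
#' @param config A [driver_config()].
#' @return One-row tibble: `gene`, `n_variants`, `n_mutated_samples`,
#'   `statistic` (observed mean impact), `p`.
#' @export
impact_bias_test <- function(variants, gene, config = driver_config()) {
  variants <- canonical_variant_order(filter(variants, is_nonsynonymous(.data$consequence)))
  gvars <- filter(variants, .data$gene == !!gene)
  if (nrow(gvars) < config$min_variants) {
    abort_usage("gene {gene} has {nrow(gvars)} nonsynonymous variants; min_variants = {config$min_variants}")
  }
  pool <- filter(variants, .data$gene != !!gene)
  mc <- impact_bias_mc(combined_impact(gvars), combined_impact(pool),
                       config$n_null_draws, config$seed)
  tibble(gene = gene,
         n_variants = nrow(gvars),
         n_mutated_samples = n_distinct(gvars$sample_id),
         statistic = mc$statistic,
         p = mc$p)
}

#' Length-aware binomial recurrence test for one gene
#'
#' Under a passenger-only model, the number of nonsynonymous variants a gene
#' of coding length L accrues across n samples is Binomial(n * L, r) with r
#' the per-base per-sample background rate. The test reports the upper tail
#' `P(X >= k)` for the observed count k; `k = 0` gives p = 1.
#'
#' @param variants Variant tibble (already restricted to the cohort of
#'   interest).
#' @param gene Gene symbol.
#' @param model One-row gene-model tibble (or a row subset containing the
#'   gene) with `coding_length_bp`.
#' @param background_rate Per-base per-sample nonsynonymous mutation rate.
#' @param n_samples Number of samples in the cohort (from the sample sheet,
#'   not the variant rows: samples without variants still contribute
#'   opportunity).
#' @param config A [driver_config()] (used for bookkeeping fields only).
#' @return One-row tibble: `gene`, `n_variants`, `n_mutated_samples`,
#'   `statistic` (the observed count), `p`.
#' @export
recurrence_test <- function(variants, gene, model, background_rate, n_samples,
                            config = driver_config(method = "recurrence")) {
  model <- filter(model, .data$gene == !!gene)
  if (nrow(model) != 1) abort_usage("gene {gene} not found (or duplicated) in gene models")
  gvars <- filter(variants, .data$gene == !!gene, is_nonsynonymous(.data$consequence))
  k <- nrow(gvars)
  if (background_rate < 0 || background_rate >= 1) {
    abort_range("background_rate must lie in [0, 1)")
  }
  if (background_rate == 0 && k >= 1) {
    abort_usage("background_rate is 0 but gene {gene} has {k} variants; the model is degenerate")
  }
  trials <- as.double(n_samples) * as.double(model$coding_length_bp)
  p <- if (k == 0) 1 else pbinom(k - 1, trials, background_rate, lower.tail = FALSE)
  tibble(gene = gene,
         n_variants = k,
         n_mutated_samples = n_distinct(gvars$sample_id),
         statistic = as.double(k),
         p = p)
}

#' Estimate the cohort-wide background mutation rate
#'
#' Total nonsynonymous variant count over non-excluded genes divided by
#' (number of samples x total coding length of non-excluded genes): the
#' per-base per-sample passenger rate the recurrence test needs. Exclude
#' putative drivers to avoid inflating the background.
#'
#' @param variants Variant tibble.
#' @param models Gene-model tibble.
#' @param n_samples Cohort size (from the sample sheet).
#' @param exclude Character vector of gene symbols to leave out.
#' @return A single rate (double, per base per sample).
#' @export
estimate_background_rate <- function(variants, models, n_samples,
                                     exclude = character()) {
  keep <- filter(models, !.data$gene %in% exclude)
  total_len <- sum(as.double(keep$coding_length_bp))
  if (total_len <= 0) abort_usage("total coding length of non-excluded genes is zero")
  n_var <- variants %>%
    filter(is_nonsynonymous(.data$consequence), .data$gene %in% keep$gene) %>%
    nrow()
  n_var / (as.double(n_samples) * total_len)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment; output order matches input order and values are
#' capped at 1.
#'
#' @param pvals Numeric vector of raw p-values in (0, 1\].
#' @return Numeric vector of q-values.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(is.na(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    abort_range("p-values must lie in (0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Scan every eligible gene for driver significance
#'
#' Runs the configured per-gene test over all genes with at least
#' `min_variants` nonsynonymous variants (in the chosen subtype, if given)
#' and adjusts the resulting p-values by Benjamini-Hochberg across the scan.
#' Ineligible genes are not errors: they are reported in the `skipped` table
#' with a reason, mirroring how driver-detection tools drop untestable genes.
#'
#' @param variants Variant tibble with a `subtype` column (as produced by
#'   [read_variant_table()] or [simulate_cohort()]).
#' @param sheet Sample sheet tibble; defines cohort sizes (samples with no
#'   variants count).
#' @param models Gene-model tibble (required for `method = "recurrence"`).
#' @param config A [driver_config()].
#' @param subtype Optional subtype label; when given the scan is restricted
#'   to that subtype's samples and variants.
#' @param background_rate Optional fixed background rate for the recurrence
#'   test; estimated from the scanned cohort via
#'   [estimate_background_rate()] when `NULL`.
#' @return A `driver_scan` object: list with `results` (tibble with `q`
#'   column), `skipped`, `config`, `subtype`, `n_samples`,
#'   `background_rate`. Use [tidy()] / [glance()] / [autoplot()] on it.
#' @export
run_driver_scan <- function(variants, sheet, models = NULL,
                            config = driver_config(), subtype = NULL,
                            background_rate = NULL) {
  validate_sample_sheet(sheet)
  if (!is.null(subtype)) {
    keep_samples <- sheet$sample_id[sheet$subtype == subtype]
    if (length(keep_samples) == 0) abort_usage("no samples with subtype '{subtype}' in sheet")
    variants <- filter(variants, .data$sample_id %in% keep_samples)
    n_samples <- length(keep_samples)
  } else {
    n_samples <- nrow(sheet)
  }
  variants <- canonical_variant_order(filter(variants, is_nonsynonymous(.data$consequence)))
  counts <- variants %>% count(.data$gene, name = "n_variants")
  eligible <- counts$gene[counts$n_variants >= config$min_variants]
  skipped <- tibble(gene = counts$gene[counts$n_variants < config$min_variants],
                    reason = "too_few_variants")
  if (config$method == "recurrence") {
    if (is.null(models)) abort_usage("recurrence scans need gene models")
    no_model <- setdiff(eligible, models$gene)
    if (length(no_model) > 0) {
      skipped <- bind_rows(skipped, tibble(gene = no_model, reason = "no_gene_model"))
      eligible <- setdiff(eligible, no_model)
    }
    if (is.null(background_rate)) {
      background_rate <- estimate_background_rate(variants, models, n_samples)
    }
  }
  eligible <- sort(eligible)
  rows <- purrr::imap(eligible, function(g, i) {
    if (config$method == "impact_bias") {
      cfg_g <- config
      cfg_g$seed <- derive_seed(config$seed, i)
      tryCatch(impact_bias_test(variants, g, cfg_g),
               splitsig_usage_error = function(e) {
                 tibble(gene = g, reason = "insufficient_background")
               })
    } else {
      recurrence_test(variants, g, models, background_rate, n_samples, config)
    }
  })
  is_skip <- purrr::map_lgl(rows, ~ "reason" %in% names(.x))
  skipped <- bind_rows(skipped, bind_rows(rows[is_skip]))
  results <- bind_rows(rows[!is_skip])
  if (nrow(results) > 0) {
    results$q <- bh_fdr(results$p)
  } else {
    warn("driver scan found no eligible genes")
    results <- tibble(gene = character(), n_variants = integer(),
                      n_mutated_samples = integer(), statistic = double(),
                      p = double(), q = double())
  }
  structure(list(results = results, skipped = skipped, config = config,
                 subtype = subtype, n_samples = n_samples,
                 background_rate = background_rate),
            class = "driver_scan")
}

#' @exportS3Method generics::tidy
tidy.driver_scan <- function(x, ...) x$results

#' @exportS3Method generics::glance
glance.driver_scan <- function(x, ...) {
  tibble(subtype = x$subtype %||% NA_character_,
         method = x$config$method,
         n_samples = x$n_samples,
         n_genes_tested = nrow(x$results),
         n_genes_skipped = nrow(x$skipped),
         n_significant = sum(x$results$q < x$config$q_threshold),
         n_highlighted = sum(x$results$p < x$config$p_threshold))
}

#' @export
print.driver_scan <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<driver_scan> method=%s subtype=%s: %d genes tested, %d significant at q<%g, %d skipped\n",
              g$method, g$subtype %||% "(all)", g$n_genes_tested,
              g$n_significant, x$config$q_threshold, g$n_genes_skipped))
  print(head(arrange(x$results, .data$q), 10))
  invisible(x)
}

#' Volcano-style plot of a driver scan
#'
#' @param object A `driver_scan`.
#' @param ... Unused.
#' @return A ggplot: per-gene statistic against -log10(q), with the scan's
#'   q threshold drawn as a dashed line.
#' @exportS3Method ggplot2::autoplot
autoplot.driver_scan <- function(object, ...) {
  res <- object$results
  ggplot2::ggplot(res, ggplot2::aes(x = .data$statistic, y = -log10(.data$q))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$q < object$config$q_threshold)) +
    ggplot2::geom_hline(yintercept = -log10(object$config$q_threshold),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey40"),
                                 name = sprintf("q < %g", object$config$q_threshold)) +
    ggplot2::labs(x = if (object$config$method == "impact_bias")
                    "mean combined impact" else "nonsynonymous variant count",
                  y = expression(-log[10](q)),
                  title = "Per-gene driver significance") +
    ggplot2::theme_minimal()
}
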