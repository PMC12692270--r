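# Pathway-level impact bias and the shared/subtype-specific set logic.

#' Functional-impact-bias test for a gene set
#'
#' Pools the nonsynonymous variants of every gene in the set and applies the
#' same impact-bias permutation machinery as [impact_bias_test()], with the
#' remaining cohort variants as the background pool. A set of one gene
#' therefore reproduces that gene's single-gene test exactly (same seed).
#' Genes in the set that are absent from the cohort are ignored (curated
#' pathway collections always exceed any one exome's mutated-gene universe).
#'
#' @param variants Variant tibble (cohort or one subtype's slice).
#' @param genes Character vector of gene symbols in the pathway (duplicates
#'   collapsed).
#' @param config A [driver_config()].
#' @param pathway Optional pathway name carried into the result.
#' @return One-row tibble: `pathway`, `genes_mutated`, `n_variants`,
#'   `statistic`, `p`.
#' @export
pathway_bias_test <- function(variants, genes, config = driver_config(),
                              pathway = NA_character_) {
  genes <- unique(genes)
  variants <- canonical_variant_order(filter(variants, is_nonsynonymous(.data$consequence)))
  in_set <- filter(variants, .data$gene %in% genes)
  if (nrow(in_set) < config$min_variants) {
    abort_usage("pathway has {nrow(in_set)} nonsynonymous variants; min_variants = {config$min_variants}")
  }
  pool <- filter(variants, !.data$gene %in% genes)
  if (nrow(pool) == 0) {
    abort_usage("background pool is empty: the pathway covers every mutated gene")
  }
  mc <- impact_bias_mc(combined_impact(in_set), combined_impact(pool),
                       config$n_null_draws, config$seed)
  tibble(pathway = pathway,
         genes_mutated = n_distinct(in_set$gene),
         n_variants = nrow(in_set),
         statistic = mc$statistic,
         p = mc$p)
}

#' Scan a gene-set collection for mutated pathways
#'
#' Applies [pathway_bias_test()] to every pathway with enough variants and
#' adjusts p-values by Benjamini-Hochberg across all tested pathways.
#'
#' @param variants Variant tibble.
#' @param sheet Sample sheet.
#' @param gene_sets Long tibble (`pathway`, `gene`) as from [read_gmt()].
#' @param config A [driver_config()].
#' @param subtype Optional subtype restriction.
#' @return A `pathway_scan` object (list with `results`, `skipped`,
#'   `config`, `subtype`); `tidy()` returns the results tibble.
#' @export
run_pathway_scan <- function(variants, sheet, gene_sets,
                             config = driver_config(), subtype = NULL) {
  validate_sample_sheet(sheet)
  if (!is.null(subtype)) {
    keep <- sheet$sample_id[sheet$subtype == subtype]
    if (length(keep) == 0) abort_usage("no samples with subtype '{subtype}' in sheet")
    variants <- filter(variants, .data$sample_id %in% keep)
  }
  variants <- canonical_variant_order(filter(variants, is_nonsynonymous(.data$consequence)))
  pathways <- sort(unique(gene_sets$pathway))
  mutated_genes <- unique(variants$gene)
  rows <- purrr::imap(pathways, function(pw, i) {
    genes <- gene_sets$gene[gene_sets$pathway == pw]
    n_in <- sum(variants$gene %in% genes)
    if (n_in < config$min_variants) {
      return(tibble(pathway = pw, reason = "too_few_variants"))
    }
    if (all(mutated_genes %in% genes)) {
      return(tibble(pathway = pw, reason = "empty_background"))
    }
    cfg_i <- config
    cfg_i$seed <- derive_seed(config$seed, i)
    pathway_bias_test(variants, genes, cfg_i, pathway = pw)
  })
  is_skip <- purrr::map_lgl(rows, ~ "reason" %in% names(.x))
  results <- bind_rows(rows[!is_skip])
  skipped <- bind_rows(rows[is_skip])
  if (nrow(results) > 0) results$q <- bh_fdr(results$p)
  structure(list(results = results, skipped = skipped, config = config,
                 subtype = subtype),
            class = "pathway_scan")
}

#' @exportS3Method generics::tidy
tidy.pathway_scan <- function(x, ...) x$results

#' @exportS3Method generics::glance
glance.pathway_scan <- function(x, ...) {
  tibble(subtype = x$subtype %||% NA_character_,
         n_pathways_tested = nrow(x$results),
         n_pathways_skipped = nrow(x$skipped),
         n_significant = if (nrow(x$results)) sum(x$results$q < x$config$q_threshold) else 0L)
}

#' Classify pathways as shared or subtype-specific
#'
#' Intersects two per-subtype pathway scans at a q threshold: pathways
#' significant in both are `shared`, in exactly one `specific_A` /
#' `specific_B`, otherwise `neither`. A pathway tested in only one scan is
#' treated (with a warning) as non-significant in the other.
#'
#' @param results_a,results_b `pathway_scan` objects or tidy result tibbles
#'   with `pathway` and `q` columns (e.g. an externally produced pathway->q
#'   table from a transcriptome analysis).
#' @param q_threshold Significance threshold (default 0.05).
#' @param labels Length-2 character vector naming the two sides (defaults to
#'   the scans' subtype fields, else "A"/"B").
#' @return A `subtype_comparison`: tibble with `pathway`, `q_a`, `q_b`,
#'   `category`; the three significant sets are also available via
#'   `attr(, "sets")`.
#' @export
compare_subtypes <- function(results_a, results_b, q_threshold = 0.05,
                             labels = NULL) {
  get_tbl <- function(x) if (inherits(x, "pathway_scan")) x$results else as_tibble(x)
  get_lab <- function(x, default) {
    if (inherits(x, "pathway_scan") && !is.null(x$subtype)) x$subtype else default
  }
  ta <- get_tbl(results_a)
  tb <- get_tbl(results_b)
  require_columns(ta, c("pathway", "q"), "pathway results A")
  require_columns(tb, c("pathway", "q"), "pathway results B")
  labels <- labels %||% c(get_lab(results_a, "A"), get_lab(results_b, "B"))
  only_a <- setdiff(ta$pathway, tb$pathway)
  only_b <- setdiff(tb$pathway, ta$pathway)
  if (length(only_a) + length(only_b) > 0) {
    warn(glue::glue("{length(only_a) + length(only_b)} pathway(s) tested in only one subtype; treated as non-significant in the other"))
  }
  merged <- dplyr::full_join(select(ta, "pathway", q_a = "q"),
                             select(tb, "pathway", q_b = "q"),
                             by = "pathway") %>%
    mutate(sig_a = !is.na(.data$q_a) & .data$q_a < q_threshold,
           sig_b = !is.na(.data$q_b) & .data$q_b < q_threshold,
           category = dplyr::case_when(
             sig_a & sig_b ~ "shared",
             sig_a ~ paste0("specific_", labels[1]),
             sig_b ~ paste0("specific_", labels[2]),
             TRUE ~ "neither")) %>%
    select("pathway", "q_a", "q_b", "category") %>%
    arrange(.data$category, .data$pathway)
  sets <- list(shared = merged$pathway[merged$category == "shared"],
               specific_a = merged$pathway[merged$category == paste0("specific_", labels[1])],
               specific_b = merged$pathway[merged$category == paste0("specific_", labels[2])])
  structure(merged, sets = sets, labels = labels, q_threshold = q_threshold,
            class = c("subtype_comparison", class(merged)))
}
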