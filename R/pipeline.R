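# End-to-end orchestration: run every stage on a set of input files and
# write plain-TSV reports plus a JSON run manifest into an output directory.

write_stage_tsv <- function(df, outdir, name) {
  path <- file.path(outdir, paste0(name, ".tsv"))
  df <- as_tibble(df)
  df <- df[, !purrr::map_lgl(df, is.list), drop = FALSE]
  readr::write_tsv(df, path)
  path
}

#' Run the full subtype-comparison pipeline
#'
#' Orchestrates the analysis end to end: per-subtype driver scans (both the
#' impact-bias and recurrence engines), candidate selection, the
#' cohort-split randomisation test, per-subtype pathway scans with the
#' shared/specific comparison, hotspot and domain-cluster calls, CNA burden
#' and recurrent-event counts, and ddCt fold changes. Every stage writes a
#' TSV into `outdir` and a JSON run manifest records the seed, input
#' checksums and per-stage row counts, so a rerun with the same inputs and
#' seed is byte-identical.
#'
#' @param paths Named list of input files: `variants`, `sheet` (required);
#'   optional `models`, `domains`, `gene_sets`, `segments`, `ct`.
#' @param outdir Output directory (created if needed).
#' @param seed Integer master seed for all resampling stages.
#' @param driver_cfg,rand_cfg,rule Stage configurations; seeds inside
#'   `driver_cfg` / `rand_cfg` are overridden by `seed`.
#' @param genome_size_bp Genome size for FGA (required when `segments`
#'   given).
#' @param region,region_states Optional recurrent-CNA region
#'   (list with `chrom`, `start`, `end`) and its states.
#' @param ct_genes,ct_groups Target genes and `c(group, reference)` pair for
#'   the expression stage.
#' @param housekeeping Housekeeping genes for the expression stage.
#' @return Invisibly, a list of the per-stage results; side effect: TSVs and
#'   `manifest.json` under `outdir`.
#' @export
run_full_pipeline <- function(paths, outdir, seed = 1L,
                              driver_cfg = driver_config(),
                              rand_cfg = randomisation_config(),
                              rule = candidate_rule(),
                              genome_size_bp = NULL,
                              region = NULL,
                              region_states = c("loss", "cn_loh"),
                              ct_genes = NULL,
                              ct_groups = c("tumour", "normal"),
                              housekeeping = c("GAPDH", "ACTB")) {
  for (p in unlist(paths)) {
    if (!file.exists(p)) abort_usage("input file does not exist: {p}")
  }
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  driver_cfg$seed <- as.integer(seed)
  rand_cfg$seed <- as.integer(seed)
  results <- list()
  row_counts <- list()

  vt <- read_variant_table(paths$variants, paths$sheet)
  variants <- vt$variants
  sheet <- vt$sheet
  models <- if (!is.null(paths$models)) read_gene_models(paths$models) else NULL
  subtypes <- sort(unique(sheet$subtype))
  if (length(subtypes) != 2) {
    abort_usage("pipeline expects exactly two subtypes; sheet has {length(subtypes)}")
  }

  scans <- purrr::map(subtypes, function(s) {
    run_driver_scan(variants, sheet, models, driver_cfg, subtype = s)
  })
  names(scans) <- subtypes
  for (s in subtypes) {
    write_stage_tsv(scans[[s]]$results, outdir, paste0("drivers_", s))
    write_stage_tsv(scans[[s]]$skipped, outdir, paste0("drivers_skipped_", s))
    row_counts[[paste0("drivers_", s)]] <- nrow(scans[[s]]$results)
  }
  results$scans <- scans

  candidates <- select_candidates(scans[[1]], scans[[2]], rule)
  write_stage_tsv(candidates, outdir, "candidates")
  row_counts$candidates <- nrow(candidates)
  results$candidates <- candidates

  if (nrow(candidates) > 0) {
    rand <- randomisation_test(variants, sheet, candidates, models,
                               driver_cfg, rand_cfg)
    write_stage_tsv(tidy(rand), outdir, "randomisation")
    null_long <- rand$results %>%
      select("gene", "candidate_subtype", "null_sigs") %>%
      tidyr::unnest("null_sigs") %>%
      group_by(.data$gene, .data$candidate_subtype) %>%
      mutate(iteration = dplyr::row_number()) %>%
      ungroup()
    write_stage_tsv(null_long, outdir, "randomisation_null")
    row_counts$randomisation <- nrow(rand$results)
    results$randomisation <- rand
  }

  if (!is.null(paths$gene_sets)) {
    gene_sets <- read_gmt(paths$gene_sets)
    pw <- purrr::map(subtypes, function(s) {
      run_pathway_scan(variants, sheet, gene_sets, driver_cfg, subtype = s)
    })
    names(pw) <- subtypes
    for (s in subtypes) {
      write_stage_tsv(pw[[s]]$results, outdir, paste0("pathways_", s))
    }
    comparison <- compare_subtypes(pw[[1]], pw[[2]])
    write_stage_tsv(comparison, outdir, "pathway_comparison")
    row_counts$pathway_comparison <- nrow(comparison)
    results$pathways <- pw
    results$pathway_comparison <- comparison
  }

  hotspots <- call_hotspots(variants)
  write_stage_tsv(mutate(hotspots,
                         samples = purrr::map_chr(.data$samples, paste, collapse = ",")),
                  outdir, "hotspots")
  row_counts$hotspots <- nrow(hotspots)
  results$hotspots <- hotspots

  if (!is.null(paths$domains) && !is.null(models)) {
    domains <- read_domains(paths$domains, models)
    dom_res <- purrr::pmap(domains, function(gene, domain_name, start_aa, end_aa) {
      if (!any(variants$gene == gene & is_nonsynonymous(variants$consequence) &
                 !is.na(variants$protein_pos))) return(NULL)
      plen <- models$protein_length_aa[match(gene, models$gene)]
      domain_cluster_test(variants, gene,
                          list(domain_name = domain_name, start_aa = start_aa,
                               end_aa = end_aa), plen)
    }) %>% bind_rows()
    write_stage_tsv(dom_res, outdir, "domain_clusters")
    row_counts$domain_clusters <- nrow(dom_res)
    results$domain_clusters <- dom_res
  }

  if (!is.null(paths$segments)) {
    if (is.null(genome_size_bp)) abort_usage("genome_size_bp is required with segments input")
    segs <- read_segments(paths$segments)
    burden <- fraction_genome_altered(segs, genome_size_bp)
    write_stage_tsv(burden, outdir, "cna_burden")
    row_counts$cna_burden <- nrow(burden)
    results$cna_burden <- burden
    if (!is.null(region)) {
      event <- count_recurrent_event(segs, sheet, region, region_states)
      write_stage_tsv(event, outdir, "cna_recurrent_event")
      results$cna_event <- event
    }
  }

  if (!is.null(paths$ct) && !is.null(ct_genes)) {
    ct <- read_ct_table(paths$ct, housekeeping)
    folds <- purrr::map(ct_genes, function(g) {
      ddct_fold_change(ct, g, ct_groups[1], ct_groups[2], housekeeping)
    }) %>% bind_rows()
    write_stage_tsv(folds, outdir, "expression_folds")
    row_counts$expression_folds <- nrow(folds)
    results$expression <- folds
  }

  manifest <- list(
    tool = "splitsig",
    version = as.character(utils::packageVersion("splitsig")),
    seed = as.integer(seed),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = purrr::map(paths, ~ unname(tools::md5sum(.x))),
    row_counts = row_counts,
    config = list(method = driver_cfg$method,
                  n_null_draws = driver_cfg$n_null_draws,
                  n_iter = rand_cfg$n_iter,
                  q_sig = rule$q_sig, q_nonsig = rule$q_nonsig)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(results)
}
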