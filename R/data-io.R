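# Readers and writers for the tabular formats the pipeline consumes.
#
# All readers are thin wrappers over readr with strict validation: a malformed
# row is an error naming the offending field, never a silently dropped row.
# `#`-prefixed comment lines are accepted everywhere.

read_tsv_strict <- function(path, col_types) {
  if (!file.exists(path)) {
    abort_usage("input file does not exist: {path}")
  }
  readr::read_tsv(path, comment = "#", col_types = col_types,
                  progress = FALSE, na = c("", "NA"))
}

#' Read a sample sheet
#'
#' A sample sheet maps each tumour sample to its subtype label (the study
#' design this package targets used two histological subtypes, morphoeic and
#' nodular basal cell carcinoma, but labels are arbitrary strings).
#'
#' @param path Tab-separated file with columns `sample_id`, `subtype`.
#' @return A tibble with columns `sample_id`, `subtype`.
#' @export
read_sample_sheet <- function(path) {
  sheet <- read_tsv_strict(path, readr::cols(.default = readr::col_character()))
  require_columns(sheet, c("sample_id", "subtype"), "sample sheet")
  sheet <- select(sheet, "sample_id", "subtype")
  validate_sample_sheet(sheet)
}

#' Validate a sample sheet tibble
#'
#' @param sheet Tibble with columns `sample_id`, `subtype`.
#' @return The validated tibble, invisibly unchanged.
#' @export
validate_sample_sheet <- function(sheet) {
  require_columns(sheet, c("sample_id", "subtype"), "sample sheet")
  if (anyDuplicated(sheet$sample_id)) {
    dup <- unique(sheet$sample_id[duplicated(sheet$sample_id)])
    abort_consistency("duplicated sample_id(s) in sample sheet: {paste(dup, collapse = ', ')}")
  }
  if (any(is.na(sheet$sample_id)) || any(is.na(sheet$subtype))) {
    abort_format("sample sheet contains missing sample_id or subtype values")
  }
  sheet
}

#' Read an annotated somatic-variant table
#'
#' The variant table is a flat MAF-inspired TSV with one row per somatic
#' variant: `sample_id`, `gene`, optional `chrom` / `genomic_pos` /
#' `protein_pos` (1-based residue), a `consequence` class, and optional
#' `sift` / `polyphen` scores in \[0, 1\] (SIFT: lower is more damaging;
#' PolyPhen: higher is more damaging). Every variant's sample must appear in
#' the sample sheet; the sheet's subtype label is joined onto each row.
#'
#' @param path_variants Variant TSV path.
#' @param path_sheet Sample-sheet TSV path (see [read_sample_sheet()]).
#' @return A list with elements `variants` (tibble, one row per variant, with
#'   a `subtype` column joined on) and `sheet` (the sample-sheet tibble).
#' @export
read_variant_table <- function(path_variants, path_sheet) {
  sheet <- read_sample_sheet(path_sheet)
  types <- readr::cols(
    sample_id = readr::col_character(),
    gene = readr::col_character(),
    chrom = readr::col_character(),
    genomic_pos = readr::col_double(),
    protein_pos = readr::col_double(),
    consequence = readr::col_character(),
    sift = readr::col_double(),
    polyphen = readr::col_double()
  )
  raw <- read_tsv_strict(path_variants, types)
  require_columns(raw, c("sample_id", "gene", "consequence"), "variant table")
  for (col in c("chrom", "genomic_pos", "protein_pos", "sift", "polyphen")) {
    if (!col %in% names(raw)) raw[[col]] <- NA
  }
  variants <- raw %>%
    select("sample_id", "gene", "chrom", "genomic_pos", "protein_pos",
           "consequence", "sift", "polyphen") %>%
    mutate(genomic_pos = as.integer(.data$genomic_pos),
           protein_pos = as.integer(.data$protein_pos),
           chrom = as.character(.data$chrom),
           sift = as.double(.data$sift),
           polyphen = as.double(.data$polyphen))
  variants <- validate_variants(variants, sheet = sheet)
  list(variants = left_join(variants, sheet, by = "sample_id"), sheet = sheet)
}

#' Validate a variant tibble
#'
#' Checks the consequence enumeration, score ranges, positive positions, and
#' (optionally) membership of every sample in a sheet and of every
#' `protein_pos` within the gene's protein length.
#'
#' @param variants Variant tibble.
#' @param sheet Optional sample sheet; when given, unknown samples are an error.
#' @param models Optional gene-model tibble (see [read_gene_models()]); when
#'   given, `protein_pos` beyond the protein length is an error.
#' @return The validated variant tibble.
#' @export
validate_variants <- function(variants, sheet = NULL, models = NULL) {
  require_columns(variants, c("sample_id", "gene", "consequence"), "variant table")
  bad_cons <- setdiff(unique(variants$consequence), consequence_levels)
  if (length(bad_cons) > 0) {
    abort_format("unknown consequence value(s): {paste(bad_cons, collapse = ', ')} (allowed: {paste(consequence_levels, collapse = ', ')})")
  }
  for (col in c("sift", "polyphen")) {
    if (col %in% names(variants)) {
      v <- variants[[col]]
      if (any(!is.na(v) & (v < 0 | v > 1))) {
        abort_range("column '{col}' contains values outside [0, 1]")
      }
    }
  }
  for (col in c("genomic_pos", "protein_pos")) {
    if (col %in% names(variants)) {
      v <- variants[[col]]
      if (any(!is.na(v) & v < 1)) abort_range("column '{col}' must be >= 1")
    }
  }
  if (!is.null(sheet)) {
    unknown <- setdiff(unique(variants$sample_id), sheet$sample_id)
    if (length(unknown) > 0) {
      abort_consistency("variant sample(s) absent from sample sheet: {paste(unknown, collapse = ', ')}")
    }
  }
  if (!is.null(models) && "protein_pos" %in% names(variants)) {
    joined <- variants %>%
      filter(!is.na(.data$protein_pos)) %>%
      left_join(select(models, "gene", "protein_length_aa"), by = "gene") %>%
      filter(!is.na(.data$protein_length_aa),
             .data$protein_pos > .data$protein_length_aa)
    if (nrow(joined) > 0) {
      abort_range("protein_pos exceeds protein length for gene(s): {paste(unique(joined$gene), collapse = ', ')}")
    }
  }
  variants
}

#' Write a variant tibble to TSV
#'
#' @param variants Variant tibble (a joined `subtype` column is dropped).
#' @param path Output path.
#' @export
write_variant_table <- function(variants, path) {
  out <- variants
  out$subtype <- NULL
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a gene-model table
#'
#' @param path TSV with columns `gene`, `coding_length_bp`, `protein_length_aa`.
#' @return A tibble with one row per gene.
#' @export
read_gene_models <- function(path) {
  types <- readr::cols(gene = readr::col_character(),
                       coding_length_bp = readr::col_double(),
                       protein_length_aa = readr::col_double())
  models <- read_tsv_strict(path, types)
  require_columns(models, c("gene", "coding_length_bp", "protein_length_aa"), "gene model table")
  if (any(models$coding_length_bp < 1) || any(models$protein_length_aa < 1)) {
    abort_range("gene model lengths must be positive")
  }
  if (anyDuplicated(models$gene)) {
    abort_consistency("duplicated gene(s) in gene model table")
  }
  mutate(models,
         coding_length_bp = as.integer(.data$coding_length_bp),
         protein_length_aa = as.integer(.data$protein_length_aa))
}

#' Read a protein-domain annotation table
#'
#' Domains are 1-based inclusive residue intervals, e.g. the filamin repeat
#' 24 of FLNB.
#'
#' @param path TSV with columns `gene`, `domain_name`, `start_aa`, `end_aa`.
#' @param models Optional gene models; when given, a domain end beyond the
#'   protein length is an error.
#' @return Tibble of domain annotations.
#' @export
read_domains <- function(path, models = NULL) {
  types <- readr::cols(gene = readr::col_character(),
                       domain_name = readr::col_character(),
                       start_aa = readr::col_double(),
                       end_aa = readr::col_double())
  domains <- read_tsv_strict(path, types)
  require_columns(domains, c("gene", "domain_name", "start_aa", "end_aa"), "domain table")
  if (any(domains$start_aa < 1)) abort_range("domain start_aa must be >= 1")
  if (any(domains$end_aa < domains$start_aa)) {
    abort_range("domain end_aa must be >= start_aa")
  }
  domains <- mutate(domains, start_aa = as.integer(.data$start_aa),
                    end_aa = as.integer(.data$end_aa))
  if (!is.null(models)) {
    bad <- domains %>%
      left_join(select(models, "gene", "protein_length_aa"), by = "gene") %>%
      filter(!is.na(.data$protein_length_aa),
             .data$end_aa > .data$protein_length_aa)
    if (nrow(bad) > 0) {
      abort_range("domain extends past protein end for gene(s): {paste(unique(bad$gene), collapse = ', ')}")
    }
  }
  domains
}

#' Read a GMT gene-set file
#'
#' Standard MSigDB-style GMT dialect: one pathway per line, tab-separated as
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a set
#' are collapsed (set semantics).
#'
#' @param path GMT file path.
#' @return A long tibble with columns `pathway`, `gene`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort_usage("input file does not exist: {path}")
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0) abort_format("GMT file contains no gene sets")
  parsed <- purrr::map(lines, function(line) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      abort_format("GMT line has fewer than 3 fields (name, description, >=1 gene): '{substr(line, 1, 60)}'")
    }
    genes <- unique(parts[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) abort_format("GMT gene set '{parts[1]}' is empty")
    tibble(pathway = parts[1], gene = genes)
  })
  sets <- bind_rows(parsed)
  if (anyDuplicated(unique(select(sets, "pathway"))$pathway)) sets <- distinct(sets)
  sets
}

#' Read CNA segments (SEG-style TSV)
#'
#' Coordinates are 1-based inclusive. Segment states are `neutral`, `loss`,
#' `gain` or `cn_loh` (copy-neutral loss of heterozygosity). Overlapping
#' segments on one chromosome of one sample are rejected.
#'
#' @param path TSV with columns `sample_id`, `chrom`, `start`, `end`, `state`.
#' @return Tibble of validated segments.
#' @export
read_segments <- function(path) {
  types <- readr::cols(sample_id = readr::col_character(),
                       chrom = readr::col_character(),
                       start = readr::col_double(),
                       end = readr::col_double(),
                       state = readr::col_character())
  segs <- read_tsv_strict(path, types)
  require_columns(segs, c("sample_id", "chrom", "start", "end", "state"), "segment table")
  validate_segments(mutate(segs, start = as.integer(.data$start),
                           end = as.integer(.data$end)))
}

#' Validate a segment tibble
#'
#' @param segs Segment tibble as returned by [read_segments()].
#' @return The validated tibble.
#' @export
validate_segments <- function(segs) {
  require_columns(segs, c("sample_id", "chrom", "start", "end", "state"), "segment table")
  bad_state <- setdiff(unique(segs$state), segment_states)
  if (length(bad_state) > 0) {
    abort_format("unknown segment state(s): {paste(bad_state, collapse = ', ')} (allowed: {paste(segment_states, collapse = ', ')})")
  }
  if (any(segs$start < 1)) abort_range("segment start must be >= 1")
  if (any(segs$start > segs$end)) {
    bad <- segs[segs$start > segs$end, ]
    abort_range("segment start > end for sample {bad$sample_id[1]} at {bad$chrom[1]}:{bad$start[1]}-{bad$end[1]}")
  }
  overlaps <- segs %>%
    group_by(.data$sample_id, .data$chrom) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    summarise(has_overlap = any(.data$start[-1] <= .data$end[-n()]) && n() > 1,
              .groups = "drop") %>%
    filter(.data$has_overlap)
  if (nrow(overlaps) > 0) {
    abort_consistency("overlapping segments for sample {overlaps$sample_id[1]} on {overlaps$chrom[1]}")
  }
  segs
}

#' Write a segment tibble to TSV
#' @param segs Segment tibble.
#' @param path Output path.
#' @export
write_segments <- function(segs, path) {
  readr::write_tsv(segs, path)
  invisible(path)
}

#' Read a qPCR Ct table
#'
#' One row per well: experimental `group`, biological/technical `replicate_id`,
#' `gene`, and the raw threshold-cycle value `ct`. Every (group, replicate)
#' must carry a Ct for every housekeeping gene so that normalisation is
#' defined.
#'
#' @param path TSV with columns `group`, `replicate_id`, `gene`, `ct`.
#' @param housekeeping Character vector of housekeeping gene symbols whose
#'   presence per replicate is enforced (default GAPDH and ACTB, the usual
#'   GAPDH / beta-actin pair).
#' @return Tibble of Ct values.
#' @export
read_ct_table <- function(path, housekeeping = c("GAPDH", "ACTB")) {
  types <- readr::cols(group = readr::col_character(),
                       replicate_id = readr::col_character(),
                       gene = readr::col_character(),
                       ct = readr::col_double())
  ct <- read_tsv_strict(path, types)
  require_columns(ct, c("group", "replicate_id", "gene", "ct"), "Ct table")
  validate_ct_table(ct, housekeeping)
}

#' Validate a Ct table
#' @param ct Ct tibble.
#' @param housekeeping Housekeeping gene symbols that must be present for
#'   every (group, replicate); use `character()` to skip the check.
#' @return The validated tibble.
#' @export
validate_ct_table <- function(ct, housekeeping = c("GAPDH", "ACTB")) {
  require_columns(ct, c("group", "replicate_id", "gene", "ct"), "Ct table")
  if (any(is.na(ct$ct)) || any(ct$ct <= 0)) {
    abort_range("Ct values must be positive and non-missing")
  }
  if (length(housekeeping) > 0) {
    missing_hk <- ct %>%
      distinct(.data$group, .data$replicate_id) %>%
      tidyr::crossing(gene = housekeeping) %>%
      dplyr::anti_join(ct, by = c("group", "replicate_id", "gene"))
    if (nrow(missing_hk) > 0) {
      abort_consistency(paste0(
        "missing housekeeping Ct for ", missing_hk$group[1], "/",
        missing_hk$replicate_id[1], " gene ", missing_hk$gene[1]))
    }
  }
  ct
}

#' Write a Ct tibble to TSV
#' @param ct Ct tibble.
#' @param path Output path.
#' @export
write_ct_table <- function(ct, path) {
  readr::write_tsv(ct, path)
  invisible(path)
}
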