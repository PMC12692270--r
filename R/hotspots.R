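# Recurrent-residue hotspots and protein-domain mutational clustering.

#' Call recurrent-residue hotspots
#'
#' A hotspot is a single protein residue carrying nonsynonymous variants in
#' at least `min_samples` distinct samples (a sample mutated twice at the
#' same residue counts once). The motivating observation is of the
#' FLNB-P2586S type: one residue hit independently in three tumours of the
#' same subtype.
#'
#' @param variants Variant tibble; rows without `protein_pos` are ignored.
#' @param gene Optional gene symbol to restrict to; default scans all genes.
#' @param min_samples Minimum number of distinct mutated samples (default 2).
#' @return Tibble: `gene`, `residue`, `n_samples`, `samples` (list-column of
#'   sample ids), sorted by decreasing recurrence.
#' @export
call_hotspots <- function(variants, gene = NULL, min_samples = 2) {
  v <- filter(variants, is_nonsynonymous(.data$consequence), !is.na(.data$protein_pos))
  if (!is.null(gene)) v <- filter(v, .data$gene == !!gene)
  if (nrow(v) == 0) {
    return(tibble(gene = character(), residue = integer(),
                  n_samples = integer(), samples = list()))
  }
  v %>%
    distinct(.data$gene, .data$protein_pos, .data$sample_id) %>%
    group_by(.data$gene, residue = .data$protein_pos) %>%
    summarise(n_samples = n(), samples = list(sort(.data$sample_id)),
              .groups = "drop") %>%
    filter(.data$n_samples >= min_samples) %>%
    arrange(dplyr::desc(.data$n_samples), .data$gene, .data$residue)
}

#' Test a protein domain for mutational clustering
#'
#' Under a uniform-placement null, each of a gene's m positioned variants
#' lands inside a domain of length d (on a protein of length L) with
#' probability d/L independently, so the in-domain count is
#' Binomial(m, d/L). The reported p is the upper tail `P(X >= k)` for the
#' observed in-domain count k — the chance that uniformly placed variants
#' cluster in the domain at least this strongly.
#'
#' @param variants Variant tibble.
#' @param gene Gene symbol.
#' @param domain One-row tibble (or list) with `domain_name`, `start_aa`,
#'   `end_aa` (1-based inclusive).
#' @param protein_len Protein length in residues.
#' @return One-row tibble: `gene`, `domain_name`, `k_in_domain`, `m_total`,
#'   `domain_len_aa`, `protein_len_aa`, `p`.
#' @export
domain_cluster_test <- function(variants, gene, domain, protein_len) {
  if (protein_len <= 0) abort_usage("protein_len must be positive")
  if (domain$end_aa < domain$start_aa) abort_range("domain end_aa < start_aa")
  if (domain$end_aa > protein_len) abort_range("domain extends past the protein end")
  v <- filter(variants, .data$gene == !!gene,
              is_nonsynonymous(.data$consequence), !is.na(.data$protein_pos))
  m <- nrow(v)
  if (m < 1) abort_usage("gene {gene} has no positioned nonsynonymous variants")
  domain_len <- domain$end_aa - domain$start_aa + 1
  k <- sum(v$protein_pos >= domain$start_aa & v$protein_pos <= domain$end_aa)
  p <- if (k == 0) 1 else pbinom(k - 1, m, domain_len / protein_len, lower.tail = FALSE)
  tibble(gene = gene,
         domain_name = domain$domain_name %||% NA_character_,
         k_in_domain = k, m_total = m,
         domain_len_aa = as.integer(domain_len),
         protein_len_aa = as.integer(protein_len),
         p = p)
}

#' Lollipop-style plot of per-residue mutation recurrence
#'
#' @param variants Variant tibble.
#' @param gene Gene symbol.
#' @param protein_len Protein length (x-axis extent).
#' @param domains Optional domain tibble for this gene; drawn as shaded
#'   intervals.
#' @return A ggplot.
#' @export
plot_lollipop <- function(variants, gene, protein_len, domains = NULL) {
  v <- variants %>%
    filter(.data$gene == !!gene, is_nonsynonymous(.data$consequence),
           !is.na(.data$protein_pos)) %>%
    distinct(.data$protein_pos, .data$sample_id) %>%
    count(.data$protein_pos, name = "n_samples")
  p <- ggplot2::ggplot(v, ggplot2::aes(x = .data$protein_pos, y = .data$n_samples))
  if (!is.null(domains) && nrow(domains) > 0) {
    p <- p + ggplot2::geom_rect(
      data = domains,
      ggplot2::aes(xmin = .data$start_aa, xmax = .data$end_aa,
                   ymin = -Inf, ymax = Inf, fill = .data$domain_name),
      alpha = 0.25, inherit.aes = FALSE)
  }
  p +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$protein_pos, yend = 0)) +
    ggplot2::geom_point(size = 2, colour = "firebrick") +
    ggplot2::xlim(0, protein_len) +
    ggplot2::labs(x = "protein residue", y = "mutated samples",
                  title = gene) +
    ggplot2::theme_minimal()
}
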