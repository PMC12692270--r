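# Relative quantification of qPCR data by the Livak 2^-ddCt method.

#' Relative expression by 2^-ddCt
#'
#' Per replicate, the target gene's Ct is normalised to the arithmetic mean
#' of the housekeeping Cts — on the linear scale this is exactly the
#' geometric mean of housekeeping expression, the usual multi-reference
#' normalisation. Each replicate's dCt is then referenced to the mean dCt of
#' the reference group (ddCt), and `2^-ddCt` converts to fold change. The
#' summary fold is `2^-(mean ddCt)` (the geometric mean of per-replicate
#' folds, the standard Livak convention), and the group comparison is an
#' unpaired two-tailed t-test on the dCt values (variance-stabilised scale).
#'
#' @param ct Ct tibble (see [read_ct_table()]).
#' @param gene Target gene symbol.
#' @param group Group whose expression is quantified.
#' @param reference_group Group used as the ddCt calibrator.
#' @param housekeeping Housekeeping gene symbols (default GAPDH, ACTB).
#' @param var_equal Use the classical equal-variance Student t-test
#'   (default `TRUE`); set `FALSE` for the Welch variant.
#' @return One-row tibble: `gene`, `group`, `reference_group`, `mean_fold`,
#'   `per_replicate_folds` (list-column), `n_replicates`, `p` (`NA` when a
#'   group has a single replicate).
#' @export
ddct_fold_change <- function(ct, gene, group, reference_group,
                             housekeeping = c("GAPDH", "ACTB"),
                             var_equal = TRUE) {
  validate_ct_table(ct, housekeeping)
  groups <- c(group, reference_group)
  missing_grp <- setdiff(groups, unique(ct$group))
  if (length(missing_grp) > 0) {
    abort_usage("group(s) not present in Ct table: {paste(missing_grp, collapse = ', ')}")
  }
  dct <- ct %>%
    filter(.data$group %in% groups) %>%
    group_by(.data$group, .data$replicate_id) %>%
    summarise(ct_target = {
      v <- .data$ct[.data$gene == !!gene]
      if (length(v) == 0) NA_real_ else mean(v)
    },
    ct_hk = mean(.data$ct[.data$gene %in% housekeeping]),
    .groups = "drop") %>%
    mutate(dct = .data$ct_target - .data$ct_hk)
  if (any(is.na(dct$ct_target))) {
    bad <- dct[is.na(dct$ct_target), ]
    abort_consistency("gene {gene} has no Ct for {bad$group[1]}/{bad$replicate_id[1]}")
  }
  dct_grp <- dct$dct[dct$group == group]
  dct_ref <- dct$dct[dct$group == reference_group]
  ddct <- dct_grp - mean(dct_ref)
  folds <- 2^(-ddct)
  mean_fold <- 2^(-mean(ddct))
  p <- if (identical(group, reference_group)) {
    1
  } else if (length(dct_grp) >= 2 && length(dct_ref) >= 2) {
    # zero-variance dCt (e.g. noiseless synthetic data) leaves the t
    # statistic undefined; report NA rather than fail
    tryCatch(t.test(dct_grp, dct_ref, var.equal = var_equal)$p.value,
             error = function(e) NA_real_)
  } else {
    NA_real_
  }
  tibble(gene = gene, group = group, reference_group = reference_group,
         mean_fold = mean_fold,
         per_replicate_folds = list(folds),
         n_replicates = length(dct_grp),
         p = p)
}
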