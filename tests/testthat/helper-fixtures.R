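# Small in-code fixtures shared across the suite.

make_sheet <- function(n_a = 2, n_b = 2, labels = c("morphoeic", "nodular")) {
  tibble::tibble(
    sample_id = c(sprintf("M%02d", seq_len(n_a)), sprintf("N%02d", seq_len(n_b))),
    subtype = rep(labels, c(n_a, n_b)))
}

# build a variant tibble from compact per-variant arguments
make_variants <- function(sample_id, gene, consequence = "missense",
                          sift = NA_real_, polyphen = NA_real_,
                          protein_pos = NA_integer_, genomic_pos = NA_integer_,
                          chrom = NA_character_, sheet = NULL) {
  v <- tibble::tibble(sample_id = sample_id, gene = gene, chrom = chrom,
                      genomic_pos = as.integer(genomic_pos),
                      protein_pos = as.integer(protein_pos),
                      consequence = consequence,
                      sift = sift, polyphen = polyphen)
  if (!is.null(sheet)) v <- dplyr::left_join(v, sheet, by = "sample_id")
  v
}

# variants whose combined impact is exactly `impact` (sift/polyphen agree)
make_impact_variants <- function(sample_id, gene, impact, sheet = NULL, ...) {
  make_variants(sample_id, gene, consequence = "missense",
                sift = 1 - impact, polyphen = impact, sheet = sheet, ...)
}

write_fixture_tsv <- function(df, name) {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  readr::write_tsv(df, path)
  path
}

# independent brute-force BH step-up (oracle for bh_fdr)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# independent binomial upper-tail by log-space term summation (oracle for
# recurrence_test and domain_cluster_test); sums P(X = i) for i in k..n
binom_upper_tail_oracle <- function(k, n, pr) {
  if (k <= 0) return(1)
  i <- k:n
  terms <- exp(lchoose(n, i) + i * log(pr) + (n - i) * log1p(-pr))
  sum(terms)
}
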