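# Internal helpers shared across modules.

consequence_levels <- c("missense", "nonsense", "splice_site", "synonymous", "other")
segment_states <- c("neutral", "loss", "gain", "cn_loh")

abort_format <- function(msg, ...) {
  abort(glue::glue(msg, ..., .envir = parent.frame()),
        class = c("splitsig_format_error", "splitsig_error"))
}

abort_consistency <- function(msg, ...) {
  abort(glue::glue(msg, ..., .envir = parent.frame()),
        class = c("splitsig_consistency_error", "splitsig_error"))
}

abort_range <- function(msg, ...) {
  abort(glue::glue(msg, ..., .envir = parent.frame()),
        class = c("splitsig_range_error", "splitsig_error"))
}

abort_usage <- function(msg, ...) {
  abort(glue::glue(msg, ..., .envir = parent.frame()),
        class = c("splitsig_usage_error", "splitsig_error"))
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort_format("{what} is missing required column(s): {paste(missing, collapse = ', ')}")
  }
  invisible(df)
}

#' Derive a reproducible child seed from a master seed
#'
#' Mixes a master seed with one or more integer indices (gene rank, iteration
#' number, ...) through a Lehmer-style multiplicative congruence so that every
#' unit of work in a scan or randomisation run gets its own stable seed. The
#' result is always a non-negative integer below 2^31, independent of the
#' order in which work units are executed.
#'
#' @param seed Master integer seed.
#' @param ... Integer indices identifying the work unit.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  x <- (as.double(seed) %% 2147483647) + 1
  for (i in idx) {
    x <- (x * 48271 + as.double(i) + 1) %% 2147483647
  }
  as.integer(x)
}

# Canonical variant ordering: results of seeded resampling must not depend on
# the row order of the input file.
canonical_variant_order <- function(variants) {
  variants %>%
    arrange(.data$sample_id, .data$gene,
            is.na(.data$genomic_pos), .data$genomic_pos,
            is.na(.data$protein_pos), .data$protein_pos)
}

is_nonsynonymous <- function(consequence) consequence != "synonymous"
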