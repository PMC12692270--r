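# Copy-number burden and recurrent-event summaries.

#' Fraction of genome altered per sample
#'
#' Sums the length of every non-neutral segment (losses, gains and — by
#' default — copy-neutral LOH, which is allelically altered even though the
#' net copy number is unchanged) and expresses it as a percentage of the
#' genome size.
#'
#' @param segs Segment tibble (all samples; see [read_segments()]).
#' @param genome_size_bp Denominator genome size in bp.
#' @param altered_states Segment states counted as altered
#'   (default loss, gain, cn_loh).
#' @return Tibble: `sample_id`, `bp_altered`, `fga_percent`.
#' @export
fraction_genome_altered <- function(segs, genome_size_bp,
                                    altered_states = c("loss", "gain", "cn_loh")) {
  if (is.null(genome_size_bp) || genome_size_bp <= 0) {
    abort_usage("genome_size_bp must be positive")
  }
  validate_segments(segs)
  segs %>%
    group_by(.data$sample_id) %>%
    summarise(bp_altered = sum((as.double(.data$end) - .data$start + 1) *
                                 (.data$state %in% altered_states)),
              .groups = "drop") %>%
    mutate(fga_percent = 100 * .data$bp_altered / as.double(genome_size_bp))
}

#' Count a recurrent CNA event per subtype
#'
#' A sample carries the event when its segments in the listed states cover at
#' least `min_overlap_frac` of the region (e.g. "chromosome 9q loss or
#' cn-LOH"). Counts are reported per subtype.
#'
#' @param segs Segment tibble (all samples).
#' @param sheet Sample sheet.
#' @param region List or one-row data frame with `chrom`, `start`, `end`.
#' @param states Segment states that constitute the event
#'   (e.g. `c("loss", "cn_loh")`).
#' @param min_overlap_frac Minimum fraction of the region that must be
#'   covered (default 0.5).
#' @return Tibble: `subtype`, `n_samples`, `n_with_event`; per-sample detail
#'   in `attr(, "per_sample")`.
#' @export
count_recurrent_event <- function(segs, sheet, region, states,
                                  min_overlap_frac = 0.5) {
  validate_sample_sheet(sheet)
  validate_segments(segs)
  if (min_overlap_frac <= 0 || min_overlap_frac > 1) {
    abort_range("min_overlap_frac must lie in (0, 1]")
  }
  unknown <- setdiff(unique(segs$sample_id), sheet$sample_id)
  if (length(unknown) > 0) {
    abort_consistency("segment sample(s) absent from sample sheet: {paste(unknown, collapse = ', ')}")
  }
  bad_state <- setdiff(states, segment_states)
  if (length(bad_state) > 0) abort_format("unknown event state(s): {paste(bad_state, collapse = ', ')}")
  region_len <- as.double(region$end) - region$start + 1
  if (region_len <= 0) abort_range("region end must be >= start")

  # segments within a sample/chromosome never overlap, so overlaps sum freely
  covered <- segs %>%
    filter(.data$chrom == region$chrom, .data$state %in% states) %>%
    mutate(ov = pmax(0, pmin(as.double(.data$end), as.double(region$end)) -
                       pmax(as.double(.data$start), as.double(region$start)) + 1)) %>%
    group_by(.data$sample_id) %>%
    summarise(bp_covered = sum(.data$ov), .groups = "drop")

  per_sample <- sheet %>%
    left_join(covered, by = "sample_id") %>%
    mutate(bp_covered = dplyr::coalesce(.data$bp_covered, 0),
           has_event = .data$bp_covered >= min_overlap_frac * region_len)

  counts <- per_sample %>%
    group_by(.data$subtype) %>%
    summarise(n_samples = n(), n_with_event = sum(.data$has_event),
              .groups = "drop")
  structure(counts, per_sample = per_sample,
            region = region, states = states,
            class = class(counts))
}

#' Bar plot of per-sample CNA burden
#'
#' @param burden Tibble from [fraction_genome_altered()].
#' @param sheet Optional sample sheet to colour bars by subtype.
#' @return A ggplot.
#' @export
plot_fga <- function(burden, sheet = NULL) {
  if (!is.null(sheet)) burden <- left_join(burden, sheet, by = "sample_id")
  p <- ggplot2::ggplot(burden,
                       ggplot2::aes(x = stats::reorder(.data$sample_id, -.data$fga_percent),
                                    y = .data$fga_percent))
  if (!is.null(sheet)) {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = .data$subtype))
  } else {
    p <- p + ggplot2::geom_col(fill = "grey40")
  }
  p + ggplot2::labs(x = NULL, y = "% genome altered",
                    title = "Copy-number burden per sample") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
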