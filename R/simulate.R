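# Synthetic two-subtype cohorts with planted signal.
#
# The generator produces every input the pipeline consumes — variant tables,
# sample sheets, gene models, segments, Ct tables — with the statistical
# structure the analysis assumes: Poisson passenger mutations at a per-base
# rate with uninformative (uniform) impact scores, plus explicitly planted
# drivers, hotspots, copy-number events and expression fold changes whose
# recovery the tests measure.

#' Specify a planted driver gene
#'
#' @param gene Gene symbol (must exist in the catalogue).
#' @param subtypes Subtype label(s) whose samples carry the driver signal
#'   (one label = subtype-specific, both = shared).
#' @param rate_multiplier Multiplies the gene's passenger rate in carrier
#'   subtypes (>= 1).
#' @param impact_shift Amount in \[0, 1\] added to the mean of the impact
#'   score distribution of the gene's variants in carrier subtypes
#'   (scores truncated to \[0, 1\]).
#' @return A `driver_spec` list.
#' @export
driver_spec <- function(gene, subtypes, rate_multiplier = 1, impact_shift = 0) {
  if (rate_multiplier < 1) abort_range("rate_multiplier must be >= 1")
  if (impact_shift < 0 || impact_shift > 1) abort_range("impact_shift must lie in [0, 1]")
  structure(list(gene = gene, subtypes = subtypes,
                 rate_multiplier = rate_multiplier,
                 impact_shift = impact_shift),
            class = "driver_spec")
}

#' Rate multiplier that yields a target per-sample recurrence
#'
#' Under Poisson counts with per-base rate r and coding length L, a sample
#' carries at least one variant with probability `1 - exp(-m r L)`; solving
#' for the multiplier m that makes that probability equal `recurrence` gives
#' `m = -log(1 - recurrence) / (r L)`.
#'
#' @param recurrence Target probability in (0, 1) that a carrier-subtype
#'   sample is mutated.
#' @param background_rate Per-base per-sample passenger rate.
#' @param coding_length_bp Gene coding length.
#' @return The required rate multiplier.
#' @export
multiplier_for_recurrence <- function(recurrence, background_rate, coding_length_bp) {
  if (recurrence <= 0 || recurrence >= 1) abort_range("recurrence must lie in (0, 1)")
  -log(1 - recurrence) / (background_rate * coding_length_bp)
}

#' Build a default gene catalogue
#'
#' 200 genes with coding lengths drawn log-uniformly between 0.5 and 15 kb
#' (the span of typical human coding genes) and protein lengths of one third
#' the coding length.
#'
#' @param n_genes Number of genes (default 200).
#' @param length_range Coding-length range in bp (default 500-15000).
#' @param seed Integer seed.
#' @return Gene-model tibble.
#' @export
simulate_gene_catalogue <- function(n_genes = 200, length_range = c(500, 15000),
                                    seed = 1L) {
  lens <- withr::with_seed(seed,
    round(exp(runif(n_genes, log(length_range[1]), log(length_range[2])))))
  tibble(gene = sprintf("GENE%03d", seq_len(n_genes)),
         coding_length_bp = as.integer(lens),
         protein_length_aa = as.integer(pmax(1, floor(lens / 3))))
}

#' Configuration of the synthetic cohort
#'
#' Defaults mirror the study design the pipeline targets: two subtypes of 10
#' samples each, a 200-gene catalogue, and Poisson passenger mutations.
#'
#' @param n_samples_per_subtype Integer pair (default `c(10, 10)`).
#' @param subtypes Labels for the two subtypes
#'   (default `c("morphoeic", "nodular")`).
#' @param gene_catalogue Gene-model tibble. The default is the fixed
#'   [simulate_gene_catalogue()] universe: the gene catalogue is part of the
#'   study design and does not vary with the cohort seed.
#' @param background_rate Per-base per-sample nonsynonymous passenger rate
#'   (default 3e-6).
#' @param drivers List of [driver_spec()]s.
#' @param hotspot_specs List of lists with `gene`, `residue`, `n_samples`,
#'   `subtype`: plants a missense variant at that residue in that many
#'   samples of that subtype.
#' @param seed Integer master seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_samples_per_subtype = c(10L, 10L),
                              subtypes = c("morphoeic", "nodular"),
                              gene_catalogue = NULL,
                              background_rate = 3e-6,
                              drivers = list(),
                              hotspot_specs = list(),
                              seed = 1L) {
  if (length(n_samples_per_subtype) != 2 || any(n_samples_per_subtype < 1)) {
    abort_usage("n_samples_per_subtype must be two positive integers")
  }
  if (background_rate < 0) abort_range("background_rate must be >= 0")
  gene_catalogue <- gene_catalogue %||% simulate_gene_catalogue()
  bad <- setdiff(purrr::map_chr(drivers, "gene"), gene_catalogue$gene)
  if (length(bad) > 0) {
    abort_usage("driver gene(s) absent from catalogue: {paste(bad, collapse = ', ')}")
  }
  structure(list(n_samples_per_subtype = as.integer(n_samples_per_subtype),
                 subtypes = subtypes,
                 gene_catalogue = gene_catalogue,
                 background_rate = background_rate,
                 drivers = drivers,
                 hotspot_specs = hotspot_specs,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# consequence mix for simulated nonsynonymous variants
sim_consequence_probs <- c(missense = 0.85, nonsense = 0.10, splice_site = 0.05)

#' Simulate a two-subtype somatic variant cohort
#'
#' Per sample and gene, the variant count is Poisson(rate x coding length),
#' with the rate multiplied by any applicable [driver_spec()]. Passenger
#' impact scores are independent Uniform(0, 1) for SIFT and PolyPhen
#' (maximally uninformative, so any detected bias is planted, not a
#' distributional artefact); driver-gene variants in carrier subtypes have
#' their score means shifted by `impact_shift` (truncated to \[0, 1\]).
#' Consequences are drawn 85% missense / 10% nonsense / 5% splice-site;
#' every simulated variant carries SIFT and PolyPhen scores (independent
#' uniforms for passengers). Planted hotspots add a damaging missense variant at
#' a fixed residue in the requested number of subtype samples. Fully
#' deterministic given the config seed.
#'
#' @param cfg A [simulation_config()].
#' @return List with `variants` (tibble incl. `subtype`), `sheet`, `models`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  models <- cfg$gene_catalogue
  sheet <- tibble(
    sample_id = c(sprintf("%s_%02d", toupper(substr(cfg$subtypes[1], 1, 1)),
                          seq_len(cfg$n_samples_per_subtype[1])),
                  sprintf("%s_%02d", toupper(substr(cfg$subtypes[2], 1, 1)),
                          seq_len(cfg$n_samples_per_subtype[2]))),
    subtype = rep(cfg$subtypes, cfg$n_samples_per_subtype))
  if (anyDuplicated(sheet$sample_id)) {
    sheet$sample_id <- paste0(rep(c("A", "B"), cfg$n_samples_per_subtype), "_",
                              sheet$sample_id)
  }

  driver_mult <- function(gene, subtype) {
    m <- 1
    shift <- 0
    for (d in cfg$drivers) {
      if (d$gene == gene && subtype %in% d$subtypes) {
        m <- m * d$rate_multiplier
        shift <- max(shift, d$impact_shift)
      }
    }
    list(mult = m, shift = shift)
  }

  variants <- withr::with_seed(cfg$seed, {
    rows <- purrr::map(seq_len(nrow(sheet)), function(si) {
      sid <- sheet$sample_id[si]
      sub <- sheet$subtype[si]
      per_gene <- purrr::map(seq_len(nrow(models)), function(gi) {
        g <- models$gene[gi]
        L <- models$coding_length_bp[gi]
        ds <- driver_mult(g, sub)
        n <- rpois(1, cfg$background_rate * ds$mult * L)
        if (n == 0) return(NULL)
        cons <- sample(names(sim_consequence_probs), n, replace = TRUE,
                       prob = sim_consequence_probs)
        sift <- pmax(0, runif(n) - ds$shift)
        poly <- pmin(1, runif(n) + ds$shift)
        plen <- models$protein_length_aa[gi]
        ppos <- ifelse(cons == "splice_site", NA_integer_,
                       sample.int(plen, n, replace = TRUE))
        tibble(sample_id = sid, gene = g,
               chrom = paste0("chr", 1 + (gi %% 22)),
               genomic_pos = sample.int(L, n, replace = TRUE),
               protein_pos = as.integer(ppos),
               consequence = cons, sift = sift, polyphen = poly)
      })
      bind_rows(per_gene)
    })
    passenger <- bind_rows(rows)

    hot <- purrr::map(cfg$hotspot_specs, function(h) {
      pool <- sheet$sample_id[sheet$subtype == h$subtype]
      if (h$n_samples > length(pool)) {
        abort_usage("hotspot spec for {h$gene} asks for more samples than subtype {h$subtype} has")
      }
      carriers <- sort(sample(pool, h$n_samples))
      gi <- match(h$gene, models$gene)
      if (is.na(gi)) abort_usage("hotspot gene {h$gene} absent from catalogue")
      if (h$residue > models$protein_length_aa[gi]) {
        abort_range("hotspot residue beyond protein length for {h$gene}")
      }
      tibble(sample_id = carriers, gene = h$gene,
             chrom = paste0("chr", 1 + (gi %% 22)),
             genomic_pos = as.integer(h$residue * 3L),
             protein_pos = as.integer(h$residue),
             consequence = "missense",
             sift = 0.01, polyphen = 0.99)
    })
    bind_rows(passenger, bind_rows(hot))
  })
  if (nrow(variants) == 0) {
    variants <- tibble(sample_id = character(), gene = character(),
                       chrom = character(), genomic_pos = integer(),
                       protein_pos = integer(), consequence = character(),
                       sift = double(), polyphen = double())
  }
  variants <- canonical_variant_order(left_join(variants, sheet, by = "sample_id"))
  list(variants = variants, sheet = sheet, models = models)
}

#' Specify a planted copy-number event
#'
#' @param chrom,start,end Region coordinates (1-based inclusive).
#' @param state Segment state (`loss`, `gain`, `cn_loh`).
#' @param subtype Subtype whose samples receive the event.
#' @param n_samples Number of subtype samples that carry it.
#' @return A `cna_spec` list.
#' @export
cna_spec <- function(chrom, start, end, state, subtype, n_samples) {
  if (!state %in% segment_states) abort_format("unknown segment state '{state}'")
  if (start > end) abort_range("start > end in cna_spec")
  structure(list(chrom = chrom, start = as.integer(start), end = as.integer(end),
                 state = state, subtype = subtype, n_samples = as.integer(n_samples)),
            class = "cna_spec")
}

#' Simulate per-sample CNA segment profiles
#'
#' Every sample gets a whole-genome neutral backbone on each chromosome;
#' planted events carve their region out of the backbone for a seeded choice
#' of carrier samples, so planted burdens are exactly recoverable.
#'
#' @param sheet Sample sheet.
#' @param cna_specs List of [cna_spec()]s.
#' @param chrom_sizes Named integer vector of chromosome sizes; the default
#'   is a compact two-chromosome genome of 1e8 bp per chromosome.
#' @param seed Integer seed (selects carrier samples).
#' @return List with `segments` (tibble) and `genome_size_bp`.
#' @export
simulate_segments <- function(sheet, cna_specs = list(),
                              chrom_sizes = c(chr1 = 1e8, chr9 = 1e8),
                              seed = 1L) {
  validate_sample_sheet(sheet)
  genome_size <- sum(as.double(chrom_sizes))
  events <- withr::with_seed(seed, purrr::map(cna_specs, function(sp) {
    if (!sp$chrom %in% names(chrom_sizes)) {
      abort_usage("cna_spec chromosome {sp$chrom} not in chrom_sizes")
    }
    if (sp$end > chrom_sizes[[sp$chrom]]) {
      abort_range("cna_spec region extends past {sp$chrom}")
    }
    pool <- sheet$sample_id[sheet$subtype == sp$subtype]
    if (sp$n_samples > length(pool)) {
      abort_usage("cna_spec asks for more carriers than subtype {sp$subtype} has")
    }
    tibble(sample_id = sort(sample(pool, sp$n_samples)),
           chrom = sp$chrom, start = sp$start, end = sp$end, state = sp$state)
  }))
  events <- bind_rows(events)

  backbone <- tidyr::crossing(sample_id = sheet$sample_id,
                              chrom = names(chrom_sizes)) %>%
    mutate(size = as.integer(chrom_sizes[.data$chrom]))
  segments <- purrr::pmap(backbone, function(sample_id, chrom, size) {
    ev <- events[events$sample_id == sample_id & events$chrom == chrom, , drop = FALSE]
    ev <- ev[order(ev$start), , drop = FALSE]
    pieces <- list()
    cursor <- 1L
    for (i in seq_len(nrow(ev))) {
      if (ev$start[i] > cursor) {
        pieces[[length(pieces) + 1]] <- tibble(sample_id = sample_id, chrom = chrom,
                                               start = cursor, end = ev$start[i] - 1L,
                                               state = "neutral")
      }
      pieces[[length(pieces) + 1]] <- ev[i, c("sample_id", "chrom", "start", "end", "state")]
      cursor <- ev$end[i] + 1L
    }
    if (cursor <= size) {
      pieces[[length(pieces) + 1]] <- tibble(sample_id = sample_id, chrom = chrom,
                                             start = cursor, end = size,
                                             state = "neutral")
    }
    bind_rows(pieces)
  }) %>% bind_rows()
  list(segments = validate_segments(segments), genome_size_bp = genome_size)
}

#' Simulate a qPCR Ct table
#'
#' Each gene gets a baseline Ct in the reference group; a planted fold map
#' lowers the target group's Ct by log2(fold) (higher expression = earlier
#' threshold cycle). Independent Gaussian noise of sd `ct_noise_sd` is added
#' to every well, including the housekeeping wells, emulating pipetting and
#' amplification variability. With `ct_noise_sd = 0` the planted folds are
#' exactly recoverable by [ddct_fold_change()].
#'
#' @param genes Target gene symbols.
#' @param fold_map Named numeric vector: fold change (group vs reference) per
#'   gene; genes not named get fold 1.
#' @param n_replicates Replicates per group (must be >= 1).
#' @param ct_noise_sd Gaussian Ct noise sd (>= 0).
#' @param groups Length-2 labels, `c(group, reference_group)`.
#' @param housekeeping Housekeeping gene symbols (default GAPDH, ACTB).
#' @param seed Integer seed.
#' @return A Ct tibble.
#' @export
simulate_ct_table <- function(genes, fold_map = numeric(),
                              n_replicates = 3L, ct_noise_sd = 0.2,
                              groups = c("tumour", "normal"),
                              housekeeping = c("GAPDH", "ACTB"),
                              seed = 1L) {
  if (n_replicates < 1) abort_usage("n_replicates must be >= 1")
  if (ct_noise_sd < 0) abort_range("ct_noise_sd must be >= 0")
  base_ct <- setNames(25 + 2 * seq_along(genes) %% 3, genes)
  hk_ct <- setNames(c(18, 20)[seq_along(housekeeping) %% 2 + 1], housekeeping)
  grid <- tidyr::crossing(group = groups,
                          replicate_id = sprintf("rep%d", seq_len(n_replicates)),
                          gene = c(genes, housekeeping))
  withr::with_seed(seed, {
    grid %>%
      mutate(ct = dplyr::case_when(
               .data$gene %in% housekeeping ~ hk_ct[.data$gene],
               .data$group == groups[1] ~ base_ct[.data$gene] -
                 log2(ifelse(is.na(fold_map[.data$gene]), 1, fold_map[.data$gene])),
               TRUE ~ base_ct[.data$gene]),
             ct = .data$ct + rnorm(n(), 0, ct_noise_sd))
  })
}
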