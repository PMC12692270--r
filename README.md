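# splitsig

Subtype-specific somatic driver discovery by cohort-split randomisation.

`splitsig` is an R package for comparing the somatic mutation landscape of
two tumour subtypes — the motivating design is morphoeic versus nodular basal
cell carcinoma, ten whole exomes per arm — and asking which driver genes,
pathways, mutation hotspots, copy-number events and expression changes are
*specific* to one subtype rather than shared. It is aimed at cancer-genomics
analysts working with small annotated cohorts (a MAF-like variant table plus
a sample sheet), where arm sizes are too small to trust a naive
"significant here, not there" comparison.

## What it computes

**Per-gene driver significance**, by two self-contained engines:

* *Functional-impact bias*: each nonsynonymous variant gets a combined damage
  score s ∈ [0, 1] (mean of 1 − SIFT and PolyPhen); a gene with k variants is
  scored by its mean impact s̄ against N seeded draws of k variants from the
  cohort pool excluding the gene, with the add-one empirical p
  `p = (1 + #{s̄* ≥ s̄}) / (1 + N)`.
* *Length-aware recurrence*: under a passenger model the gene's variant count
  is X ~ Binomial(nL, r) for n samples, coding length L and background rate r
  (estimated cohort-wide); the test reports P(X ≥ k) analytically.

q-values are Benjamini–Hochberg across each scan (driver call at q < 0.1 by
default).

**Subtype-specificity by randomisation.** A gene significant in one arm
(q < 0.05) but not the other (q > 0.1) is only a *candidate*. The pooled
cohort is then split 100 times into random groups sized like the true arms;
the candidate's −log₁₀ p in the group standing in for its subtype forms an
empirical null, and the true-label significance is placed in it with a
symmetric add-one two-tail p. `two_tail_p < 0.05` declares the gene
subtype-specific.

Around that core: pathway-level impact bias with shared/specific set
comparison, recurrent-residue hotspot calling and binomial protein-domain
cluster tests, fraction-of-genome-altered and recurrent-CNA-event summaries
(cn-LOH counts as altered), and 2^−ΔΔCt qPCR quantification with
geometric-mean housekeeping normalisation. A deterministic simulator
generates full synthetic cohorts with planted drivers, hotspots, CNA events
and expression folds, so every stage is testable without patient data.

## Worked example

Simulate a 10 + 10 cohort with a morphoeic-only driver (8× mutation rate,
impact shift 0.6, plus a 3-sample hotspot at residue 50), scan both arms with
the recurrence engine, select candidates, and run the randomisation test:

```r
library(splitsig)

cohort <- simulate_cohort(simulation_config(
  background_rate = 3e-5,
  drivers = list(driver_spec("GENE050", "morphoeic",
                             rate_multiplier = 8, impact_shift = 0.6)),
  hotspot_specs = list(list(gene = "GENE050", residue = 50L,
                            n_samples = 3L, subtype = "morphoeic")),
  seed = 42))

cfg    <- driver_config(method = "recurrence", seed = 1)
scan_m <- run_driver_scan(cohort$variants, cohort$sheet, cohort$models, cfg,
                          subtype = "morphoeic")
scan_n <- run_driver_scan(cohort$variants, cohort$sheet, cohort$models, cfg,
                          subtype = "nodular")
candidates <- select_candidates(scan_m, scan_n)
rand <- randomisation_test(cohort$variants, cohort$sheet, candidates,
                           cohort$models, cfg,
                           randomisation_config(n_iter = 100, seed = 1))
rand
```

```
<randomisation_result> recurrence/monte_carlo: 3 candidate(s), 2 specific at two-tail alpha=0.05 (100 splits)
# A tibble: 3 × 8
  gene    candidate_subtype observed_sig null_mean null_sd two_tail_p specific
  <chr>   <chr>                    <dbl>     <dbl>   <dbl>      <dbl> <lgl>
1 GENE050 morphoeic                 4.34      1.76   0.966     0.0198 TRUE
2 GENE188 morphoeic                 3.28      1.20   0.766     0.0396 TRUE
3 GENE074 nodular                   3.74      1.48   1.08      0.0594 FALSE
```

The planted driver GENE050 was mutated 9 times across 6 of 10 morphoeic
samples (scan q = 0.0031, untested in the nodular arm) and its true-label
significance (−log₁₀ p = 4.34) exceeds all 100 random-split values, giving
the two-tail floor 2/101 ≈ 0.0198: declared subtype-specific. GENE074, a
passenger that drifted to candidacy in the nodular arm, is *not* declared
specific — the randomisation null absorbs it. The planted hotspot and
expression fold are recovered the same way:

```r
call_hotspots(cohort$variants, "GENE050", min_samples = 3)
#>   gene    residue n_samples samples
#> 1 GENE050      50         3 <chr [3]>

ct <- simulate_ct_table("GLI2", c(GLI2 = 16), n_replicates = 3,
                        ct_noise_sd = 0.2, seed = 7)
ddct_fold_change(ct, "GLI2", "tumour", "normal")
#>   gene  group  reference_group mean_fold ... n_replicates        p
#> 1 GLI2  tumour normal               13.5              3    4.78e-6
```

A 16-fold planted overexpression is recovered as 13.5-fold under Ct noise of
sd 0.2 with three replicates; `autoplot()` methods and `plot_lollipop()` /
`plot_fga()` provide the standard figures for each result type, and
`run_full_pipeline()` executes every stage over a directory of input files,
writing per-stage TSVs and a JSON run manifest.

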