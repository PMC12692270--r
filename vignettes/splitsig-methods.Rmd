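---
title: "Methods: subtype-specific somatic driver discovery by cohort-split randomisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subtype-specific somatic driver discovery by cohort-split randomisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(splitsig)
library(dplyr)
```

# The problem

Basal cell carcinoma presents in histological subtypes with very different
clinical behaviour: morphoeic (infiltrative, locally recurrent) tumours versus
indolent nodular ones. With small cohorts — ten tumours per subtype is a
realistic design for a rare subtype — the question "which driver genes are
*specific* to one subtype?" is harder than "which genes are drivers?": a gene
can reach significance in one arm and not the other purely because each arm is
small. `splitsig` implements a pipeline for exactly this comparison: per-gene
driver statistics, a candidate rule, and a cohort-split randomisation test
that asks whether a candidate's subtype-restricted significance is stronger
than what arbitrary balanced relabellings of the pooled cohort produce.

# Per-gene driver statistics

## Combined impact score

Each nonsynonymous variant is reduced to a damage score in $[0,1]$: the mean
of the available components, where SIFT contributes $1-\mathrm{sift}$ (SIFT is
small for damaging variants) and PolyPhen contributes its score directly.
Variants with neither score fall back on consequence: nonsense and splice-site
variants score 1 (presumed loss of function), anything else 0.5
(uninformative). Scores from different predictor versions are treated as
opaque reals in $[0,1]$; the package does not re-annotate.

## Functional-impact bias (permutation test)

For a gene $g$ with $k$ nonsynonymous variants, the statistic is the observed
mean combined impact $\bar{s}_g$. The null is built by drawing, without
replacement, $k$ variants from the cohort-wide nonsynonymous pool excluding
$g$, $N$ times (default $N = 10{,}000$), and the p-value is the add-one
empirical upper tail

$$p_g = \frac{1 + \#\{\bar{s}^{\ast} \ge \bar{s}_g\}}{1 + N}.$$

The add-one form keeps $p > 0$ and is slightly conservative; ties count as at
least as extreme. Genes with fewer than `min_variants` (default 2) variants
are skipped with a recorded reason — one variant cannot show bias. This is a
deliberately self-contained analogue of functional-impact-bias driver tools;
it does not reproduce their multi-metric z-score machinery, and makes the
pipeline runnable without external downloads.

The Monte-Carlo resolution matters: $p \ge 1/(N+1)$, so $-\log_{10} p$
saturates at $\log_{10}(N+1)$. $N$ should be chosen so that the observed
significances of genes of interest sit below that ceiling.

## Length-aware recurrence

Under a passenger-only model with per-base per-sample rate $r$, the count of
nonsynonymous variants in a gene of coding length $L$ across $n$ samples is
$X \sim \mathrm{Binomial}(nL, r)$, and the test reports $P(X \ge k)$
analytically. The rate is estimated cohort-wide as (total nonsynonymous
variants) / ($n \times$ total coding length), optionally excluding putative
drivers. This is the recurrence core of covariate-rich background models,
without per-gene covariates (expression, replication timing), which require
external resources.

## Multiple testing

q-values are Benjamini–Hochberg across the genes actually tested in a scan.
The FDR procedure behind the published thresholds is not named in the source
methods; BH is the field default and is exposed as `bh_fdr()` so it can be
swapped. Scan thresholds default to $q < 0.1$ (driver call), with raw
$p < 0.05$ eligibility / $p < 0.02$ highlighting retained for the
recurrence-style scan where small cohorts make FDR adjustment unstable.

# Candidate selection and the randomisation comparison test

A gene is a candidate for subtype A when $q_A < 0.05$ and $q_B > 0.1$
(defaults; both configurable). A gene skipped or untested in B counts as
"not significant in B" — the permissive reading; `strict = TRUE` requires an
actual $q_B > 0.1$. A gene can never be a candidate for both subtypes, since
$q < 0.05$ and $q > 0.1$ cannot hold simultaneously in one arm.

The specificity test then repeatedly splits the *pooled* cohort at random
into two groups sized like the true subtypes (default 100 iterations,
sampling without replacement). By convention group 1 stands in for the
candidate's subtype and takes its size, so unequal designs generalise. In
each split the candidate's significance $-\log_{10} p$ (same per-gene engine
as the true scan, same eligibility rules; a gene with too few variants in a
split scores 0) is computed in group 1, giving an empirical null
$\{t_1,\dots,t_m\}$. With observed true-label significance $t_{\mathrm{obs}}$,

$$p_{\text{two-tail}} = \min\!\left(1,\;
  \frac{2\,(\min(\#\{t_i \le t_{\mathrm{obs}}\},
               \#\{t_i \ge t_{\mathrm{obs}}\}) + 1)}{m + 1}\right),$$

and the gene is declared subtype-specific when $p_{\text{two-tail}} <
\alpha = 0.05$. The formula is the symmetric add-one empirical two-tail: it
is never 0, is capped at 1, and has floor $2/(m+1)$ ($\approx 0.0198$ at 100
splits). Significance is tracked as $-\log_{10}$ of the *raw* per-gene p, not
q, because the q of a gene depends on which other genes happen to be testable
inside each split. `mode = "exact"` enumerates every ordered balanced split
(complements are distinct, since group 1 carries the subtype role) and is the
oracle against which the Monte-Carlo mode is validated on small cohorts.

## Power characteristics

Two structural facts limit this procedure for moderate drivers, and the
package's validation suite measures rather than hides them. First, a random
split that happens to capture all of a candidate's carrier samples reproduces
the observed statistic almost exactly; with $C$ carriers among $n=20$ the
per-split probability is $\binom{20-C}{10-C}/\binom{20}{10}$ (about 4% at
$C=4$), and the add-one two-tail formula needs no more than one of 100 splits
at or above the observed value to declare specificity. Second, the
combined-impact distribution of passengers (mean of two uniforms) has thin
tails, so subsets of a high-impact driver's variants remain extreme inside
splits. Consequently a driver mutated in ~40% of one arm with a moderate
impact shift is usually *not* declared specific, while strongly recurrent or
near-loss-of-function drivers (≥60% recurrence, impact shift near 1) are.
The acceptance suite plants the moderate configuration deliberately and
reports the measured recovery rate as-is.

# Pathway-level analysis

A pathway's statistic pools the nonsynonymous variants of its member genes
and applies the same impact-bias permutation against the remaining cohort; a
single-gene set reproduces that gene's test exactly (same seed). q-values are
BH across tested pathways, and two per-subtype scans are intersected at
$q < 0.05$ into shared / specific-to-A / specific-to-B / neither. The
comparison also accepts an externally produced pathway→q table (e.g. from a
transcriptome enrichment analysis), so DNA/RNA intersections can be
assembled; enrichment analysis itself is out of scope. Genes of a set absent
from the cohort are ignored — curated collections always exceed one exome's
mutated universe.

# Hotspots and domain clustering

A hotspot is a residue carrying nonsynonymous variants in at least
`min_samples` (default 2) distinct samples; a sample hit twice at one residue
counts once. Domain clustering is formalised with the minimal defensible
null: $m$ positioned variants fall into a domain of length $d$ on a protein
of length $L$ independently with probability $d/L$, so the in-domain count is
$\mathrm{Binomial}(m, d/L)$ and the reported p is its upper tail. This is a
descriptive-cluster test, not a kernel or 3D method; protein positions from
multi-isoform annotations are taken at face value against the supplied
protein length.

# Copy-number summaries

Fraction of genome altered is the percentage of the genome covered by
non-neutral segments; copy-neutral LOH counts as altered by default (it is
allelically aberrant despite net-neutral dosage), configurable via
`altered_states`. A recurrent regional event (e.g. "9q loss or cn-LOH")
counts a sample when its qualifying segments cover at least
`min_overlap_frac` (default 0.5) of the region — the source material does not
state a rule, and half-region coverage is a conservative middle ground
between "any overlap" and "full arm".

# Relative expression (2^−ΔΔCt)

Per replicate, $\Delta Ct = Ct_{\text{target}} - \overline{Ct}_{\text{hk}}$,
where the arithmetic mean of housekeeping Cts is exactly the geometric mean
of housekeeping expression on the linear scale (the standard two-reference
normalisation; defaults GAPDH and ACTB). $\Delta\Delta Ct$ references the
mean $\Delta Ct$ of the calibrator group, folds are $2^{-\Delta\Delta Ct}$,
and the summary fold is $2^{-\overline{\Delta\Delta Ct}}$ — the geometric
mean of per-replicate folds, the usual Livak convention. The group test is an
unpaired two-tailed Student t-test on $\Delta Ct$ values (variance-stabilised
scale; Welch via `var_equal = FALSE`). Amplification-efficiency correction is
out of scope.

# The synthetic cohort generator

`simulate_cohort()` emulates the target study design: two subtypes of 10
samples each over a fixed 200-gene catalogue with coding lengths log-uniform
on 0.5–15 kb (the catalogue is part of the study design and does not vary
with the cohort seed). Per sample and gene, counts are Poisson(rate ×
length); the default background rate is 3e-6 nonsynonymous variants per base
per sample. Passenger SIFT/PolyPhen scores are independent uniforms —
maximally uninformative, so any detected bias is planted, not a
distributional artefact. Planted drivers multiply the rate and/or shift the
score means (truncated to $[0,1]$) in carrier subtypes;
`multiplier_for_recurrence()` converts a target per-sample carrier
probability into the required multiplier. Consequences are drawn 85%
missense / 10% nonsense / 5% splice-site (documented constants). Hotspots,
segment profiles (planted events carved out of a neutral backbone, so
burdens are exactly recoverable) and Ct tables (planted folds, Gaussian well
noise) complete the fixture set. Everything is byte-deterministic given the
configuration and seed.

What the generator does **not** emulate: trinucleotide signatures, gene-level
covariates of mutability, subclonality, correlated impact scores, sample
contamination. Passing recovery tests therefore show the statistics behave as
designed under their own assumptions — not that those assumptions hold in any
given patient cohort.

# Numerical and design choices

* **Seeding.** One master seed; per-gene and per-iteration seeds are derived
  by an integer mixing function (`derive_seed()`), so results are independent
  of execution order and reproducible to the byte. Variants are canonically
  sorted (sample, gene, genomic position, protein position) before any
  seeded resampling, making results invariant to input row order.
* **Ties.** All empirical tails count ties as "at least as extreme"; the
  add-one convention keeps every p in $(0,1]$.
* **Degenerate inputs.** A zero background rate with observed variants is
  refused (it would imply $p = 0$); a split in which a candidate has no (or
  too few) variants records significance 0 rather than erroring; zero-variance
  ΔCt groups report fold but `NA` for the t-test p.
* **Validation problem sizes.** The suite validates the Monte-Carlo engine
  against exhaustive enumeration on pools ≤ 10, the recurrence and domain
  tests against log-space binomial tail summation (relative error < 1e-12),
  exact-mode randomisation against brute-force enumeration of all 20
  balanced 3-vs-3 splits, null calibration on three 200-gene/20-sample
  cohorts, type-I control of the randomisation test over 50 seeds, and
  recovery of a planted 16-fold expression difference over 50 seeds. The
  planted-driver specificity chain is measured over 20 seeds at the
  moderate effect size discussed above.

# Known limitations

* The driver engines are deliberate simplifications; they share the *logic*
  of impact-bias and recurrence tools, not their covariate models, and
  absolute q-values on real cohorts will differ from those tools'.
* The randomisation comparison test has limited power for drivers of
  moderate recurrence (see *Power characteristics*); its strength is type-I
  control, which the suite verifies directly.
* The domain-cluster null assumes positional uniformity within the mutated
  protein, ignoring codon mutability differences.
* CNA summaries consume segment calls; segmentation quality is upstream of
  this package.
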