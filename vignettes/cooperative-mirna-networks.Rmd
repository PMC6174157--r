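---
title: "Recovering cooperatively suppressed transcription factors from paired tumor/normal miRNA and mRNA profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering cooperatively suppressed transcription factors from paired tumor/normal miRNA and mRNA profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mircoop)
library(dplyr)
```

## The analysis problem

Tumors frequently up-regulate groups of miRNAs whose joint action silences a
shared target. Because each miRNA only modestly represses any single
transcript, the signature of such *cooperative suppression* is distributed:
no single miRNA-target pair is striking, but one transcription factor (TF)
ends up targeted by dozens of co-upregulated miRNAs and is coordinately down
in every tumor. `mircoop` implements the integrated analysis that exposes
this structure in a small paired design — a handful of patients, each
contributing one tumor and one adjacent-normal sample profiled by both
RNA-seq and small-RNA-seq:

1. **Quantification.** mRNA expression as RPKM (reads per kilobase of
   summed exonic length per million *uniquely mapped* reads), miRNA
   expression as TPM (tags per million *total clean* reads), and CPM for
   filtering. The two per-million denominators differ deliberately: only
   unambiguously aligned reads enter RPKM, while the miRNA TPM convention
   divides by the library's clean-read total.
2. **Per-pair differential expression.** With one tumor and one normal
   sample per patient there are no replicates, so each pair is tested with
   an exact conditional negative-binomial (NB) test at a supplied
   dispersion. Features pass a CPM > 1 filter, p-values are BH-adjusted
   within each pair, and a feature is called up/down when |fold change| >
   1.5 and FDR < 0.05.
3. **Target prediction.** Canonical seed matching (6mer, 7mer-A1, 7mer-m8,
   8mer; strict Watson-Crick in the seed), a seed-weighted local
   hybridization alignment score, and an additive context-style site score.
   A gene passes for a miRNA when the summed alignment score reaches 90% of
   that miRNA's perfect-duplex score, or when the best site is a 7mer or
   better with a negative context-style score.
4. **Network assembly.** A passing (miRNA, gene) pair becomes a negative
   regulatory edge supported by every pair in which the two change
   significantly in opposite directions; edges must recur in at least two
   pairs. The up-miRNA/down-TF subnetwork and its in-degree table rank
   candidate hubs.
5. **Enrichment.** Hypergeometric (optionally Wallenius non-central)
   GO-style term tests with BH correction and the rich factor k/K.

A synthetic-cohort generator with planted ground truth makes every stage
testable without sequencing data, and closed-form clinical formulas
(IHC histoscore with the 1.07 high/low cutoff, `2^-ddCt` expression,
xenograft tumor volume) support the downstream bench readouts.

## The exact test for designs without replicates

For one pair, counts $(y_a, y_b)$ with library sizes $(N_a, N_b)$ are first
equalized to the common size $\sqrt{N_a N_b}$ (scaling and rounding
half-to-even). Conditional on the equalized total $s = y'_a + y'_b$, each
split $i$ receives weight

$$w(i) = \mathrm{NB}(i;\ \mu = s/2,\ \phi)\ \cdot\ \mathrm{NB}(s-i;\ \mu = s/2,\ \phi),$$

and the two-sided p-value sums the normalized weights not exceeding the
observed one (a $1+10^{-9}$ relative tie tolerance avoids float-equality
artifacts). The weights are accumulated as cumulative log-ratios
$\log w(i{+}1) - \log w(i) = \log\frac{(i+r)(s-i)}{(i+1)(s-i-1+r)}$ with
$r = 1/\phi$, which is numerically stable for any dispersion and passes
smoothly into the Binomial$(s, 1/2)$ conditional law as $\phi \to 0$. The
test is validated against a direct density-product enumeration for all
totals up to 60 and against the exact binomial two-tail at $\phi = 10^{-8}$.

The dispersion cannot be estimated from $n=1$ per group, so it is a
parameter: `run_pair_de()` defaults to 0.1, a deliberately conservative
choice for real data of this kind. When the pipeline analyses a cohort it
simulated itself the generative dispersion is known, and `run_pipeline()`
uses it (config `de$dispersion = NULL`); for file-based input it falls back
to 0.1. BH adjustment is applied within each pair across all tested
features of the matrix; the adjustment universe is a modelling choice that
matters mainly for borderline features.

Fold changes are computed on CPM with a pseudocount of 0.5 (the fold-change
formula for the original analysis is not pinned down; a symmetric
pseudocounted ratio is the least surprising choice and is antisymmetric
under swapping conditions).

## Target scoring choices

The original thresholds ("alignment score > 500", "context+ score < 0")
refer to the internal scales of specific external tools, which a
re-implementation cannot reproduce numerically. Both scores are therefore
re-expressed on this package's own documented scales:

* **Alignment.** Local alignment of the reversed miRNA against a UTR
  window: Watson-Crick +5, G:U wobble +2 (wobble is allowed in the
  alignment but never in the seed match), mismatch −4, gap open −8, gap
  extension −2, with pair/mismatch terms doubled at miRNA positions 2-8. A
  perfect 22-nt duplex scores 145. The absolute pass threshold is
  re-expressed *per miRNA* as `align_min_frac` (default 0.9) of that
  miRNA's perfect-duplex score, which transfers the "very strong
  hybridization" semantics across miRNA lengths; an absolute `align_min`
  can be set instead.
* **Context-style score.** Site-type base values (8mer −0.31, 7mer-m8
  −0.16, 7mer-A1 −0.10, 6mer −0.03) minus 0.1 × the A/U fraction of the
  30-nt flanks minus 0.1 × a terminal-proximity term
  $\max(0,\ 1 - 2\min(d_5, d_3)/(L - \ell))$, which is exactly 0 for a
  centered site and exactly 1 for a site flush against a UTR end. The
  weights keep the feature ordering (site type ≫ AU context ≈ position)
  and are configurable; the threshold "< 0" is kept. Because the base
  values are negative, the context branch effectively requires a 7mer or
  better — a lone 6mer can only pass through the alignment branch.
* **Aggregation.** Alignment scores sum over retained (non-overlapping)
  sites and are thresholded per gene; the context score is the per-site
  minimum. Overlaps are resolved greedily by descending alignment score
  with leftmost tie-break.

## What the synthetic cohort emulates

`simulation_config()` defaults describe the design the generator stands in
for: 4 tumor/normal pairs, 2000 genes of which 150 are TFs, 300 miRNAs, 40
planted co-upregulated miRNAs at fold change 4, and one hub TF carrying one
8mer site for each of 25 distinct planted miRNAs.

* **Cooperative targeting.** The planted miRNAs share a pool of 60 target
  genes (70% TFs), each targeted by 8-15 planted miRNAs; the hub gets
  exactly 25. Suppression compounds multiplicatively (0.55 per targeting
  miRNA) with a floor at 0.1× baseline — the simplest compounding form
  consistent with cooperative repression being stronger than any single
  miRNA's effect.
* **Counts.** Relative abundances are log-normal (sdlog 0.8, floored at
  0.4× the median so every feature is comfortably quantifiable at the
  desk-scaled depth of 1-2 million reads per library). Biological
  variability is a per-(feature, patient) gamma effect with variance
  `nb_dispersion` (default 0.05) *shared between the tumor and normal
  sample of a pair*, with Poisson sampling noise on top: marginally every
  count is NB(mean, dispersion), while within-pair ratios are
  sampling-limited. This is precisely the rationale for collecting paired
  tissue — patient-level variation cancels within a pair — and it is what
  makes 4-pair coordinated recovery of the planted effects an achievable
  benchmark. An independent-noise variant would put an irreducible
  $\sqrt{2\phi} \approx 0.32$ standard deviation on every within-pair log
  ratio, and no analysis could then call 90% of planted features
  coordinately in all four pairs.
* **Composition.** Fold-change effects are applied without renormalizing
  column totals, so the planted fold change is recoverable from the
  counts; tumor miRNA libraries consequently carry a small global up-shift.
  Planted miRNAs draw their abundances from the below-median stratum:
  planting 13% of the mirnome's *mass* at FC 4 would shift every other
  miRNA's apparent fold change by ~1.4×, an artifact of the synthetic
  design rather than a property of the method. UTR lengths are uniform on
  [200, 800] nt (desk-scaled relative to human 3'UTRs).
* **Background heterogeneity.** 10% of features receive a log-normal fold
  change (sdlog = log 1.5) independently in each pair, modelling
  patient-specific perturbations. These straddle the 1.5× calling
  threshold and are exactly what the ≥2-pair recurrence filter is designed
  to remove. The generator does not emulate batch effects, GC bias,
  isoform structure, stromal/immune admixture, or shared miRNA families
  (planted seeds are forced distinct) — passing recovery tests therefore
  demonstrates correctness of the inference machinery under the stated
  model, not robustness to those real-data complications.

Determinism: one `rng_seed` drives every stage through fixed offsets, so
identical configs give byte-identical outputs and each stage is
reproducible in isolation.

## Problem sizes used by the test suite

The suite exercises the generator at the full default scale (2000 genes,
300 miRNAs, 4 pairs, 5 seeds) for end-to-end recovery; null calibration
uses 10,000-feature cohorts over 20 seeds; the site-grammar oracle runs
1000 random 500-nt UTRs against 50 miRNAs; exact-test enumeration covers
all conditional totals up to 60 at three dispersions. These sizes were
chosen so the full suite completes in minutes on a single core while still
covering the regimes where the approximations could fail (small counts,
boundary sites, tied weights).

## Numerical and degenerate-input choices

* Equalized totals of zero give p = 1 (no evidence), never an error.
* The tie tolerance on conditional weights is multiplicative (1 + 1e-9),
  so exact symmetric splits return p = 1 regardless of float rounding.
* Wallenius enrichment uses an exact O(n·N) forward recursion up to
  N = 2000 and seeded Monte-Carlo beyond; uniform weights reproduce the
  central hypergeometric test to 1e-6. Weights must be supplied
  explicitly — the package refuses to guess a bias model.
* Terms with no universe genes or no study hits are dropped before BH so
  untestable rows cannot dilute the correction.
* `classify_expression()` is boundary-inclusive (score ≥ 1.07 is "high"),
  matching the published rule; the cutoff ships as a constant because its
  derivation (an ROC operating point on a specific cohort) is not
  reproducible from first principles.
* Edge patterns (`miR_up_gene_down`, `miR_down_gene_up`) are kept
  separate: mixed directions across pairs are two independent edges and
  never pool their support.

## Known limitations

* The exact test treats the supplied dispersion as truth; with one sample
  per condition this is unavoidable, and results should be read as
  conditional on that choice (the default 0.1 is conservative).
* Target prediction is sequence-only: no thermodynamic duplex energies, no
  conservation, no CDS/5'UTR sites, no expression-weighted site
  accessibility.
* "Negative correlation" is operationalized as sign-opposite significant
  calls within a pair, not a correlation coefficient — with four pairs a
  correlation estimate would be noise.
* The TF list is an input; the package ships a synthetic one and makes no
  attempt to derive TF status from annotation.

## A worked example

```{r example, eval = FALSE}
library(mircoop)

res <- run_pipeline(list(rng_seed = 1), outdir = "mircoop_run")

# planted miRNAs recovered as coordinately up
rec <- summarize_recurrence(res$de_mirna)
mean(res$cohort$truth$up_mirna_ids %in%
       rec$feature_id[rec$coordinated & lengths(rec$pairs_up) > 0])

# the hub TF tops the targeting-miRNA ranking
head(hub_statistics(res$tf_network))

# term enrichment of the coordinately down genes
autoplot(res$enrichment)
```
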