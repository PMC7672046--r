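---
title: "Case-only rare-variant prioritization for AIS cohorts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-only rare-variant prioritization for AIS cohorts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varfunnel)
```

## The problem and the study design

Adolescent idiopathic scoliosis (AIS) is a lateral spinal curvature (Cobb
angle above 10 degrees) arising in otherwise healthy adolescents.  Family
and population studies support a polygenic contribution, and case-only
whole-exome designs are an economical way to nominate susceptibility
variants: instead of sequencing matched controls, the case cohort's allele
counts are compared against public reference panels of similar ancestry.

`varfunnel` implements that design as a reusable, fully tested pipeline.
The reference configuration mirrors a Southern Han Chinese cohort of 195
sporadic AIS patients screened against two panels: the 1000 Genomes
Southern Han Chinese panel (CHS, 105 diploid individuals) and the ExAC
East Asian panel (EAS, 4,327 diploid individuals).  All patient-facing
inputs are synthetic here; the package ships a generator that emulates the
study design with planted, known-truth variants so that every stage of the
pipeline is verifiable without access to patient data.

## The prioritization funnel

Candidate variants pass four filters, in a fixed order:

1. **Read-level genotype QC.**  A call is accepted only when its site
   depth is at least `min_depth` (default 30 reads) and its read-level
   alternate-allele fraction lies strictly inside the heterozygous window
   (0.4, 0.6) or strictly above the homozygous threshold 0.9.  The window
   boundaries themselves fail, as does the gap (0.6, 0.9]: with the
   inequalities read literally, a fraction of exactly 0.4, 0.6 or 0.9 is
   evidence of neither a clean heterozygote nor a clean homozygote.  A
   variant survives if at least one carrier call passes.
2. **Recurrence.**  Only variants mutated in `min_carriers` or more
   patients (default 2) are kept, a repeatability guard against private
   artifacts.  The threshold is configurable because the two natural
   readings of "recurrent" (at least two vs more than two) differ by one;
   the package defaults to *two or more*.
3. **Population frequency.**  Variants whose panel allele frequency
   exceeds `panel_af_cutoff` (default 5%) **in every panel** are removed
   as common polymorphism.  Absence from a panel counts as frequency
   zero, so a variant common in a single panel survives this filter; such
   survivors are surprising and are flagged in a dedicated attribute.  A
   `panel_af_mode = "any"` switch gives the stricter either-panel rule
   used by many pipelines.
4. **Deleteriousness consensus.**  Verdicts from five upstream predictors
   (SIFT, PolyPhen2, LRT, FATHMM, MutationTaster) arrive as annotation
   inputs; a variant is retained when at least `min_deleterious_votes`
   (default 2) are deleterious.  Missing verdicts never count as votes,
   and PolyPhen2's intermediate `possibly_damaging` label is deliberately
   not a deleterious vote.

Every stage returns a subset of its input, so the funnel report's counts
are non-increasing by construction; the recurrence, population and
consensus stages examine disjoint evidence and therefore commute, which
the test suite verifies on random cohorts.

## Burden testing and classification

For each candidate and each panel, the package builds a 2x2 allele-count
table: case alternate alleles (`het + 2*hom` carriers) against
`2 * 195 - case_alt`, and panel alternate alleles against the panel
complement.  Panels publish frequencies, not counts, so the panel count
is `round(af * 2n)` with half-counts rounded up — counts must be integral
for the exact test.

Both Fisher's exact test (two-sided, by the probability-mass definition:
the sum of probabilities of all margin-fixed tables no more probable than
the observed one) and the 1-df Pearson chi-squared without continuity
correction are computed; classification uses Fisher, and chi-squared is
reported alongside with a low-expected-count flag.  Benjamini–Hochberg
correction is applied **within each panel's family of panel-present
variants**: a variant absent from a panel is not a test in that panel's
family.  Per-database families are the most literal reading of a
per-database comparison, and they keep a panel's family from being
diluted by variants it never observed.

A candidate is then

* **novel** — at least `min_carriers` case carriers and zero frequency in
  every panel (no test is possible; the classification is deterministic
  given the rule);
* **differential** — present in at least one panel with BH q below
  `alpha` (default 0.05).  With `panel_sig_mode = "any"` (the default)
  significance in one present panel suffices; `"all"` demands every
  present panel.  The disjunctive default follows the discovery logic of
  comparing the cohort against one database *or* the other: the small
  CHS panel (210 alleles) has essentially no power for variants near
  0.1% frequency, and demanding concordant significance there would veto
  discoveries made in the 15-fold larger EAS panel on the basis of a
  test that cannot reject anything;
* **not associated** otherwise.

Novel and differential are mutually exclusive (panel absence versus
presence decides).

## Gene-family enrichment

Genes of novel/differential variants are tested for over-representation
in gene families (HGNC-style many-to-many map) or GMT gene sets with the
upper-tail hypergeometric probability, computed through `phyper` in log
space.  The **universe** is the set of genes carrying at least one
variant that survived the population-frequency stage: enrichment should
be judged against genes the exome screen could actually have nominated,
not against the whole genome, which would overstate significance.  Sets
are intersected with the universe before their size `K` is computed; BH
runs across all tested sets (those with `K >= 1` and overlap `k >= 1`)
and results are ranked by `-log10(FDR)`, with q clipped at `1e-300`
before the logarithm so that ranking never produces infinities.

## Clinical subgroup association

Patients are dichotomized per feature: categorical features (sex, curve
shape, main-curve direction, apex class) pass through their two levels;
continuous features (Cobb angle, tilted-vertebrae count, age) split at
the cohort mean, with values exactly at the mean assigned to "below" (an
explicit, configurable tie rule — the natural-language rule "below/above
the mean" does not say where ties go).

Each associated variant is screened feature by feature: carriers versus
non-carriers compared by Wilcoxon rank-sum for continuous features (exact
enumeration when the two groups total at most 12 without ties, otherwise
the tie-corrected normal approximation with continuity correction) and by
Fisher's exact test on the 2x2 carrier-by-level table for binary features
(a rank-sum on 0/1 coding is available as a switch; Fisher is the default
for interpretability).  BH correction is applied within each feature
across variants.  Variants carried by nobody or by everybody provide no
contrast and are skipped with a warning.

Per-feature significant sets are intersected Venn-style over the four
structural features (apex location, Cobb angle, direction, tilted count);
sex and curve shape are screened but excluded from the intersection, sex
being a demographic rather than a curve-morphology feature.  Pairwise
feature association uses a per-type scheme (Fisher/chi-squared,
Wilcoxon/Kruskal–Wallis, Spearman) — the choice of statistic per pair is
a documented package decision, as correlation heatmaps of this kind
rarely name one.

## The synthetic cohort generator

`simulate_dataset()` emits a cohort VCF-equivalent, per-panel frequency
tables, an annotation sidecar with native predictor labels, a clinical
table, a gene-family map and the planted truth.  Its defaults *are* the
study conditions: 195 patients, CHS = 105 and EAS = 4,327 diploid panel
samples, and a clinical composition of 156 F / 39 M, 131 C / 64 S curves,
52 L / 143 R, 106 / 89 apex classes, age 14.93 ± 3.04 y, Cobb
41.88 ± 18.35°, 13.00 ± 3.84 tilted vertebrae.  Categorical fields are
allocated to exact counts by largest-remainder rounding, so the reference
composition is reproduced exactly, not in expectation.

* **Planted novel variants** (default 10) recur in 2–6 patients, are
  absent from every panel and carry 3–5 deleterious verdicts — they
  satisfy the novel rule by construction, which is what makes sensitivity
  1.0 a meaningful deterministic check rather than a statistical one.
* **Planted differential variants** (default 10) recur in 5–10 patients
  and carry frequency 0.001 in the EAS panel; their CHS record is a
  binomial resample, so they are usually (about 81% of the time at this
  frequency) absent from the 105-sample panel, as real rare variants are.
  The two planted classes get separate carrier ranges because their
  detectability regimes differ: the novel rule is deterministic from two
  carriers up, while the differential call needs enough allele-count
  excess to survive FDR correction.
* **Null variants** draw a latent population frequency from a point mass
  at zero (probability 0.30, cohort-private variants) plus
  `0.5 * Beta(0.3, 3)`; panel records are binomial resamples of that
  frequency and case carrier counts are binomial in the diploid carrier
  probability `1 - (1 - af)^2`.  No distributional description of the
  real cohort's spectrum is available, so this background is a package
  choice: heavy near zero, with enough mass above 5% (roughly a fifth of
  non-private variants) to exercise the population filter.  A
  `background_af = list(type = "fixed", af)` mode gives every null
  variant one frequency, which is what the binomial goodness-of-fit
  calibration test uses.
* **Calls** are heterozygous with integer alternate-read counts chosen
  strictly inside the (0.4, 0.6) window and depth `30 + NegBin(mu = 40,
  size = 8)`, so an uncorrupted call always passes QC.  A
  `corruption_rate` (default 5%) of null carrier calls is emitted as QC
  failures (depth 5–29, or alternate fraction in (0.6, 0.9)); corruption
  applies to null variants only, so the planted truth deterministically
  survives QC — the generator's contract is that planted variants *are*
  discoverable and null variants exercise every failure path.
* One designated family receives every planted gene; null genes scatter
  uniformly over 40 background families, with ~5% given a second
  membership to exercise many-to-many handling.

Everything is a deterministic function of the configuration seed; the
generator restores the caller's RNG state on exit.

What the generator does **not** emulate: linkage disequilibrium between
variants, population stratification between cohort and panels, alignment
or calling artifacts beyond the depth/fraction corruption, gene length
(every gene is equally likely to host a variant), and indels (excluded
by the pipeline's SNV rule at read time).  Passing recovery tests on this
synthetic data therefore demonstrates that the *procedure* is implemented
correctly and has the advertised operating characteristics under its own
assumptions — not that those assumptions hold in any particular patient
cohort.

## Numerical choices and degenerate inputs

* Fisher's two-sided p sums all tables whose probability is at most
  `(1 + 1e-7)` times the observed table's, the standard tie guard; a zero
  margin is degenerate and returns p = 1 with a flag.
* Chi-squared with a zero margin returns p = 1 with a warning; expected
  cells below 5 set a `low_expected` flag rather than silently switching
  tests.
* Panel allele counts round half up (`floor(x + 0.5)`), chosen over
  banker's rounding so that published half-allele frequencies never
  vanish.
* Wilcoxon on two identical constant groups returns p = 1 (degenerate,
  no ordering information).
* BH q-values are computed by `p.adjust(method = "BH")`; inputs outside
  [0, 1] are an error, not a clamp.
* `-log10` ranking floors q at `1e-300`.

## Problem sizes used by the shipped checks

The packaged tests and the acceptance script run the full design
(195 cases, 105/4,327 panels) with cohorts of 300–2,000 variants, 200
recovery simulations of 500 variants each, 150 all-null simulations of
400 variants, and exhaustive oracle grids (all 2x2 tables with total at
most 60; all hypergeometric configurations with universe at most 25; all
rank-sum splits with at most 10 observations).  These sizes were chosen
so the whole verification battery runs in a few minutes on a single CPU
while keeping every Monte-Carlo margin wide; the statistical conclusions
do not change with larger cohorts because the per-variant tests depend
on the design constants (case and panel sample sizes), not on how many
variants accompany a given one — the only exception is the BH family
size, which the recovery simulations deliberately keep realistic by
running the full funnel before testing.

## Known limitations

* The headline variant counts of a real 195-patient exome funnel
  (hundreds of thousands of raw SNVs) are not reproducible from synthetic
  desk-scale data; the package reproduces the funnel's *structure* and
  its operating characteristics, not the historical counts.
* The per-variant burden test ignores relatedness and fine-scale
  ancestry mismatch between cohort and panel; both inflate differential
  calls in real data and are out of scope here.
* Gene assignment is single-valued per variant (the annotation sidecar
  carries one symbol); overlapping transcripts are not modelled.
* The clinical screen treats carriers as a group regardless of genotype
  dosage; with essentially all carriers heterozygous at these
  frequencies, a dosage model would add nothing detectable.
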