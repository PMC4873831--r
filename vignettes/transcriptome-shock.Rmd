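---
title: "Classifying transcriptome shock in allopolyploids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying transcriptome shock in allopolyploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyshock)
```

## The problem

A newly formed allopolyploid carries two diverged parental genomes in
one nucleus. Its transcriptome can respond in two distinct ways that
this package separates cleanly:

* **Total expression.** For each gene, the polyploid's summed
  expression over both homeologs is compared to the *mid-parent value*
  (MPV) — the expectation if each parental allele simply kept its
  diploid output. Genes matching the MPV are *additive*; the rest are
  *nonadditive* and are further resolved into expression-level
  dominance (ELD) and transgressive expression (TRE).
* **Homeolog partitioning.** Independently of the total, the relative
  contribution of the two subgenome copies (measured as the A-subgenome
  fraction of the transcript pool) can be inherited from the parents or
  remodeled — a parental bias can be erased, or a novel bias can arise.

Both layers are tracked over consecutive selfing generations to ask
whether shock-induced changes are transient or transgenerationally
stable, and allele fractions from natural polyploids can be laid
alongside to ask whether the same subgenome dominance persists over
evolutionary time.

## The classification model

### Parental divergence and the expression space

Parents are contrasted with a moderated t-test (below) under
Benjamini–Yekutieli (BY) FDR control. Genes with adjusted p < α
(default 0.05) are *parental expression-differential* (PED), the rest
*parental expression-conserved* (PEC). This split constrains the
downstream space: a PEC gene has no "dominant parent" to match, so it
can only be constant, transgressive, or ambiguous; ELD exists only for
PED genes. The constraint is enforced structurally by the decision
tree, never patched afterwards.

### Additivity and the pattern decision tree

Three contrasts are computed per gene against the polyploid group:
versus the MPV group (T_m), versus parent A (T_a) and versus parent B
(T_b), each BY-adjusted across genes at the same α.

1. T_m not significant → **additive** (`constant` for PEC genes,
   `additive` for PED genes). Equality is operationalized as
   non-significance — the field's convention for this design — which
   accepts absence of evidence; the calibration of that choice is
   checked by the type-I-error test in the suite.
2. T_m significant → nonadditive:
   * above both parents (T_a, T_b significant, both differences
     positive) → `over_tre`; below both → `under_tre`;
   * PED genes indistinguishable from the higher parent but different
     from the lower → `eld_high_*` (named for the matched parent);
     the mirror case → `eld_low_*`;
   * everything else → `ambiguous`.

The tree is deliberately not exhaustive: a polyploid can sit between
its parents, differing from the MPV and from both parents. Such genes
get the explicit `ambiguous` bin rather than being forced into a
category, and a gene indistinguishable from *both* parents while
differing from the MPV (possible when the MPV group is a measured mix)
is also `ambiguous`, not ELD. Requiring T_m significance first means an
ELD call always differs from the MPV; whether that extra requirement
should be imposed was genuinely open, and imposing it was chosen
because it keeps "nonadditive" a single, consistent notion across all
patterns.

### The MPV: measured mix versus computed

The default MPV group is the measured 1:1 parental RNA mix — a
physical pool hybridized like any other sample, which carries real
replicate noise and any mixing bias. When no mix was assayed, the
computed mode pairs parental replicates by index and averages on the
linear scale, `MPV_i = log2((2^a_i + 2^b_i)/2)`; averaging log2 values
directly would understate the mix whenever parents differ (by up to
`lfc/2 - log2(...)`, ~0.56 log2 units at a 1.5-unit parental gap).

### Detection filtering

Array-style present/absent flags need probe-level data, which this
package does not consume. The same reproducibility intent is
implemented as a threshold rule: a gene is present in a genotype group
when *every* replicate is at or above the detection threshold (log2
scale, default 5.0), and retained when present in at least one group.
The threshold is configuration, reported in the run manifest; setting
it to `-Inf` disables filtering (used for parameter-recovery runs,
where the generator plants no absent genes and filtering would only
remove genes whose planted labels we intend to score).

### Transgenerational consistency

The default `exact_pattern` mode requires the identical nonadditive
pattern label in every generation — the strict reading of "the same
nonadditive expression pattern". The looser `nonadditive_only` mode
(persistently nonadditive, any pattern) is computed alongside because
consistency counts in this literature can reflect either reading.
Genes `ambiguous` in any generation are excluded from the consistent
set: no pattern identity can be asserted for them. Source
decomposition (PEC/PED × TRE/ELD, with a TRE-versus-ELD proportion
test) is only defined under `exact_pattern`, where the label is
generation-invariant.

### Homeolog partitioning

A *comparable data point* is a gene × generation with (a) a
total-expression category call and (b) at least two replicate allele
fractions in both the polyploid generation and the mix — the term is
used loosely in this literature, and this is the formalization adopted
here. Partitioning is *altered* when a two-sample t-test of polyploid
versus mix fractions gives raw p < 0.05; each group's *bias* is a
one-sample t against 0.5, also at raw p < 0.05 (per-locus testing
style; a flag enables BH adjustment across genes). Welch is the
default two-sample test since nothing in the design argues for pooled
variances (pooled is a flag), and raw fractions are tested by default
with an arcsine-square-root option behind a flag — for 3-replicate
groups well inside (0,1) the transform changes little. The qualitative
outcomes are `stable`, `erasure` (bias → balanced), `novel_bias`
(balanced → biased) and `shifted_bias` — a fourth bin added because
altered points can keep or reverse a bias (0.9 → 0.7), which the
classic two-outcome dichotomy cannot express. Subgenome dominance is
summarized per genotype as the mean per-gene A-fraction, bias counts,
and a paired t-test (paired by gene) against the mix baseline; natural
accessions are compared against the same mix baseline because no
per-accession parental mix exists.

## The synthetic-data generator

`simulate_expression()` emulates the study design the classifiers
target, with planted truth for everything downstream:

* Baseline parental log2 means ~ Uniform(4, 12); PED genes (fraction
  `frac_ped`, default 0.70 — the divergence scale reported for wheat
  diploid parents) get an offset of magnitude in `ped_lfc_range`
  (default 1.5–4 log2 units) with random sign.
* The mix is the linear-scale average of the parental true means — a
  physical RNA pool, not a log-space average.
* Polyploid means follow the planted pattern, drawn from
  `category_mix` weights renormalized over the admissible set per gene
  (constant only for PEC; additive/ELD only for PED — the expression
  space enforced at generation time; asking for ELD with
  `frac_ped = 0` errors). TRE offsets sit at least
  `max(tre_min_delta, 2·replicate_sd·tre_sep_factor)` beyond the outer
  parent, so planted transgressive genes stay separated even as noise
  goes to zero.
* Nonadditive first draws are held fixed across all generations with
  probability `frac_transgen_consistent` (default 0.4, the middle of
  the consistent-share range this design is meant to produce); the
  rest re-draw in *every* generation, including the first, so
  generations are exchangeable and no generation is artificially
  enriched for nonadditivity.
* Replicate noise is Normal on the log2 scale (`replicate_sd`, default
  0.25 — a typical between-replicate SD for well-behaved array data; 3
  replicates per group as in the emulated design).

`simulate_homeolog()` plants a per-gene outcome class from the
`unaltered`/`erasure`/`novel_bias` weights. The outcome dictates the
baseline type — erasure needs a biased parental-ortholog ratio (0.5 ±
`baseline_bias`, Beta-spread around that mean), novel bias needs a
balanced one (pinned at exactly 0.5, so the planted dichotomy is
self-consistent) — and is applied to every generation. Replicate noise
is Normal on the logit scale (`logit_sd`, default 0.12 ≈ a 3-point SD
at a 50:50 ratio, the precision of pyrosequencing-style allele
quantification); fractions are clamped to [0.01, 0.99]. Natural
accessions get the mix baseline shifted A-ward by `natural_shift`
(default 0.08), mirroring the subgenome dominance such accessions are
expected to show.

What the generator does **not** emulate: probe-level artifacts, batch
and hybridization effects, heavy-tailed or gene-dependent variance,
missing data, correlated genes, aneuploidy, or per-generation drift in
partitioning. Passing recovery tests therefore demonstrates the
correctness of the classification machinery under its own model, not
robustness to every pathology of real arrays.

## Numerical choices

* Zero-variance limits are defined, not errors: t = 0, p = 1 for equal
  means with zero variance; t = ±Inf, p = 0 otherwise. Near-constant
  data (variance at floating-point noise) take the same limits, which
  makes zero-noise recovery exact rather than flaky.
* When every gene-wise variance is zero the variance prior cannot be
  fitted; the moderated test falls back to the ordinary t with a
  warning.
* The variance-prior fit is the standard moment match on log
  variances, with the trigamma inverse solved by Newton iteration; a
  non-positive excess variance yields d₀ = ∞ (fully shared variance).
* Call tables are written sorted (tissue, generation, gene; radix
  order, locale-independent) with 6-decimal reals, so identical runs
  are byte-identical and write → read is the identity.
* Allele-fraction scale detection: values are percent iff any value
  exceeds 1; files whose values straddle 1 are rejected as ambiguous
  (a genuine percent file with entries below 1% would need manual
  conversion).

## Problem sizes

The test suite and acceptance script run at sizes chosen to give tight
statistical checks while staying desk-sized: 5,000 genes × 4
generations for the noisy recovery bar (≥ 90% at `replicate_sd` 0.25,
3 replicates, separations ≥ 1.5 log2 units), 250 genes for the exact
zero-noise checks, 2,500 null genes for type-I-error calibration
(within 3 binomial SEs of α = 0.05), and 100 seeded 60-gene
simulations for the structural invariants. The analysis scripts use
2,000 genes × 2 tissues.

## Known limitations

* The detection rule is a stand-in for probe-level present/absent
  flagging; counts of "expressed genes" depend on its threshold and
  are not comparable to array flag counts.
* "Additive" is a non-rejection call; power depends on replicate
  number and noise, and a raised α can only move genes from additive
  to nonadditive (asserted as an invariant), never the reverse.
* Partitioning tests treat replicate fractions as independent
  normals; with 3 replicates the t-tests are exact only under
  normality on the chosen scale.
* The pipeline consumes normalized log2 matrices; normalization and
  probe summarization are out of scope by design.
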