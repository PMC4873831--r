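# polyshock

Classification of gene-expression responses to allopolyploidy
("transcriptome shock") from replicated expression profiles, for plant
genomicists studying synthetic or natural allopolyploids alongside
their diploid parents.

When two diverged genomes merge into one nucleus, each gene's total
expression can stay at the mid-parent expectation or be rewired, and
the two subgenome copies (homeologs) can re-partition their
contributions. `polyshock` implements the full classification chain on
a genes × samples log2 expression matrix (parents, a 1:1 parental RNA
mix, polyploid generations) and a homeolog allele-fraction table:

- **PEC/PED** — are the two parents' orthologs expressed equally
  (parental expression-conserved) or differentially
  (parental expression-differential)?
- **Additivity** — does the polyploid match the mid-parent value (MPV),
  represented by the measured 1:1 RNA mix or by the computed
  linear-scale average `log2((2^a + 2^b)/2)`?
- **Pattern** — nonadditive genes are resolved into expression-level
  dominance (ELD: matching one parent, differing from the other; PED
  genes only) or transgressive expression (over-/under-TRE: beyond both
  parents), with an explicit `ambiguous` bin for the remainder.
- **Transgenerational consistency** — genes keeping the same
  nonadditive pattern across all generations, decomposed into
  PEC/PED × TRE/ELD sources.
- **Homeolog partitioning** — per comparable data point (gene ×
  generation with a category call and replicated allele fractions in
  both polyploid and mix), altered partitioning and its qualitative
  outcome: stable, erasure of parental bias, novel bias, or shifted
  bias; plus per-genotype subgenome-dominance summaries.

## Statistics

Group contrasts use an empirical-Bayes moderated t-statistic: with
gene-wise pooled variance s²_g on df degrees of freedom and a prior
(d₀, s₀²) fitted across genes by moment matching on log variances,

    s̃²_g = (d₀·s₀² + df·s²_g) / (d₀ + df)
    t̃_g  = (x̄₁ − x̄₂) / (s̃_g · √(1/n₁ + 1/n₂)),   t̃_g ~ t(d₀ + df)

P-values are adjusted by the Benjamini–Yekutieli step-up
(q_(i) = min_{j≥i} m·c(m)/j · p_(j), c(m) = Σ 1/k), valid under
arbitrary dependence; the FDR threshold defaults to 0.05. Partitioning
and bias calls use plain Welch/one-sample t-tests at raw p < 0.05, and
count comparisons use the continuity-corrected two-proportion
chi-square test. All thresholds are configurable.

A synthetic-data generator (`sim_config()`, `simulate_expression()`,
`simulate_homeolog()`) plants known PEC/PED status, expression
patterns, transgenerational consistency and partitioning outcomes, so
every classification can be scored against ground truth
(`score_pattern_recovery()` and friends).

## Worked example

The `analysis/` scripts run the whole workflow on a simulated study
(2,000 genes, two tissues, parents + mix + four polyploid generations,
3 replicates, 150 pyrosequenced genes):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_classify.R
Rscript analysis/03_transgen.R
Rscript analysis/04_homeolog.R
Rscript analysis/05_report.R
```

which prints, among other things:

```
leaf: 1949 genes pass detection; PED fraction 0.71
leaf: additive share by generation S5=0.576, S6=0.573, S7=0.577, S8=0.574
leaf: 416 genes keep the same nonadditive pattern in every generation
leaf: TRE share among consistent genes 0.815 (TRE vs ELD prop-test p = 3.36e-73)
leaf: pattern recovery 98.2%, transgenerational sensitivity 90.4%,
      partitioning recovery 97.9%
```

The PED fraction recovers the planted 0.70 divergence rate; roughly
58% of calls are additive; and the recovery report at the end scores
every call against the planted truth. Tables land under `results/`.

Equivalent one-call form:

```r
library(polyshock)
res <- run_pipeline(run_config(simulate = sim_config(n_genes = 2000, seed = 1)),
                    out_dir = "results/run")
head(res$calls)
```

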