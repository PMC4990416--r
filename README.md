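# refsel

Reference-gene selection and efficiency-corrected quantification for
quantitative PCR, for anyone who measures transcripts by qRT-PCR and
needs defensible normalisation: the package takes long-format Ct tables
and standard-curve dilution series and carries them through stability
analysis, reference-set choice, normalisation and group comparison,
with an in-silico checker for DNA-refractory assay layouts and a
simulator for validating the whole pipeline against known truth.

## What it computes

* **Quantification.** Standard curves are ordinary least squares of Ct
  on log2 relative template concentration; the efficiency is
  `2^(-1/slope)` (slope −1 ⇔ perfect doubling). Experimental Cts are
  divided by the gene's slope, giving log2 relative quantities `q` in
  which equal differences mean equal template ratios for every assay.
  Everything downstream stays on the log2 scale; ratios appear only in
  final reports.
* **geNorm.** Gene stability `M_j` = mean over partners k of
  `sd_s(q_j − q_k)`; stepwise elimination of the argmax; pairwise
  variation `V(n, n+1)` = sd of the change in sample normalisation
  factors when the (n+1)-th ranked gene joins the pool, with the
  conventional 0.15 inclusion cutoff.
* **NormFinder-type model.** `q_igj = α_i + b_gj + d_ig + ε_igj` with
  per-gene-and-group variances; stability
  `ρ_i = mean_g(|d̃_ig| + sqrt(σ̂²_ig/n_g))` after bias-corrected
  variance estimation and empirical-Bayes shrinkage of the inter-group
  deviations `d`. Combinations are scored with the member-mean `d̃`
  (opposite deviations cancel) — including a greedy stepwise path and a
  nested-loop search that scores *all* combinations of every size while
  an outer loop eliminates the least stable candidate, writing every
  evaluated set to a ledger.
* **Robustness.** Leave-one-group-out re-ranking with rank ranges and
  top-m set preservation counts.
* **Group statistics.** Cell means with one pooled variance per gene,
  pairwise t contrasts, Bonferroni correction over the whole family,
  fold changes with exponentiated confidence intervals.
* **Assay layout.** Exact primer placement, unique-product amplicon
  prediction, exon-junction rules (each primer wholly within a
  different exon; probe spans a spanned junction), and genomic amplicon
  length = mRNA length + spanned introns, with unknown introns
  propagated.
* **Simulation.** `simulate_experiment()` draws complete experiments
  (Ct table, dilution series, annotation, truth ledger) from the same
  additive model; presets emulate a 12-tissue × 6-bird panel and a 2×2
  infection-by-interferon fibroblast design.

## A worked example

```r
library(refsel)
sim <- simulate_experiment(sim_preset("fibroblast_2x2", seed = 7))
cfg <- workflow_config(ct = sim$ct, annotation = sim$annotation,
                       curves = sim$curves,
                       exclude_genes = c("B2M", "28s", "IL8", "TGFB"),
                       baseline = "u_c")
res <- run_workflow(cfg)
print(res$genorm)
```

```
geNorm analysis
  M values: ACTB=0.153, HMBS=0.136, HPRT1=0.126, PGK1=0.132, PLA2=0.128, PPIA=0.141, RPL13=0.154, RPLP0=0.153, TBP=0.145 
  ranking (most stable first): PGK1 > PLA2 > HPRT1 > PPIA > TBP > HMBS > RPLP0 > ACTB > RPL13 (first two tied: PGK1/PLA2)
  V series: V2:3=0.030, V3:4=0.028, V4:5=0.022, V5:6=0.018, V6:7=0.018, V7:8=0.016, V8:9=0.014 
  include 2 genes (cutoff 0.15)
```

Two reference genes already satisfy the V < 0.15 criterion in this
homogeneous cell-culture design (real tissue panels typically need
more). The infection-responsive gene B2M, excluded from the candidate
set and normalised against the selected references, comes back with its
designed ≈3.5-fold maximum inter-group change:

```r
subset(res$relative, gene == "B2M")
```

```
  gene group delta_log2         se     fold fold_ci_lo fold_ci_hi
5  B2M   u_c  0.0000000 0.00000000 1.000000   1.000000   1.000000
6  B2M   u_a  0.4061599 0.09828447 1.325154   1.142359   1.537198
7  B2M   i_c  1.7671782 0.09828447 3.403875   2.934337   3.948546
8  B2M   i_a  1.9282433 0.09828447 3.805915   3.280919   4.414918
```

`delta_log2` is the log2 difference from the uninfected/untreated
baseline (`u_c`), `fold = 2^delta_log2`, and the CI bounds are the
t-interval on the log2 scale exponentiated at the end. Groups are
`u`/`i` for uninfected/infected crossed with `a`/`c` for with/without
interferon pre-treatment.

A command-line wrapper over the same functions ships in
`inst/cli/refsel.R` (`stdcurve`, `quantify`, `genorm`, `normfinder`,
`nested`, `normalize`, `diffexpr`, `robustness`, `checkassay`,
`simulate`, `run`).

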