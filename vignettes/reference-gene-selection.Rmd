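---
title: "Selecting and using qPCR reference genes with refsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting and using qPCR reference genes with refsel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refsel)
```

## The problem

Quantitative RT-PCR measures a transcript's abundance through the
quantification cycle Ct: the PCR cycle at which fluorescence crosses a
fixed threshold. Ct depends not only on the transcript's true level but
also on how much RNA was recovered from each sample. The standard remedy
is normalisation against *reference* (housekeeping) transcripts assumed
stable across the experimental conditions — but no gene is universally
stable, so a suitable subset must be selected from a candidate panel for
every new experimental context. `refsel` implements that whole workflow:
efficiency-corrected quantification, two complementary stability
analyses (geNorm and a NormFinder-type model, including an exhaustive
nested-loop combination search), robustness checks, multi-gene
normalisation, and group comparison with gene-specific variances, plus
an in-silico checker for the primer/probe exon layout that makes an
assay refractory to genomic DNA, and a simulator that generates complete
experiments with known truth.

## Quantification model

A dilution series of template measured at log2 relative concentrations
$x$ gives a standard curve $\mathrm{Ct} = a + bx$. With perfect two-fold
amplification per cycle the slope is $b = -1$; the per-cycle efficiency
is $2^{-1/b}$. Working in log2 (rather than log10) makes the slope
directly interpretable. Experimental Cts are converted to log2 relative
quantities by $q = \mathrm{Ct}/b$, so that equal differences in $q$
represent equal template ratios for every assay, whatever its
efficiency. The intercept $a$ is the log2 of the (arbitrary) threshold
amount and is estimated far outside the dilution range, so absolute $q$
values are meaningless: only within-gene differences between samples
carry information, and every downstream statistic in the package is
invariant to adding a constant to a gene's row or to a sample's column.

All computation stays on the log2 scale — measurement error and
biological variation are approximately normal there — and log
differences become ratios (fold changes) only in the final reports.

Tunable parameters: curves are *flagged* (never rejected) when the
efficiency $2^{-1/b}$ leaves `[1.8, 2.2]` fold/cycle or $R^2 < 0.98$;
both bounds are arguments of `fit_standard_curve()`. The slope CI uses
Student's t with $n-2$ df. Genes without a curve fall back to a fixed
slope of $-1$ (plain delta-Cq), which `ct_to_log2_quantity()` lets you
disable. Ct values must lie in `(0, max_cycles]` with `max_cycles = 40`
by default (the usual cycling limit); no-signal wells are `NA`, never 0
or 40.

## geNorm

For genes $j,k$ the pairwise log-ratio across samples is
$A_{jk,s} = q_{j,s} - q_{k,s}$; its sample standard deviation (n−1
denominator throughout) is $V_{jk}$, and the stability of gene $j$ is
$M_j = \mathrm{mean}_{k \ne j} V_{jk}$. Stepwise selection repeatedly
recomputes $M$ and removes the argmax until two genes remain; those two
cannot be resolved by a pairwise measure and are reported as a tied
pair. To decide how many genes to use, the normalisation factor
$\mathrm{NF}_{n,s}$ is the mean log2 quantity of the top $n$ genes and
$V(n,n+1) = \mathrm{sd}_s(\mathrm{NF}_{n,s} - \mathrm{NF}_{n+1,s})$;
genes are added until $V$ first drops below the conventional cutoff
0.15 (an argument, not a constant).

geNorm assumes candidate genes are not co-regulated: two correlated
genes have a quiet mutual ratio and can protect each other's ranking.

## The NormFinder-type model

With samples annotated by experimental group, the model for gene $i$,
group $g$, sample $j$ is

$$ q_{igj} = \alpha_i + b_{gj} + d_{ig} + \varepsilon_{igj}, \qquad
\mathrm{Var}(\varepsilon_{igj}) = \sigma^2_{ig}, $$

where $b_{gj}$ is a per-sample loading effect common to all genes and
$d_{ig}$ the gene's systematic inter-group deviation, with the
identifying assumption $\sum_i d_{ig} \approx 0$ (the panel is stable on
average). Centering each sample on its across-gene mean removes
$\alpha$ and $b$; group means of the centred values estimate $d$; the
centred within-group variances $v_{ig}$ are corrected for the
correlation the centering induces by solving the moment equations

$$ \hat S_g = \tfrac{k}{k-1} \textstyle\sum_i v_{ig}, \qquad
\hat\sigma^2_{ig} = \left(v_{ig} - \hat S_g / k^2\right)\tfrac{k}{k-2}, $$

truncated at 0 (hence the requirement of at least three genes). The $d$
estimates are shrunk with the empirical-Bayes factor
$\hat\gamma^2 / (\hat\gamma^2 + \hat\sigma^2_{ig}/n_g)$, where
$\hat\gamma^2 = \sum d^2 / ((k-1)(G-1)) - \overline{\hat\sigma^2/n}$,
truncated at 0. A gene's stability is

$$ \rho_i = \mathrm{mean}_g\!\left( |\tilde d_{ig}| +
\sqrt{\hat\sigma^2_{ig}/n_g} \right), $$

balancing systematic inter-group deviation against intra-group noise;
with one group it reduces to a purely intra-group measure. For a set
$S$ the normalisation factor averages members, so the set's inter-group
term is $|\mathrm{mean}_{i \in S}\, \tilde d_{ig}|$ — deviations of
opposite sign cancel, which is why the best pair can beat both of its
members — and its intra-group term is
$\sqrt{\sum_{i\in S}\hat\sigma^2_{ig}}\,/\,(|S|\sqrt{n_g})$, so the
formula reduces exactly to $\rho_i$ for a singleton and set and single
stabilities are directly comparable. Sets are scored under the model
fitted once on the full candidate matrix, not refitted per subset.

The exact constants of this fit are pinned by a parameter-recovery
test rather than by reference to any particular implementation: on data
simulated from the model itself ($k=8$, $G=3$, $n_g=50$, 200
replicates) the mean $\hat\sigma^2$ must sit within 5% of truth and the
estimated stability ranking must equal the true ranking in at least 95%
of replicates. The suite runs exactly that check.

### Greedy and nested-loop selection

The classic stepwise extension grows the reference set greedily: the
best pair, then the best superset of it of each size. Because of
compensation, the best $m$-set need not contain the best $(m-1)$-set,
and unstable candidates left in the panel bias the across-gene
centering. `nested_normfinder()` therefore (a) scores *all*
combinations of every size among the eligible genes, and (b) wraps the
search in an outer loop that removes the least stable candidate and
refits until three remain, recording every evaluated combination and
the greedy path in a ledger. Optional filters exclude genes from
combination membership by stability value or rank; filters apply after
each refit and before enumeration. When the filters leave fewer than
two eligible genes the iteration records "no eligible combination"
rather than failing. Exhaustive enumeration refuses more than 20
eligible genes unless forced. Exhaustive-best-of-size can never be
worse than the greedy set of that size (the greedy set is in the
enumerated universe); the suite verifies zero violations over 100
simulated instances, and the typical improvement is small — which is
why the greedy sets remain a sensible default.

Determinism: every argmin/argmax tie anywhere in the package breaks
lexicographically on (sorted) gene names, in the C locale, and is
recorded where relevant.

## Normalisation and group comparison

`normalization_factors()` averages the chosen reference genes' log2
quantities per sample (the log2 of their geometric mean);
`apply_normalization()` subtracts them, cancelling per-sample loading.
Reference genes are dropped from the normalised matrix by default —
their flatness after normalisation is an artefact of their use — but
can be kept for display. An rRNA assay is treated as an ordinary gene
column, so rRNA-based normalisation is expressed as `refs = "28s"`.

Group comparison uses cell means per gene × group with a single
residual variance per gene pooled across groups (the error structure
selected for both motivating designs), fitted in closed form. The
residual df is the per-gene $\sum_g (n_g - 1)$ — a deliberate,
documented simplification of a joint generalised-least-squares fit; in
the balanced case it coincides with it exactly, and a simulated-null
test bounds the family-wise type-I error. Contrasts are two-sided t
tests; the Bonferroni family is every test in the invocation
($m = \#\text{genes} \times \#\text{pairs}$, printed in the output),
$p_{\text{adj}} = \min(1, m\,p)$, with significance tiers at adjusted
0.05/0.01/0.001. Fold changes and their CIs are $2^{\Delta}$ and
$2^{\Delta \pm t^* \mathrm{se}}$, computed only at report time.

## Assay layout checking

A TaqMan assay refractory to genomic DNA needs each primer wholly
inside a different exon — so the amplicon spans at least one
intron — and the probe spanning a spanned junction.
`find_amplicon()` places primers by exact matching (the panel's assays
match their targets perfectly; mismatch-tolerant search is out of
scope), demands a unique oriented product, and reports 0-based
half-open coordinates with both primers counted in the length.
`check_assay_layout()` maps primers and probe (searched on both
strands) onto a `gene_model()` of exon intervals and predicts the
genomic amplicon as mRNA length plus spanned intron lengths, with
unknown introns (missing from the assembly) propagating to an unknown
DNA length. The packaged `assay_panel.csv` carries the ten-assay
chicken panel with its accession manifest; transcript sequences are not
bundled, but two *synthetic* two-exon constructs
(`synthetic_transcripts.fa`, generated, labelled as such) embed the
real ACTB and HPRT1 primers with the published amplicon geometry so the
checker has an executable example offline.

## The simulator and what passing tests mean

`simulate_experiment()` draws data from exactly the additive model
above (plus the standard-curve layer), with a truth ledger. Two presets
fix the study conditions:

* `tissue_panel`: 12 tissues × 6 birds, the ten-gene panel plus a
  "28s" column. Fixed tissue-deviation profiles (constants of the
  preset, identical across seeds) with scale 0.4 for the designed
  stable four (HMBS, TBP, RPL13, RPLP0), 0.55 for the other candidates
  and 0.7 for rRNA; PGK1 carries an extra +3.5 log2 deviation in heart
  (the designed-unstable gene); skin has a −1.5 loading offset (less
  RNA recovered); loading sd τ = 0.5 dominates gene noise σ = 0.2.
* `fibroblast_2x2`: 4 groups (±infection × ±interferon) × 4 embryos;
  B2M responds to infection with a maximum deviation of 1.807 log2
  (≈3.5-fold), IL8 to treatment, the rRNA column rises with infection,
  and the remaining candidates are near-stable (σ = 0.12, τ = 0.4).

The simulator emulates the *structure* of real experiments — loading
effects, group deviations, assay efficiencies near −1, technical
replicates, dilution series — but not everything real data has: gene
noise is independent across genes (no co-regulation), deviations are
homoscedastic within group, and there are no plate-position effects or
amplification failures. Passing the end-to-end tests therefore shows
the algorithms recover what they model, not that any particular real
panel is stable. One visible consequence: the simulated tissue panel
satisfies the geNorm V < 0.15 criterion with two genes, whereas a real
tissue collection — whose "stable" genes still share structured
inter-tissue variation — typically needs more. The suite asserts
design-based properties (the designed-unstable gene is eliminated first
in ≥95/100 runs; normalisation removes the designed loading-variance
share), not dataset-specific counts.

Problem sizes used by the test-suite and the acceptance script: 50
random panels (≤8 genes × ≤12 samples) for the geNorm oracle
comparison; 200 replicates at $k=8$, $G=3$, $n_g=50$ for NormFinder
recovery; 100 instances ($k=8$, $G=3$, $n_g=6$) for nested-loop
dominance; 200 null replicates (6 genes × 4 groups of 4) for
family-wise error; 100 tissue-preset seeds for end-to-end recovery.

## Reproducing a published analysis

The workflow was built around a published chicken reference-gene study
whose raw Ct deposit is distributed as supplementary material and is
not redistributable here. `run_workflow()` reproduces its analysis
directly once the deposit's long-format CSVs are placed under
`inst/extdata/s1_raw_ct/` (see the acceptance test of the same name for
the expected file names); the corresponding suite block fails with an
explanatory message while the deposit is absent. Raw-Ct geNorm input is
available via `genorm_input = "ct"`, matching analyses that rank on Ct
directly; it coincides with the slope-adjusted ranking exactly when all
slopes are equal.

## Known limitations

* No inter-run calibration: the quantification model assumes each gene
  (samples plus standards) was run on a single plate with one
  threshold.
* Missing data: geNorm offers a pairwise-complete mode (≥3 shared
  samples per pair); the NormFinder fit requires a complete matrix.
* The per-gene-variance group model deliberately omits Welch-type
  corrections and random effects for biological units.
* Exact primer matching only; no melting temperature, dimer or
  secondary-structure prediction.
* The nested-loop search is exhaustive by design and guards itself
  above 20 eligible genes.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_experiment(sim_preset("fibroblast_2x2", seed = 7))
cfg <- workflow_config(ct = sim$ct, annotation = sim$annotation,
                       curves = sim$curves,
                       exclude_genes = c("B2M", "28s", "IL8", "TGFB"),
                       baseline = "u_c")
res <- run_workflow(cfg)
print(res$genorm)
subset(res$relative, gene == "B2M")
```
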