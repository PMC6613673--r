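---
title: "Models and methods behind niptsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind niptsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(niptsim)
library(dplyr)
```

`niptsim` implements a complete simulation-and-inference stack for targeted
high-coverage sequencing based non-invasive prenatal testing (NIPT): a
cell-free DNA (cfDNA) count simulator, fetal-fraction estimation from
allelic ratios, three locus-level hidden Markov models (HMMs) decoded by
the Viterbi algorithm, and chromosome-level calling by the modal decoded
condition or by supplemental machine-learning classifiers. This vignette
explains the models, their assumptions, the tunable parameters, and the
design choices where the methodology was genuinely open.

## The generative model of targeted cfDNA counts

A pregnant woman's plasma cfDNA is a mixture of maternal DNA (proportion
`1 - FF`) and placental ("fetal") DNA (the fetal fraction `FF`). A
targeted assay sequences a panel of biallelic SNPs (alleles A and B, minor
allele frequency `maf`, default 0.5 as for assay-selected common variants)
on a studied chromosome and on a reference chromosome assumed disomic in
both mother and fetus.

One simulated sample is built in four steps:

1. **Parental haplotypes.** Each parent receives two homologous
   chromosomes of `n_loci` SNPs (default 1,000); each haplotype carries B
   at a locus independently with probability `maf`.
2. **Recombination.** Each parental pair undergoes one crossover: a count
   `k ~ Uniform{0, ..., n_loci}` of terminal alleles is exchanged between
   the homologs. A `crossover = "subset"` switch instead swaps a random
   set of `k` positions; both readings conserve the per-locus allele
   multiset, and contiguity is irrelevant for whole-chromosome inference.
3. **Fetal chromosome set.** Euploidy draws one recombined homolog from
   each parent. A meiosis-I maternal trisomy transmits *both* recombined
   maternal homologs plus one paternal homolog (heterodisomy at loci where
   the mother is heterozygous); a paternal trisomy is the mirror image.
   Meiosis-II and mitotic trisomies are not modelled.
4. **Allele counts.** With maternal/fetal copy numbers `d_m(x)`, `d_f(x)`
   of allele `x`, the expected depth is
   `mu_x = RD * ((1 - FF) * d_m(x)/2 + FF * d_f(x)/2)`, so a trisomic
   locus has expected total `RD * (1 + FF/2)`. Counts are negative
   binomial with `E = mu` and `Var = vmr * mu` (parameterized as
   `p = 1/vmr`, `r = mu * p/(1 - p)`; `mu = 0` yields a deterministic 0).
   `vmr = 3` reflects the over-dispersion of targeted sequencing counts.
   Sequencing errors and missing data are deliberately not simulated: a
   targeted assay knows its alleles in advance, and spurious reads are
   excluded upstream.

Each sample also carries a euploid reference chromosome simulated with the
same `n_loci`, read depth and fetal fraction — the substrate for
fetal-fraction estimation.

## Informative SNPs and fetal fraction

Only SNPs heterozygous in mother and/or fetus ("informative") carry fetal
signal in their allelic imbalance. At `maf = 0.5`, genotype enumeration
gives informative fractions of 0.75 under euploidy and maternal trisomy
and 0.875 under paternal trisomy (both paternal alleles contribute):

```{r}
informative_fraction_theory(0.5, "maternal_trisomy")
informative_fraction_theory(0.5, "paternal_trisomy")
```

The allelic ratio of a SNP is its major over minor count (`>= 1`). On the
reference chromosome, loci where the mother is homozygous and the fetus
heterozygous satisfy `ratio > 2.5` (their noise-free ratio is
`(2 - FF)/FF`, i.e. 19 at `FF = 0.10`), and at such loci the minor depth
is half the fetal contribution, so

```
FF_hat = median( 2 * min_i / (max_i + min_i) )
```

over the selected loci. Loci with a zero minor count pass the ratio filter
(the ratio is treated as infinite — they are genuine mother-homozygous
loci) and contribute 0 to the median, which keeps the estimator defined at
very low fetal fraction. The median makes the estimate order-invariant and
robust to the heavy right tail of minor-count noise. Estimation error
shrinks with read depth; at RD 5,000 the estimate is typically within 2
percentage points of truth.

For real data without genotypes, informativeness falls back to a
minor-count floor `min_i >= max(2, 0.005 * total)` — a small
absolute-plus-relative rule that rejects sequencing noise without
discarding low-FF fetal signal. The floor is a package choice; assays with
known error profiles should tune it.

## The hidden Markov models

Loci are ordered along the chromosome and decoded with log-space Viterbi
(uniform initial distribution, lowest-index tie-break; the kernel is a
small C++ routine, checked in the test suite against exhaustive path
enumeration).

* **RC (read count), 2 states.** Observations are locus totals; `EUP` and
  `TRI` emissions are Gaussians with moments estimated from labelled
  training loci (means near `RD` and `RD * (1 + FF/2)`, variances near
  `3 * mean`). Because read counts cannot reveal the fetal fraction, the
  deployed configuration fixes the emission model at the expected
  population median `FF = 10%` (`rc_fixed`); `rc_perfect` (emissions
  matched to each cell's true FF) is the oracle upper bound.
* **AR (allelic ratio), 7 states.** Observations are allelic ratios at
  informative loci. States are allelic patterns — combinations of fetal
  condition and maternal/fetal genotype class (`E1`-`E3`, `T1`-`T3`,
  `P1`); their noise-free expected ratios follow from dosage enumeration
  (`expected_allelic_ratio()`), e.g. `E3 = (2 - FF)/FF`, `T3 = 2/FF`,
  `P1 = (2 - FF)/(2 FF)`. `P1` — mother homozygous, fetus carrying two
  non-maternal copies — cannot arise under maternal meiosis-I trisomy and
  is the paternal-specific signature. The shared `T*` patterns are grouped
  with maternal trisomy to avoid over-calling paternal trisomy.
* **RCAR (combined), 7 states.** Bivariate (total, ratio) observations
  with diagonal Gaussian emissions; the count dimension adds the dosage
  signal the AR model lacks.

Transitions implement a stay-switch ratio of 10: staying within the
current fetal condition is ten times more likely than switching condition;
within-condition state changes carry no penalty, because the allelic
pattern legitimately changes at nearly every informative SNP. Emission
moments are estimated from 100 labelled training samples per grid
condition. Infinite ratios (zero minor count) are clamped to twice the
99th percentile of the finite training ratios before fitting and decoding
— Gaussian emissions need finite observations, and such loci still carry
mother-homozygous signal. Raw (not log) ratios are used, mirroring the
Gaussian approximation of the training moments; a log-ratio variant would
be a natural extension.

At decoding time the AR/RCAR emission model is selected per sample by its
*estimated* fetal fraction (nearest trained FF; the assumed 10% is the
fallback if no locus passes the FF filter), never the true one.

## Chromosome-level calling

* **Mode.** Sum decoded state frequencies within each condition group and
  call the strict maximum; an exact tie is `unclassified` (counted as
  incorrect in every accuracy).
* **Tree.** A depth-3, Gini, unpruned classification tree (rpart) on the
  features (RD, FF, state frequencies), seed 123.
* **Margin.** A soft-margin RBF support-vector classifier (libsvm via
  e1071) with cost 1, `gamma = 1/n_features`, one-vs-one multiclass, no
  feature standardization, seed 123.

One tree and one margin classifier are trained per model configuration on
the training profiles pooled across the whole (FF x RD) grid, matching the
single classifier columns of the study design. For the RC models the label
space collapses to euploidy/trisomy (read counts cannot see parental
origin); the 7-state models use all three conditions.

The unscaled feature space has a consequence worth knowing: with read
depth in raw units, the RBF kernel is effectively zero between samples of
different RD, so the margin classifier behaves like independent per-depth
classifiers sharing one global intercept, and it cannot exploit the
fetal-fraction feature (whose scale is far below the kernel width). The
axis-aligned tree can. This asymmetry — the tree outperforming the margin
classifier at low fetal fraction, and improving at *lower* read depth
where Viterbi paths are less locked — is a property of the fixed-FF
read-count pipeline itself: at high depth the per-locus likelihood gap
exceeds the switch penalty and low-FF trisomic samples decode to the
all-euploid path, discarding depth signal that a raw total-count statistic
would retain.

## The simulation experiments

`run_grid()` reproduces the accuracy study: 3 conditions x FF 1–20% (step
1%) x a read-depth set spanning 500–15,000, with 100 training and
(desk-scale) 200 test samples per cell; per-cell accuracies are aggregated
into fetal-fraction bands (1–5, 6–10, 11–15, 16–20%) and an overall
unweighted mean over cells. The full study's read-depth grid is uniform
(500 to 15,000 in steps of 500); the desk-scale default thins it to six
*uniformly spaced* depths {500, 3400, 6300, 9200, 12100, 15000}, because a
uniform subsample is the unbiased way to approximate an average over a
uniform grid — a log-like subsample would over-weight shallow depths and
systematically deflate every depth-sensitive aggregate. With 200 test
samples per cell, band aggregates carry Monte-Carlo noise of roughly
±0.01–0.03.

Two caveats on interpreting the scaled-down grid. First, at fetal
fractions below ~3% the E and T allelic-ratio emissions coincide to the
third decimal, so AR-model calls in those cells are decided by training
noise and whole cells flip between conditions; AR-model aggregates at low
FF are accordingly unstable. Second, accuracies within a cell are
correlated through the shared trained emission model, so cell-level
variation exceeds binomial noise.

`loci_subsample_experiment()` fixes RD = 1,000 and FF in {3%, 10%} and
subsamples 50–1,000 loci per sample before decoding, quantifying how many
robust targets an assay needs. `maf_informative_experiment()` compares
simulated informative-variant fractions against the closed-form
enumeration across MAF 1–50%.

What the simulator does *not* emulate: GC and mappability bias, per-probe
efficiency differences, sequencing error, maternal CNVs, mosaicism, twin
pregnancies. Passing the simulated-grid benchmarks therefore demonstrates
the statistical machinery under the stated noise model, not clinical
performance; the experimental pipeline below is the bridge to real data.

## Real count tables

`read_count_table()` ingests tab-separated UMI-collapsed molecule counts
(sample, chromosome, locus, position, count). Outlier target loci are
removed per (sample, chromosome) by Tukey fences `[Q1 - k*IQR, Q3 +
k*IQR]` with `k = 1.5` (configurable; groups under 4 loci are left
unfiltered with a warning). Fences are applied in a single pass — the
standard practice; note that re-filtering already-filtered noisy data can
trim a few more loci, since removing gross outliers shrinks the
interquartile range.

`call_experimental_sample()` then anchors RC emissions to the data itself
— euploid mean = mean retained reference-chromosome count, trisomy mean =
euploid mean x (1 + FF/2) with an assumed FF of 10%, variances = 3 x means
— because absolute molecule counts are assay-specific and simulation-
trained emissions would not transfer. The studied chromosome is decoded in
positional order and mode-called.

## Numerical and reproducibility choices

* Per-cell RNG seeds derive deterministically from one root seed and the
  cell index (all below 2^31), so any grid cell can be regenerated in
  isolation and training samples are regenerated bit-identically rather
  than stored.
* Viterbi ties break to the lowest-index state; batched decoding is
  bit-identical to sequence-by-sequence decoding.
* Quartiles use linear interpolation (R type 7).
* Tree and margin fits are deterministic given seed, data and feature
  order; refits are bit-identical.
* Degenerate inputs: `mu = 0` counts are exact zeros; empty informative
  sets raise classed errors; a sample whose FF estimate has no passing
  locus is flagged and decoded with the fallback 10% model.

## Known limitations

The 7-state models lose identifiability as FF approaches 1–2%; the RC
fixed-FF configuration discards depth signal at high RD (see above); the
margin classifier inherits the unscaled-feature kernel geometry of
"default parameters"; and chromosome-level calls assume whole-chromosome
aneuploidy — sub-chromosomal events are visible in the decoded locus
tracks (`plot_locus_states()`) but are not called.
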