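# niptsim

Hidden Markov model framework for targeted high-coverage cfDNA
aneuploidy detection (NIPT), with a full cfDNA count simulator.

## The problem

Non-invasive prenatal testing infers the fetal chromosomal state from the
cell-free DNA (cfDNA) in maternal plasma — a mixture of maternal DNA and a
fetal fraction *FF* of placental DNA. Most computational NIPT methods
target low-coverage whole-genome sequencing; **targeted** high-coverage
panels (hundreds of SNP loci per chromosome, UMI-collapsed molecule
counts) need different machinery. `niptsim` provides it, for method
developers and assay designers who need to know — before building a panel
— how detection accuracy depends on fetal fraction, read depth, locus
count and allele frequency.

At a targeted locus with maternal/fetal copy numbers *d_m*, *d_f* of an
allele, the expected allele depth is

```
mu = RD * ( (1 - FF) * d_m / 2 + FF * d_f / 2 )
```

with negative binomial noise (variance = 3 × mean), so a trisomic locus
has expected total `RD * (1 + FF/2)`, and an informative SNP (mother
and/or fetus heterozygous) has a diagnostic major/minor allelic ratio —
e.g. `(2 - FF)/FF` when the mother is homozygous and the fetus
heterozygous. Three hidden Markov models classify consecutive loci by
Viterbi decoding with empirically trained Gaussian emissions:

* **RC** — 2 states (euploidy/trisomy) over locus totals;
* **AR** — 7 allelic-pattern states over allelic ratios, separating
  maternally and paternally originated meiosis-I trisomy;
* **RCAR** — the bivariate combination.

Chromosome-level calls come from the modal decoded condition, a depth-3
decision tree, or a soft-margin RBF kernel classifier on the decoded
state frequencies (features: RD, FF, state proportions). The fetal
fraction itself is estimated as `median(2 * min / (max + min))` over
reference-chromosome SNPs with allelic ratio > 2.5.

## Worked example

```r
library(niptsim)
library(dplyr)

# one simulated cfDNA sample: maternal trisomy, FF 10%, depth 5000
cfg <- sim_config(read_depth = 5000, fetal_fraction = 0.10,
                  condition = "maternal_trisomy", seed = 42)
sample <- simulate_sample(cfg)

estimate_ff(sample)
#> # A tibble: 1 × 3
#>   ff_hat n_loci_used status
#>    <dbl>       <int> <chr>
#> 1 0.0989         261 ok

# train the combined 7-state HMM on labelled simulated loci
train <- bind_rows(lapply(
  c("euploidy", "maternal_trisomy", "paternal_trisomy"),
  function(cond) simulate_cohort(
    sim_config(read_depth = 5000, fetal_fraction = 0.10,
               condition = cond, seed = 7), n = 30, id_prefix = cond))) |>
  filter(role == "studied")
model <- fit_hmm(true_states(filter(informative_loci(train), informative),
                             "RCAR"), "RCAR")

mode_call(decode_sample(sample, model))
#> # A tibble: 1 × 5
#>   call          method mass_euploidy mass_maternal_trisomy mass_paternal_trisomy
#> 1 maternal_tri… mode         0.00956                 0.990                     0
```

The estimated fetal fraction (0.099, from 261 reference-chromosome SNPs)
recovers the simulated 10%, and 99% of the decoded informative loci fall
in maternal-trisomy states, so the chromosome is called a maternal
trisomy.

Accuracy experiments run through `run_grid()` (fetal-fraction × read-depth
grid, all models and calling methods), `loci_subsample_experiment()`
(accuracy versus number of targeted loci) and
`maf_informative_experiment()` (informative-SNP fraction versus minor
allele frequency); results are tibbles/report objects with `tidy()`,
`glance()` and `autoplot()` methods. Real UMI molecule-count tables enter
through `read_count_table()`, are cleaned with Tukey-fence `iqr_filter()`,
and are called with `call_experimental_sample()`. A command-line wrapper
for the simulate/train/call/evaluate pipeline lives at `inst/cli/nipt.R`.

See the methods vignette (`vignettes/niptsim-methods.Rmd`) for the models,
assumptions and design decisions.

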