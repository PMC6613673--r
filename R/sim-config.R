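#' Simulation configuration
#'
#' Bundles the parameters of one simulated cell-free DNA (cfDNA) sequencing
#' condition: the number of targeted SNP loci on the studied chromosome, the
#' population minor-allele frequency of the targets, the mean sequencing read
#' depth per locus, the fetal fraction (proportion of cfDNA of placental
#' origin), the fetal chromosomal condition, and the over-dispersion of the
#' count noise.
#'
#' Allele counts are drawn from a negative binomial distribution whose
#' variance-to-mean ratio is `vmr` (3 by default, matching the
#' over-dispersion typical of targeted sequencing counts). A trisomic locus
#' raises the expected total count by a factor `1 + fetal_fraction / 2`.
#'
#' @param n_loci Number of targeted SNP loci per chromosome (default 1000).
#' @param maf Minor-allele frequency of the targeted SNPs, in `[0, 0.5]`.
#' @param read_depth Mean reads (or UMI-collapsed molecules) per locus.
#' @param fetal_fraction Fetal fraction in `(0, 1)`; the study grid spans
#'   0.01--0.20.
#' @param condition Fetal chromosomal condition: `"euploidy"`,
#'   `"maternal_trisomy"` or `"paternal_trisomy"` (meiosis-I origin).
#' @param vmr Variance-to-mean ratio of the negative binomial count noise;
#'   must exceed 1.
#' @param n_train Training samples per condition used to fit model emissions.
#' @param n_test Test samples per condition used in accuracy evaluation.
#' @param seed Optional integer seed; when set, simulation functions that
#'   receive this config re-seed the RNG so output is reproducible.
#' @param crossover Recombination mode: `"suffix"` swaps a contiguous suffix
#'   at a single uniform breakpoint (a single chromosomal crossover);
#'   `"subset"` swaps a uniformly chosen random subset of positions.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(read_depth = 1000, fetal_fraction = 0.1,
#'                   condition = "maternal_trisomy", seed = 1)
#' cfg
#' @export
sim_config <- function(n_loci = 1000, maf = 0.5, read_depth = 1000,
                       fetal_fraction = 0.10, condition = "euploidy",
                       vmr = 3, n_train = 100, n_test = 200, seed = NULL,
                       crossover = c("suffix", "subset")) {
  crossover <- match.arg(crossover)
  condition <- match_condition(condition)
  if (!is.numeric(n_loci) || n_loci < 1) {
    abort("`n_loci` must be a positive integer.", class = "niptsim_config_error")
  }
  if (!is.numeric(maf) || maf < 0 || maf > 0.5) {
    abort("`maf` must lie in [0, 0.5].", class = "niptsim_config_error")
  }
  if (!is.numeric(read_depth) || read_depth <= 0) {
    abort("`read_depth` must be positive.", class = "niptsim_config_error")
  }
  if (!is.numeric(fetal_fraction) || fetal_fraction <= 0 || fetal_fraction >= 1) {
    abort("`fetal_fraction` must lie in (0, 1).", class = "niptsim_config_error")
  }
  if (!is.numeric(vmr) || vmr <= 1) {
    abort("`vmr` must exceed 1 (over-dispersed counts).",
          class = "niptsim_config_error")
  }
  structure(
    list(n_loci = as.integer(n_loci), maf = maf, read_depth = read_depth,
         fetal_fraction = fetal_fraction, condition = condition, vmr = vmr,
         n_train = as.integer(n_train), n_test = as.integer(n_test),
         seed = if (!is.null(seed)) as.integer(seed), crossover = crossover),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  loci: %d  MAF: %.2f  RD: %g  FF: %.2f\n",
              x$n_loci, x$maf, x$read_depth, x$fetal_fraction))
  cat(sprintf("  condition: %s  vmr: %g  crossover: %s\n",
              x$condition, x$vmr, x$crossover))
  cat(sprintf("  n_train: %d  n_test: %d  seed: %s\n",
              x$n_train, x$n_test,
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

# Deterministic per-cell seed derived from a root seed, kept under 2^31.
cell_seed <- function(seed, index, stream = 1L) {
  as.integer((as.double(seed) + 7919 * index + 104729 * stream) %% 2147483647)
}
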