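# Independent oracles used by the tests; these re-derive expected values by
# brute force and stay separate from the package implementation.

# Exhaustive-enumeration Viterbi: scores every possible state path with
# diagonal-Gaussian emission log-likelihoods and returns the best path
# (first in lexicographic order on ties, matching lowest-index tie-break).
brute_force_viterbi <- function(obs, mean, var, trans, init) {
  if (!is.matrix(obs)) obs <- matrix(obs, ncol = 1)
  K <- nrow(mean); T_ <- nrow(obs)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))[, T_:1,
                                                             drop = FALSE]
  loglik <- apply(paths, 1, function(path) {
    ll <- log(init[path[1]])
    for (t in seq_len(T_)) {
      ll <- ll + sum(stats::dnorm(obs[t, ], mean[path[t], ],
                                  sqrt(var[path[t], ]), log = TRUE))
      if (t > 1) ll <- ll + log(trans[path[t - 1], path[t]])
    }
    ll
  })
  # lexicographic-first among maxima = lowest-index tie-break at every step
  ord <- do.call(order, c(list(-loglik), lapply(seq_len(T_), function(t) {
    paths[, t]
  })))
  paths[ord[1], ]
}

# Exact informative-SNP probability by explicit enumeration of parental
# alleles and transmitted combinations (independent of the package's
# closed-form function).
oracle_informative_fraction <- function(maf, condition) {
  p <- c(1 - maf, maf)  # P(A), P(B)
  total <- 0
  for (m1 in 1:2) for (m2 in 1:2) for (f1 in 1:2) for (f2 in 1:2) {
    pg <- p[m1] * p[m2] * p[f1] * p[f2]
    fetal_sets <- switch(condition,
      euploidy = list(c(m1, f1), c(m1, f2), c(m2, f1), c(m2, f2)),
      maternal_trisomy = list(c(m1, m2, f1), c(m1, m2, f2)),
      paternal_trisomy = list(c(m1, f1, f2), c(m2, f1, f2)))
    informative <- vapply(fetal_sets, function(fet) {
      m1 != m2 || length(unique(fet)) > 1
    }, logical(1))
    total <- total + pg * mean(informative)
  }
  total
}

# Noise-free expected allele counts for a (maternal, fetal) genotype pair:
# used to check allelic-ratio formulas by dosage enumeration.
oracle_expected_counts <- function(maternal, fetal, rd, ff) {
  d <- function(g, allele) sum(strsplit(g, "")[[1]] == allele)
  c(a = rd * ((1 - ff) * d(maternal, "A") / 2 + ff * d(fetal, "A") / 2),
    b = rd * ((1 - ff) * d(maternal, "B") / 2 + ff * d(fetal, "B") / 2))
}
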