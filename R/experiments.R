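#' Detection accuracy as a function of the number of targeted loci
#'
#' Subsamples loci uniformly at random from each simulated sample of a
#' full-size chromosome, decodes the subsampled sequence with the
#' read-count HMM (emissions matched to each fetal fraction by default, or
#' fixed at `fixed_ff`), and scores chromosome-level calls by mode,
#' decision tree and kernel margin (the supplemental classifiers are
#' refitted per locus count on the correspondingly subsampled training
#' profiles).
#'
#' @param seed Root seed.
#' @param n_loci_set Locus counts to evaluate.
#' @param rd Mean read depth (fixed, default 1000).
#' @param ff_set Fetal fractions evaluated (default 3% and 10%).
#' @param n_loci_full Loci per simulated chromosome before subsampling.
#' @param n_train,n_test Samples per condition and fetal fraction.
#' @param emissions `"matched"` trains RC emissions per evaluated fetal
#'   fraction (the plain RC configuration); `"fixed"` uses one model
#'   trained at `fixed_ff`.
#' @param fixed_ff Fetal fraction of the RC emission model when
#'   `emissions = "fixed"`.
#' @param maf,vmr,stay_switch_ratio As in [run_grid()].
#' @param methods Chromosome-level methods.
#' @return A tibble with per-(n_loci, ff, method, condition) accuracies;
#'   conditions are the RC label space (`euploidy` / `trisomy`), with
#'   trisomy pooled over maternal and paternal origin.
#' @export
loci_subsample_experiment <- function(seed = 1,
                                      n_loci_set = c(50, 100, 200, 500, 1000),
                                      rd = 1000, ff_set = c(0.03, 0.10),
                                      n_loci_full = 1000, n_train = 100,
                                      n_test = 200,
                                      emissions = c("matched", "fixed"),
                                      fixed_ff = 0.10, maf = 0.5, vmr = 3,
                                      stay_switch_ratio = 10,
                                      methods = c("mode", "tree", "margin")) {
  methods <- match.arg(methods, several.ok = TRUE)
  emissions <- match.arg(emissions)
  if (any(n_loci_set > n_loci_full)) {
    abort("`n_loci_set` cannot exceed `n_loci_full`.",
          class = "niptsim_evaluate_error")
  }
  cfg <- function(ff, condition) {
    sim_config(n_loci = n_loci_full, maf = maf, read_depth = rd,
               fetal_fraction = ff, condition = condition, vmr = vmr,
               n_train = n_train, n_test = n_test)
  }

  # RC emission models: one per evaluated fetal fraction ("matched", the
  # plain RC configuration) or a single one at the assumed median FF.
  train_model <- function(ff, stream) {
    set.seed(cell_seed(seed, 0L, stream))
    cells <- setNames(lapply(nipt_conditions, function(cond) {
      sim_cell(n_train, cfg(ff, cond))
    }), nipt_conditions)
    fit_pair_models(cells, rd, ff, stay_switch_ratio)$rc
  }
  models <- if (emissions == "fixed") {
    m <- train_model(fixed_ff, 1L)
    setNames(rep(list(m), length(ff_set)), as.character(ff_set))
  } else {
    setNames(lapply(seq_along(ff_set), function(i) {
      train_model(ff_set[i], i)
    }), as.character(ff_set))
  }

  sim_totals <- function(ff, n, stream) {
    setNames(lapply(seq_along(nipt_conditions), function(ci) {
      cond <- nipt_conditions[ci]
      set.seed(cell_seed(seed, 100L * stream + ci, match(ff, ff_set)))
      ch <- sim_cell(n, cfg(ff, cond))$studied
      ch$count_a + ch$count_b
    }), nipt_conditions)
  }

  decode_sub <- function(totals, n_loci, ff) {
    model <- models[[as.character(ff)]]
    n <- nrow(totals)
    obs <- numeric(n * n_loci)
    for (i in seq_len(n)) {
      idx <- if (n_loci == ncol(totals)) seq_len(ncol(totals))
             else sort(sample.int(ncol(totals), n_loci))
      obs[((i - 1L) * n_loci + 1L):(i * n_loci)] <- totals[i, idx]
    }
    path <- viterbi_gaussian_batch(matrix(obs, ncol = 1),
                                   as.integer(0:n * n_loci), model$mean,
                                   model$var, model$log_trans,
                                   model$log_init)
    path_m <- matrix(path, nrow = n_loci)
    freq <- cbind(EUP = colMeans(path_m == 1L), TRI = colMeans(path_m == 2L))
    dplyr::bind_cols(tibble::tibble(rd = rd, ff = ff),
                     freq_tibble(freq)) |>
      dplyr::mutate(mode_call = mode_call_matrix(freq, "RC"))
  }

  rows <- list()
  for (nl in n_loci_set) {
    tr_list <- list(); te_list <- list()
    set.seed(cell_seed(seed, 1000L + match(nl, n_loci_set), 3L))
    for (ff in ff_set) {
      tr_tot <- sim_totals(ff, n_train, 1L)
      te_tot <- sim_totals(ff, n_test, 2L)
      set.seed(cell_seed(seed, 2000L + match(nl, n_loci_set),
                         match(ff, ff_set)))
      for (cond in nipt_conditions) {
        truth <- rc_truth_label(cond)
        tr_list[[paste(ff, cond)]] <- decode_sub(tr_tot[[cond]], nl, ff) |>
          dplyr::mutate(truth = truth, condition = cond, ff_cell = ff)
        te_list[[paste(ff, cond)]] <- decode_sub(te_tot[[cond]], nl, ff) |>
          dplyr::mutate(truth = truth, condition = cond, ff_cell = ff)
      }
    }
    tr <- dplyr::bind_rows(tr_list); te <- dplyr::bind_rows(te_list)
    feat_cols <- c("rd", "ff", "freq_EUP", "freq_TRI")
    preds <- list(mode = te$mode_call)
    if ("tree" %in% methods) {
      preds$tree <- predict(fit_tree(tr[, feat_cols], tr$truth), te[, feat_cols])
    }
    if ("margin" %in% methods) {
      preds$margin <- predict(fit_margin(tr[, feat_cols], tr$truth),
                              te[, feat_cols])
    }
    for (meth in methods) {
      rows[[length(rows) + 1L]] <- te |>
        dplyr::mutate(.call = preds[[meth]]) |>
        dplyr::group_by(.data$ff_cell, .data$truth) |>
        dplyr::summarise(accuracy = mean(.data$.call == .data$truth),
                         n = dplyr::n(), .groups = "drop") |>
        dplyr::transmute(n_loci = nl, ff = .data$ff_cell, method = meth,
                         condition = .data$truth,
                         accuracy = .data$accuracy, n = .data$n)
    }
  }
  dplyr::bind_rows(rows)
}

#' Theoretical proportion of informative SNPs
#'
#' Exact enumeration over parental genotypes (Hardy-Weinberg at the given
#' minor-allele frequency, unrelated parents) and transmitted alleles of
#' the probability that a SNP is informative -- mother and/or fetus
#' heterozygous -- under each fetal condition. Under a meiosis-I trisomy
#' both alleles of the contributing parent are transmitted.
#'
#' @param maf Minor-allele frequency (vectorized).
#' @param condition Fetal condition.
#' @return Numeric vector of informative proportions.
#' @examples
#' informative_fraction_theory(0.5, "maternal_trisomy")  # 0.75
#' informative_fraction_theory(0.5, "paternal_trisomy")  # 0.875
#' @export
informative_fraction_theory <- function(maf, condition) {
  condition <- match_condition(condition)
  one <- function(m) {
    p <- c(A = 1 - m, B = m)
    al <- c("A", "B")
    total <- 0
    for (m1 in al) for (m2 in al) for (f1 in al) for (f2 in al) {
      pg <- p[[m1]] * p[[m2]] * p[[f1]] * p[[f2]]
      if (pg == 0) next
      fetuses <- switch(condition,
        euploidy = list(c(m1, f1), c(m1, f2), c(m2, f1), c(m2, f2)),
        maternal_trisomy = list(c(m1, m2, f1), c(m1, m2, f2)),
        paternal_trisomy = list(c(m1, f1, f2), c(m2, f1, f2)))
      p_inf <- mean(vapply(fetuses, function(fet) {
        m1 != m2 || length(unique(fet)) > 1
      }, logical(1)))
      total <- total + pg * p_inf
    }
    total
  }
  vapply(maf, one, numeric(1))
}

#' Simulated and theoretical informative-SNP proportions across MAF
#'
#' For each minor-allele frequency, simulates chromosomes of `n_variants`
#' biallelic SNPs for randomly paired parents, forms the fetal chromosome
#' set under each condition, and averages the fraction of informative
#' variants over `n_reps` replicates, alongside the closed-form value from
#' [informative_fraction_theory()].
#'
#' @param maf_set Minor-allele frequencies to evaluate.
#' @param n_variants Variants per simulated chromosome.
#' @param n_reps Replicates per MAF value.
#' @param conditions Fetal conditions to evaluate.
#' @param seed Root seed.
#' @return A tibble with columns `maf`, `condition`, `simulated`,
#'   `theoretical`, `n_reps`; class `nipt_maf_experiment`.
#' @export
maf_informative_experiment <- function(maf_set = c(0.01, 0.05, 0.10, 0.20,
                                                   0.30, 0.40, 0.50),
                                       n_variants = 1000, n_reps = 100,
                                       conditions = nipt_conditions,
                                       seed = 1) {
  rows <- list()
  for (mi in seq_along(maf_set)) {
    m <- maf_set[mi]
    for (cond in conditions) {
      set.seed(cell_seed(seed, mi, match(cond, nipt_conditions)))
      cfg <- sim_config(n_loci = n_variants, maf = max(m, 1e-9),
                        read_depth = 100, fetal_fraction = 0.1,
                        condition = cond)
      mh <- recombine_matrices(sim_hap_matrix(n_reps, n_variants, m),
                               sim_hap_matrix(n_reps, n_variants, m),
                               cfg$crossover)
      ph <- recombine_matrices(sim_hap_matrix(n_reps, n_variants, m),
                               sim_hap_matrix(n_reps, n_variants, m),
                               cfg$crossover)
      d_m <- mh[[1]] + mh[[2]]
      d_f <- fetal_dosage(mh, ph, cond)
      ploidy <- if (cond == "euploidy") 2L else 3L
      fhet <- d_f >= 1L & d_f <= ploidy - 1L
      inf_frac <- rowMeans(d_m == 1L | fhet)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        maf = m, condition = cond, simulated = mean(inf_frac),
        theoretical = informative_fraction_theory(m, cond),
        n_reps = n_reps)
    }
  }
  structure(dplyr::bind_rows(rows),
            class = c("nipt_maf_experiment", "tbl_df", "tbl", "data.frame"))
}
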