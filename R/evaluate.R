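#' Classification accuracy
#'
#' Fraction of calls equal to the truth. `"unclassified"` calls never match
#' and therefore count as incorrect.
#'
#' @param calls,truths Equal-length character vectors.
#' @return A single accuracy in `[0, 1]`.
#' @examples
#' accuracy(c("euploidy", "trisomy", "unclassified"),
#'          c("euploidy", "trisomy", "trisomy"))
#' @export
accuracy <- function(calls, truths) {
  if (length(calls) == 0) {
    abort("empty input.", class = "niptsim_evaluate_error")
  }
  if (length(calls) != length(truths)) {
    abort("`calls` and `truths` must have equal length.",
          class = "niptsim_evaluate_error")
  }
  mean(calls == truths)
}

#' Fetal-fraction band of the accuracy tables
#'
#' @param ff Fetal fractions (proportions).
#' @return Ordered factor with levels `1-5%`, `6-10%`, `11-15%`, `16-20%`.
#' @export
ff_band <- function(ff) {
  cut(round(ff * 100), breaks = c(0.5, 5.5, 10.5, 15.5, 20.5),
      labels = c("1-5%", "6-10%", "11-15%", "16-20%"), ordered_result = TRUE)
}

reg_key <- function(rd, ff) sprintf("%g|%.4f", rd, ff)

# Training observations for one (rd, ff) pair: fit RC / AR / RCAR emission
# models from ground-truth-labelled loci of all three conditions.
fit_pair_models <- function(cells, rd, ff, stay_switch_ratio) {
  rc_obs <- list(); rc_lab <- list()
  ar_obs <- list(); ar_lab <- list(); ar_tot <- list()
  for (cond in nipt_conditions) {
    ch <- cells[[cond]]$studied
    tot <- ch$count_a + ch$count_b
    rc_obs[[cond]] <- as.numeric(tot)
    rc_lab[[cond]] <- rep(if (cond == "euploidy") 1L else 2L, length(tot))
    lab <- state_label_matrix(ch$d_m, ch$d_f, ch$ploidy, cond)
    keep <- !is.na(lab)
    mx <- pmax(ch$count_a, ch$count_b)
    mn <- pmin(ch$count_a, ch$count_b)
    ratio <- ifelse(mn > 0, mx / mn, Inf)
    ar_obs[[cond]] <- ratio[keep]
    ar_tot[[cond]] <- tot[keep]
    ar_lab[[cond]] <- lab[keep]
  }
  n_train <- nrow(cells$euploidy$studied$count_a)
  list(
    rc = fit_hmm_moments(unlist(rc_lab), matrix(unlist(rc_obs),
                         dimnames = list(NULL, "total")),
                         "RC", stay_switch_ratio, rd, ff, n_train),
    ar = fit_hmm_moments(unlist(ar_lab), matrix(unlist(ar_obs),
                         dimnames = list(NULL, "ratio")),
                         "AR", stay_switch_ratio, rd, ff, n_train),
    rcar = fit_hmm_moments(unlist(ar_lab),
                           cbind(total = unlist(ar_tot),
                                 ratio = unlist(ar_obs)),
                           "RCAR", stay_switch_ratio, rd, ff, n_train)
  )
}

# Decode every sample of a read-count matrix (one sample per row) with one
# RC model, batched through the C++ kernel.
decode_rc_cell <- function(totals, model) {
  n <- nrow(totals); L <- ncol(totals)
  obs <- matrix(as.numeric(t(totals)), ncol = 1)
  path <- viterbi_gaussian_batch(obs, as.integer(0:n * L), model$mean,
                                 model$var, model$log_trans, model$log_init)
  path_m <- matrix(path, nrow = L)
  freq <- vapply(1:2, function(k) colMeans(path_m == k), numeric(n))
  if (!is.matrix(freq)) freq <- matrix(freq, nrow = 1)
  colnames(freq) <- model$states$state
  freq
}

# Decode informative loci of each sample with a (possibly sample-specific)
# 7-state model; kind is "AR" or "RCAR". Samples sharing a model are
# decoded in one batched call.
decode_7_cell <- function(chrom, models, kind) {
  n <- nrow(chrom$count_a)
  lab <- state_label_matrix(chrom$d_m, chrom$d_f, chrom$ploidy,
                            chrom$condition)
  informative <- t(!is.na(lab))                    # loci x samples
  mx <- t(pmax(chrom$count_a, chrom$count_b))
  mn <- t(pmin(chrom$count_a, chrom$count_b))
  ratio <- mx / mn
  ratio[mn == 0] <- Inf
  total <- mx + mn
  keep <- which(informative)                       # sample-major order
  len <- colSums(informative)
  if (any(len == 0)) {
    abort("a sample has no informative loci to decode.",
          class = "niptsim_hmm_error")
  }
  offsets <- c(0L, cumsum(len))
  obs_ratio <- ratio[keep]
  obs_total <- total[keep]
  if (inherits(models, "nipt_hmm")) models <- rep(list(models), n)
  model_ff <- vapply(models, function(m) m$ff, numeric(1))
  freq <- matrix(0, n, 7, dimnames = list(NULL, hmm_states("AR")$state))
  for (f in unique(model_ff)) {
    idx <- which(model_ff == f)
    m <- models[[idx[1]]]
    rows <- unlist(lapply(idx, function(i) {
      seq.int(offsets[i] + 1L, offsets[i + 1L])
    }))
    r <- pmin(obs_ratio[rows], m$ratio_cap)
    obs <- if (kind == "AR") matrix(r, ncol = 1)
           else cbind(obs_total[rows], r)
    path <- viterbi_gaussian_batch(obs,
                                   as.integer(c(0, cumsum(len[idx]))),
                                   m$mean, m$var, m$log_trans, m$log_init)
    pos <- 0L
    for (i in idx) {
      sl <- path[(pos + 1L):(pos + len[i])]
      freq[i, ] <- tabulate(sl, 7L) / len[i]
      pos <- pos + len[i]
    }
  }
  freq
}

# Truth-mode informative mask of a simulated chromosome.
informative_matrix <- function(chrom) {
  fhet <- chrom$d_f >= 1L & chrom$d_f <= chrom$ploidy - 1L
  chrom$d_m == 1L | fhet
}

freq_tibble <- function(freq) {
  colnames(freq) <- paste0("freq_", colnames(freq))
  tibble::as_tibble(freq)
}

# Decode one simulated cell (all samples of one condition at one grid
# point) under every requested model configuration; returns per-sample
# feature rows, modal calls and truth labels.
process_cell <- function(cells, cond, rd, ff_true, registry, ff_grid,
                         models, fixed_ff) {
  ch <- cells[[cond]]$studied
  ref <- cells[[cond]]$reference
  n <- nrow(ch$count_a)
  totals <- ch$count_a + ch$count_b
  out <- list()

  ff_hat <- NULL
  if (any(c("ar", "rcar") %in% models)) {
    ff_hat <- estimate_ff_matrix(ref$count_a, ref$count_b,
                                 informative_matrix(ref))
    ff_used <- ifelse(is.na(ff_hat), fixed_ff, ff_hat)
    ff_near <- ff_grid[pmax(1, pmin(length(ff_grid),
      vapply(ff_used, function(f) which.min(abs(ff_grid - f)), integer(1))))]
  }

  for (mk in models) {
    if (mk %in% c("rc_perfect", "rc_fixed")) {
      train_ff <- if (mk == "rc_perfect") ff_true else fixed_ff
      model <- registry$rc[[reg_key(rd, train_ff)]]
      freq <- decode_rc_cell(totals, model)
      feats <- dplyr::bind_cols(tibble::tibble(rd = rd, ff = ff_true),
                                freq_tibble(freq))
      calls <- mode_call_matrix(freq, "RC")
      truth <- rep(rc_truth_label(cond), n)
    } else {
      kind <- toupper(mk)
      sample_models <- lapply(ff_near, function(f) {
        registry[[mk]][[reg_key(rd, f)]]
      })
      freq <- decode_7_cell(ch, sample_models, kind)
      feats <- dplyr::bind_cols(tibble::tibble(rd = rd, ff = ff_used),
                                freq_tibble(freq))
      calls <- mode_call_matrix(freq, kind)
      truth <- rep(cond, n)
    }
    out[[mk]] <- tibble::tibble(
      model = mk, condition = cond, ff_cell = ff_true, rd_cell = rd,
      truth = truth, mode_call = calls) |>
      dplyr::bind_cols(feats)
  }
  out
}

#' Run the simulated accuracy grid
#'
#' Simulates the full experimental grid (three fetal conditions crossed
#' with fetal-fraction and read-depth grids), trains the HMM emission
#' registry from `n_train` samples per cell, Viterbi-decodes `n_test` test
#' samples per cell, and scores chromosome-level calls by the modal decoded
#' condition and by decision-tree and kernel-margin classifiers fitted on
#' the pooled training-state frequencies. Four model configurations are
#' available: `rc_perfect` (RC model with emissions matched to each cell's
#' true fetal fraction), `rc_fixed` (RC emissions fixed at
#' `fixed_ff`, the expected population median), `ar` and `rcar` (7-state
#' models decoded with emissions selected by each sample's estimated fetal
#' fraction).
#'
#' @param seed Root seed; per-cell seeds are derived deterministically.
#' @param ff_grid,rd_grid Fetal-fraction and read-depth grids. The default
#'   read-depth set subsamples the full 500--15,000 range at uniform
#'   spacing so that averages over the grid estimate the full uniform-grid
#'   average without bias.
#' @param n_loci Targeted loci per chromosome.
#' @param maf Minor-allele frequency of the targets.
#' @param n_train,n_test Training / test samples per grid cell and
#'   condition.
#' @param models Model configurations to evaluate (subset of
#'   `c("rc_perfect", "rc_fixed", "ar", "rcar")`).
#' @param methods Chromosome-level methods (subset of
#'   `c("mode", "tree", "margin")`).
#' @param fixed_ff Assumed fetal fraction of the fixed-FF RC configuration.
#' @param vmr Variance-to-mean ratio of the count noise.
#' @param stay_switch_ratio HMM transition stay-switch weight.
#' @param meta_train_per_cell Optional cap on training profiles per cell
#'   used to fit the tree/margin classifiers (all by default).
#' @param crossover Recombination mode (see [sim_config()]).
#' @param progress Print per-gridpoint progress.
#' @return An object of class `nipt_accuracy_report` with elements `cells`
#'   (per model, method, condition, ff, rd), `bands` (fetal-fraction band
#'   aggregates), `overall` (grand means per model and method) and `meta`.
#' @examples
#' \donttest{
#' rep1 <- run_grid(seed = 1, ff_grid = c(0.05, 0.15), rd_grid = 1000,
#'                  n_loci = 200, n_train = 30, n_test = 20,
#'                  models = "rc_fixed")
#' rep1$overall
#' }
#' @export
run_grid <- function(seed = 1,
                     ff_grid = seq(0.01, 0.20, by = 0.01),
                     rd_grid = c(500, 3400, 6300, 9200, 12100, 15000),
                     n_loci = 1000, maf = 0.5, n_train = 100, n_test = 200,
                     models = c("rc_perfect", "rc_fixed", "ar", "rcar"),
                     methods = c("mode", "tree", "margin"),
                     fixed_ff = 0.10, vmr = 3, stay_switch_ratio = 10,
                     meta_train_per_cell = NULL, crossover = "suffix",
                     progress = FALSE) {
  models <- match.arg(models, several.ok = TRUE)
  methods <- match.arg(methods, several.ok = TRUE)
  train_ffs <- sort(unique(c(ff_grid,
    if (any(c("rc_fixed", "ar", "rcar") %in% models)) fixed_ff)))
  pairs <- expand.grid(ff = train_ffs, rd = rd_grid,
                       KEEP.OUT.ATTRS = FALSE)

  cfg <- function(rd, ff, condition) {
    sim_config(n_loci = n_loci, maf = maf, read_depth = rd,
               fetal_fraction = ff, condition = condition, vmr = vmr,
               n_train = n_train, n_test = n_test, crossover = crossover)
  }
  sim_conditions <- function(rd, ff, n) {
    setNames(lapply(nipt_conditions, function(cond) {
      sim_cell(n, cfg(rd, ff, cond))
    }), nipt_conditions)
  }

  # Pass A: train the emission registry on every (rd, ff) pair.
  registry <- list(rc = list(), ar = list(), rcar = list())
  for (p in seq_len(nrow(pairs))) {
    rd <- pairs$rd[p]; ff <- pairs$ff[p]
    set.seed(cell_seed(seed, p, 1L))
    fits <- fit_pair_models(sim_conditions(rd, ff, n_train), rd, ff,
                            stay_switch_ratio)
    key <- reg_key(rd, ff)
    registry$rc[[key]] <- fits$rc
    registry$ar[[key]] <- fits$ar
    registry$rcar[[key]] <- fits$rcar
    if (progress) message(sprintf("trained rd=%g ff=%.2f", rd, ff))
  }

  # Pass B: regenerate the training samples (same seeds), simulate test
  # samples, decode both under every model configuration.
  train_rows <- list(); test_rows <- list()
  eval_pairs <- which(pairs$ff %in% ff_grid)
  for (p in eval_pairs) {
    rd <- pairs$rd[p]; ff <- pairs$ff[p]
    set.seed(cell_seed(seed, p, 1L))
    train_cells <- sim_conditions(rd, ff, n_train)
    set.seed(cell_seed(seed, p, 2L))
    test_cells <- sim_conditions(rd, ff, n_test)
    for (cond in nipt_conditions) {
      train_rows[[length(train_rows) + 1L]] <- dplyr::bind_rows(
        process_cell(train_cells, cond, rd, ff, registry, train_ffs,
                     models, fixed_ff))
      test_rows[[length(test_rows) + 1L]] <- dplyr::bind_rows(
        process_cell(test_cells, cond, rd, ff, registry, train_ffs,
                     models, fixed_ff))
    }
    if (progress) message(sprintf("decoded rd=%g ff=%.2f", rd, ff))
  }
  train_df <- dplyr::bind_rows(train_rows)
  test_df <- dplyr::bind_rows(test_rows)

  score_report(train_df, test_df, models, methods,
               meta_train_per_cell = meta_train_per_cell,
               meta = list(seed = seed, ff_grid = ff_grid,
                           rd_grid = rd_grid, n_loci = n_loci, maf = maf,
                           n_train = n_train, n_test = n_test,
                           fixed_ff = fixed_ff, vmr = vmr,
                           stay_switch_ratio = stay_switch_ratio))
}

# Fit the supplemental classifiers on pooled training profiles, score every
# method per grid cell and assemble the report object.
score_report <- function(train_df, test_df, models, methods,
                         meta_train_per_cell = NULL, meta = list(),
                         seed_ml = 123) {
  cell_rows <- list()
  for (mk in models) {
    tr <- dplyr::filter(train_df, .data$model == mk)
    te <- dplyr::filter(test_df, .data$model == mk)
    feat_cols <- c("rd", "ff", grep("^freq_", names(te), value = TRUE))
    feat_cols <- feat_cols[vapply(feat_cols, function(cl) {
      !all(is.na(te[[cl]]))
    }, logical(1))]
    preds <- list(mode = te$mode_call)
    if (any(c("tree", "margin") %in% methods)) {
      if (!is.null(meta_train_per_cell)) {
        tr <- tr |>
          dplyr::group_by(.data$condition, .data$ff_cell, .data$rd_cell) |>
          dplyr::slice_head(n = meta_train_per_cell) |>
          dplyr::ungroup()
      }
      x_tr <- tr[, feat_cols]; x_te <- te[, feat_cols]
      if ("tree" %in% methods) {
        fit <- fit_tree(x_tr, tr$truth, seed = seed_ml)
        preds$tree <- predict(fit, x_te)
      }
      if ("margin" %in% methods) {
        fit <- fit_margin(x_tr, tr$truth, seed = seed_ml)
        preds$margin <- predict(fit, x_te)
      }
    }
    for (meth in methods) {
      sc <- te |>
        dplyr::mutate(.call = preds[[meth]]) |>
        dplyr::group_by(.data$condition, .data$ff_cell, .data$rd_cell) |>
        dplyr::summarise(accuracy = mean(.data$.call == .data$truth),
                         n = dplyr::n(), .groups = "drop") |>
        dplyr::transmute(model = mk, method = meth,
                         condition = .data$condition, ff = .data$ff_cell,
                         rd = .data$rd_cell, accuracy = .data$accuracy,
                         n = .data$n)
      cell_rows[[length(cell_rows) + 1L]] <- sc
    }
  }
  cells <- dplyr::bind_rows(cell_rows)
  bands <- cells |>
    dplyr::mutate(band = ff_band(.data$ff)) |>
    dplyr::group_by(.data$model, .data$method, .data$band) |>
    dplyr::summarise(accuracy = mean(.data$accuracy),
                     n = sum(.data$n), .groups = "drop")
  overall <- cells |>
    dplyr::group_by(.data$model, .data$method) |>
    dplyr::summarise(accuracy = mean(.data$accuracy),
                     n = sum(.data$n), .groups = "drop")
  structure(list(cells = cells, bands = bands, overall = overall,
                 meta = meta),
            class = "nipt_accuracy_report")
}

#' @export
print.nipt_accuracy_report <- function(x, ...) {
  cat("<nipt_accuracy_report>\n")
  cat(sprintf("  %d grid cells (%d models x %d methods)\n",
              nrow(x$cells),
              length(unique(x$cells$model)),
              length(unique(x$cells$method))))
  wide <- tidyr::pivot_wider(x$bands, names_from = "method",
                             values_from = "accuracy", id_cols = c("model", "band"))
  print(as.data.frame(wide), digits = 3)
  cat("overall:\n")
  print(as.data.frame(tidyr::pivot_wider(
    x$overall, names_from = "method", values_from = "accuracy",
    id_cols = "model")), digits = 3)
  invisible(x)
}

#' @rdname run_grid
#' @param x A `nipt_accuracy_report`.
#' @param ... Unused.
#' @export
tidy.nipt_accuracy_report <- function(x, ...) x$cells

#' @rdname run_grid
#' @export
glance.nipt_accuracy_report <- function(x, ...) {
  tidyr::pivot_wider(x$overall, names_from = "method",
                     values_from = "accuracy", id_cols = "model")
}

#' Serialize / restore an accuracy report
#'
#' Round-trips losslessly through a JSON file.
#'
#' @param report A `nipt_accuracy_report`.
#' @param path Destination / source path.
#' @return `write_report()` returns `path` invisibly; `read_report()` the
#'   restored report.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(list(cells = report$cells, bands = report$bands,
                            overall = report$overall, meta = report$meta),
                       path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$cells <- tibble::as_tibble(raw$cells)
  raw$bands <- tibble::as_tibble(raw$bands) |>
    dplyr::mutate(band = factor(.data$band,
                                levels = levels(ff_band(0.01)),
                                ordered = TRUE))
  raw$overall <- tibble::as_tibble(raw$overall)
  structure(raw, class = "nipt_accuracy_report")
}
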