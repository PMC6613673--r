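#' Read a targeted molecule-count table
#'
#' Tab-separated table of UMI-collapsed molecule counts per targeted locus,
#' with header columns `sample_id`, `chromosome_id`, `locus_id`,
#' `position`, `molecule_count`. Gzip-compressed files are read
#' transparently. Counts must be non-negative integers and
#' (sample, chromosome, locus) keys unique; violations raise classed
#' errors naming the offending rows.
#'
#' @param path TSV path.
#' @param roles Optional named character vector mapping `chromosome_id`
#'   values to `"reference"` or `"studied"`; when given, a `role` column is
#'   attached.
#' @return A validated tibble.
#' @export
read_count_table <- function(path, roles = NULL) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("sample_id", "chromosome_id", "locus_id", "position",
            "molecule_count")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    abort(paste0("missing columns: ", paste(missing, collapse = ", ")),
          class = "niptsim_io_missing_column")
  }
  bad <- which(is.na(raw$molecule_count) | raw$molecule_count < 0 |
                 raw$molecule_count != round(raw$molecule_count))
  if (length(bad) > 0) {
    abort(paste0("invalid molecule_count in row(s): ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "niptsim_io_negative_count")
  }
  key <- paste(raw$sample_id, raw$chromosome_id, raw$locus_id)
  if (anyDuplicated(key)) {
    abort(paste0("duplicate (sample, chromosome, locus) key(s): ",
                 paste(head(unique(key[duplicated(key)]), 3),
                       collapse = "; ")),
          class = "niptsim_io_duplicate_key")
  }
  out <- tibble::as_tibble(raw[need])
  out$molecule_count <- as.integer(out$molecule_count)
  if (!is.null(roles)) {
    unknown <- setdiff(unique(out$chromosome_id), names(roles))
    if (length(unknown) > 0) {
      abort(paste0("chromosomes without a declared role: ",
                   paste(unknown, collapse = ", ")),
            class = "niptsim_io_error")
    }
    out$role <- unname(roles[out$chromosome_id])
  }
  out
}

#' @rdname read_count_table
#' @param table A count table tibble.
#' @export
write_count_table <- function(table, path) {
  cols <- c("sample_id", "chromosome_id", "locus_id", "position",
            "molecule_count")
  readr::write_tsv(table[cols], path)
  invisible(path)
}

#' Interquartile-range locus filtering
#'
#' Flags outlier target loci per (sample, chromosome) by Tukey fences:
#' loci are retained when their count lies within
#' `[Q1 - k * IQR, Q3 + k * IQR]`, quartiles by linear interpolation.
#' Groups with fewer than 4 loci are retained whole with a warning.
#' Filtering is idempotent: re-filtering the retained loci removes
#' nothing.
#'
#' @param table Count table with a `molecule_count` column; grouped per
#'   `sample_id` and `chromosome_id` when those columns are present.
#' @param k Fence multiplier (default 1.5; the conventional Tukey value).
#' @return `table` with a logical `retained` column added.
#' @export
iqr_filter <- function(table, k = 1.5) {
  group_cols <- intersect(c("sample_id", "chromosome_id"), names(table))
  flag <- function(x) {
    if (length(x) < 4) {
      warn("fewer than 4 loci in a group; no IQR filtering applied.",
           class = "niptsim_iqr_warning")
      return(rep(TRUE, length(x)))
    }
    q <- quantile(x, c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    x >= q[1] - k * iqr & x <= q[2] + k * iqr
  }
  groups <- if (length(group_cols) == 0) {
    list(seq_len(nrow(table)))
  } else {
    unname(split(seq_len(nrow(table)),
                 interaction(table[group_cols], drop = TRUE)))
  }
  retained <- logical(nrow(table))
  for (idx in groups) {
    retained[idx] <- flag(table$molecule_count[idx])
  }
  dplyr::mutate(table, retained = retained)
}

#' Read-count pipeline for an experimental targeted sample
#'
#' Applies the read-count HMM to a real (or fixture) molecule-count table
#' of one sample: loci are IQR-filtered per chromosome, the euploid
#' emission mean is anchored to the mean retained count over the reference
#' chromosomes, the trisomy mean to `euploid mean * (1 + assumed_ff / 2)`,
#' and variances to `vmr` times the means. The studied-chromosome loci are
#' then Viterbi-decoded in positional order and the chromosome is called
#' by the modal decoded condition.
#'
#' @param table Count table of a single sample with a `role` column (see
#'   [read_count_table()]).
#' @param assumed_ff Assumed fetal fraction (default 0.10, the expected
#'   population median).
#' @param vmr Variance-to-mean ratio anchoring the emission variances.
#' @param stay_switch_ratio HMM transition stay-switch weight.
#' @param apply_iqr Run [iqr_filter()] first (default); set `FALSE` if the
#'   table is already filtered.
#' @param k IQR fence multiplier.
#' @return An object of class `nipt_experimental_call`: list with `loci`
#'   (per-locus decoded states of the studied chromosome), `call` (one-row
#'   tibble with the chromosome-level call and state proportions) and the
#'   anchored `model`.
#' @export
call_experimental_sample <- function(table, assumed_ff = 0.10, vmr = 3,
                                     stay_switch_ratio = 10,
                                     apply_iqr = TRUE, k = 1.5) {
  if (!"role" %in% names(table)) {
    abort("`table` needs a `role` column (reference/studied).",
          class = "niptsim_io_error")
  }
  if (length(unique(table$sample_id)) != 1) {
    abort("`table` must contain exactly one sample.",
          class = "niptsim_io_error")
  }
  if (apply_iqr) {
    table <- iqr_filter(table, k = k)
  } else if (!"retained" %in% names(table)) {
    table$retained <- TRUE
  }
  kept <- dplyr::filter(table, .data$retained)
  ref <- dplyr::filter(kept, .data$role == "reference")
  stu <- dplyr::filter(kept, .data$role == "studied")
  if (nrow(ref) == 0) {
    abort("no reference loci after filtering.", class = "niptsim_io_error")
  }
  if (nrow(stu) == 0) {
    abort("no studied loci after filtering.", class = "niptsim_io_error")
  }
  mu_eup <- mean(ref$molecule_count)
  mu_tri <- mu_eup * (1 + assumed_ff / 2)
  model <- new_nipt_hmm("RC",
                        mean = matrix(c(mu_eup, mu_tri), 2, 1,
                                      dimnames = list(c("EUP", "TRI"),
                                                      "total")),
                        var = matrix(vmr * c(mu_eup, mu_tri), 2, 1,
                                     dimnames = list(c("EUP", "TRI"),
                                                     "total")),
                        stay_switch_ratio, NA_real_,
                        ff = assumed_ff)
  stu <- dplyr::arrange(stu, .data$position)
  path <- viterbi_path(matrix(stu$molecule_count, ncol = 1), model)
  loci <- dplyr::mutate(stu, state = model$states$state[path])
  freq <- tabulate(path, 2L) / length(path)
  names(freq) <- model$states$state
  call <- mode_call(setNames(freq, paste0("freq_", names(freq))),
                    kind = "RC")
  call <- dplyr::mutate(call, sample_id = table$sample_id[1],
                        assumed_ff = assumed_ff,
                        n_loci = nrow(stu), .before = 1)
  structure(list(loci = loci, call = call, model = model),
            class = "nipt_experimental_call")
}

#' @export
print.nipt_experimental_call <- function(x, ...) {
  cat(sprintf("<nipt_experimental_call: %s -> %s (%.0f%% TRI over %d loci)>\n",
              x$call$sample_id, x$call$call, 100 * x$call$mass_trisomy,
              x$call$n_loci))
  invisible(x)
}

#' @rdname call_experimental_sample
#' @param x A `nipt_experimental_call`.
#' @param ... Unused.
#' @export
tidy.nipt_experimental_call <- function(x, ...) x$loci

#' @rdname call_experimental_sample
#' @export
glance.nipt_experimental_call <- function(x, ...) x$call
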