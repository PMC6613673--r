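# Shared small fixtures, built in code at test time.

# A mixed-condition training cohort (studied chromosomes only) at one
# (read depth, fetal fraction) point; cached per session.
training_cohort <- local({
  cache <- NULL
  function(n = 20, n_loci = 500, rd = 1000, ff = 0.10) {
    if (!is.null(cache)) return(cache)
    sets <- lapply(seq_along(c("euploidy", "maternal_trisomy",
                               "paternal_trisomy")), function(i) {
      cond <- c("euploidy", "maternal_trisomy", "paternal_trisomy")[i]
      simulate_cohort(sim_config(n_loci = n_loci, read_depth = rd,
                                 fetal_fraction = ff, condition = cond,
                                 seed = 100 + i), n = n,
                      id_prefix = paste0(substr(cond, 1, 3), "_"))
    })
    cache <<- dplyr::filter(dplyr::bind_rows(sets), role == "studied")
    cache
  }
})

# A small molecule-count table fixture: `n_ref`/`n_stu` loci around a mean
# count, optionally with planted outliers and a studied-chromosome shift.
make_count_table <- function(sample_id = "mix0", mean_count = 500,
                             n_ref = 80, n_stu = 80, studied_factor = 1,
                             n_outliers = 0, seed = 1) {
  set.seed(seed)
  ref <- tibble::tibble(
    sample_id = sample_id, chromosome_id = "chr2",
    locus_id = sprintf("r%03d", seq_len(n_ref)),
    position = seq_len(n_ref) * 1000,
    molecule_count = rnbinom(n_ref, mu = mean_count,
                             size = mean_count / 2))
  stu <- tibble::tibble(
    sample_id = sample_id, chromosome_id = "chr21",
    locus_id = sprintf("s%03d", seq_len(n_stu)),
    position = seq_len(n_stu) * 1000,
    molecule_count = rnbinom(n_stu, mu = mean_count * studied_factor,
                             size = mean_count * studied_factor / 2))
  if (n_outliers > 0) {
    idx <- seq_len(n_outliers)
    stu$molecule_count[idx] <- round(mean_count * 10 * seq_len(n_outliers))
  }
  out <- dplyr::bind_rows(ref, stu)
  out$molecule_count <- as.integer(out$molecule_count)
  out$role <- ifelse(out$chromosome_id == "chr2", "reference", "studied")
  out
}
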