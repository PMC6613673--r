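test_that("informative-SNP rule follows maternal/fetal heterozygosity", {
  obs <- tibble::tibble(
    locus = 1:4,
    count_a = c(50L, 50L, 50L, 50L), count_b = c(0L, 50L, 10L, 0L),
    maternal_genotype = c("AA", "AB", "AA", "AA"),
    fetal_genotype = c("AA", "AAB", "AB", "AAA"))
  out <- informative_loci(obs, "truth")
  expect_identical(out$informative, c(FALSE, TRUE, TRUE, FALSE))

  # observed mode: minor-count floor max(2, 0.005 * total)
  out2 <- informative_loci(obs[, c("locus", "count_a", "count_b")],
                           "observed")
  expect_identical(out2$informative, c(FALSE, TRUE, TRUE, FALSE))

  expect_error(informative_loci(obs[, 1:3], "truth"),
               class = "niptsim_feature_error")
})

test_that("allelic ratios are major-over-minor with an infinite sentinel", {
  obs <- tibble::tibble(
    locus = 1:3, count_a = c(50L, 20L, 30L), count_b = c(50L, 80L, 0L),
    maternal_genotype = c("AB", "AB", "AB"),
    fetal_genotype = c("AB", "AB", "AB"))
  ars <- allelic_ratios(obs)
  expect_equal(ars$ratio, c(1, 4, Inf))
  expect_true(all(ars$ratio >= 1))
  expect_equal(ars$minor_fraction, c(1, 2 * 20 / 100, 0))

  # empty mask is an empty series, not an error
  none <- dplyr::mutate(obs, informative = FALSE)
  expect_identical(nrow(allelic_ratios(none)), 0L)
})

test_that("noise-free allelic ratios match dosage enumeration", {
  # mother AA / fetus AB at FF = 0.10: expected ratio (2 - FF) / FF = 19
  mu <- oracle_expected_counts("AA", "AB", 1000, 0.10)
  obs <- tibble::tibble(locus = 1L, count_a = mu[["a"]],
                        count_b = mu[["b"]],
                        maternal_genotype = "AA", fetal_genotype = "AB")
  expect_equal(allelic_ratios(obs)$ratio, 19)
  expect_equal(unname(mu[["a"]] / mu[["b"]]), 19)
})

test_that("fetal-fraction formula and filters behave on constructed loci", {
  base <- function(a, b, mg, fg) {
    tibble::tibble(locus = seq_along(a), count_a = a, count_b = b,
                   maternal_genotype = mg, fetal_genotype = fg)
  }
  # single selected locus: FF = 2 * 10 / 100
  one <- base(90L, 10L, "AA", "AB")
  est <- estimate_ff(one)
  expect_equal(est$ff_hat, 0.2)
  expect_identical(est$n_loci_used, 1L)

  # all selected loci with zero minor count: FF = 0 (infinite ratios pass)
  zeros <- base(c(100L, 80L), c(0L, 0L), rep("AA", 2), rep("AB", 2))
  expect_equal(estimate_ff(zeros)$ff_hat, 0)

  # mother-heterozygous loci (ratio ~ 1) are excluded by the AR > 2.5 filter
  mixed <- base(c(90L, 50L), c(10L, 50L), c("AA", "AB"), c("AB", "AB"))
  est2 <- estimate_ff(mixed)
  expect_identical(est2$n_loci_used, 1L)
  expect_equal(est2$ff_hat, 0.2)

  # no locus passing -> flagged, not an error
  est3 <- estimate_ff(base(50L, 50L, "AB", "AB"))
  expect_identical(est3$status, "no_loci")
  expect_true(is.na(est3$ff_hat))

  expect_error(estimate_ff(one[0, ]), class = "niptsim_feature_error")
})

test_that("fetal-fraction estimate is invariant to locus order and label swaps", {
  s <- simulate_sample(sim_config(read_depth = 2000, fetal_fraction = 0.10,
                                  seed = 55))
  ref <- dplyr::filter(s, role == "reference")
  est <- estimate_ff(ref)

  shuffled <- ref[sample.int(nrow(ref)), ]
  expect_equal(estimate_ff(shuffled)$ff_hat, est$ff_hat)

  swap_gt <- function(g) chartr("AB", "BA", g)
  flipped <- dplyr::mutate(ref,
    tmp = count_a, count_a = count_b, count_b = tmp,
    maternal_genotype = swap_gt(maternal_genotype),
    fetal_genotype = swap_gt(fetal_genotype))
  expect_equal(estimate_ff(flipped)$ff_hat, est$ff_hat)
})

test_that("noise-free counts at exact dosage means recover FF exactly", {
  ff <- 0.07
  gts <- list(c("AA", "AB"), c("AB", "AB"), c("AA", "AA"), c("BB", "AB"))
  rows <- lapply(gts, function(g) {
    mu <- oracle_expected_counts(g[1], g[2], 5000, ff)
    tibble::tibble(count_a = mu[["a"]], count_b = mu[["b"]],
                   maternal_genotype = g[1], fetal_genotype = g[2])
  })
  obs <- dplyr::bind_rows(rows)
  obs$locus <- seq_len(nrow(obs))
  expect_equal(estimate_ff(obs)$ff_hat, ff)
})

test_that("FF estimation error shrinks with read depth and is small at RD 5000", {
  err_at <- function(rd, n = 30) {
    cfg <- sim_config(read_depth = rd, fetal_fraction = 0.10, seed = rd)
    samples <- simulate_cohort(cfg, n = n)
    est <- samples |>
      dplyr::filter(role == "reference") |>
      dplyr::group_split(sample_id) |>
      purrr::map_dbl(~ estimate_ff(.x)$ff_hat)
    mean(abs(est - 0.10))
  }
  e <- vapply(c(500, 2000, 10000), err_at, numeric(1))
  expect_lt(e[2], e[1])
  expect_lt(e[3], e[2])
  expect_lt(err_at(5000), 0.02)
})
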