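test_that("accuracy counts unclassified as incorrect", {
  expect_equal(accuracy(c("a", "b"), c("a", "b")), 1)
  expect_equal(accuracy(rep("unclassified", 3), rep("trisomy", 3)), 0)
  expect_equal(accuracy(c("a", "a", "a", "b"), c("a", "a", "a", "a")), 0.75)
  expect_error(accuracy(character(0), character(0)),
               class = "niptsim_evaluate_error")
  expect_error(accuracy("a", c("a", "b")), class = "niptsim_evaluate_error")
})

test_that("fetal-fraction bands follow the reporting convention", {
  expect_equal(as.character(ff_band(c(0.01, 0.05, 0.06, 0.10, 0.11, 0.20))),
               c("1-5%", "1-5%", "6-10%", "6-10%", "11-15%", "16-20%"))
})

test_that("a degenerate one-cell grid reduces to a single accuracy value", {
  rep1 <- run_grid(seed = 4, ff_grid = 0.15, rd_grid = 2000, n_loci = 300,
                   n_train = 25, n_test = 12, models = "rc_perfect",
                   methods = "mode")
  expect_identical(nrow(rep1$overall), 1L)
  cells <- rep1$cells
  expect_identical(nrow(cells), 3L)  # one per condition
  expect_true(all(cells$n == 12))
  expect_equal(rep1$overall$accuracy, mean(cells$accuracy))
  # high-FF read-count decoding with matched emissions is essentially exact
  expect_gte(rep1$overall$accuracy, 0.95)
})

test_that("grid runs are reproducible and reports round-trip", {
  args <- list(seed = 9, ff_grid = c(0.04, 0.12), rd_grid = 1000,
               n_loci = 200, n_train = 20, n_test = 10,
               models = "rc_fixed", methods = c("mode", "tree"))
  r1 <- do.call(run_grid, args)
  r2 <- do.call(run_grid, args)
  expect_identical(r1$cells, r2$cells)

  path <- withr::local_tempfile(fileext = ".json")
  write_report(r1, path)
  r3 <- read_report(path)
  expect_equal(as.data.frame(r3$cells), as.data.frame(r1$cells))
  expect_equal(as.data.frame(r3$bands), as.data.frame(r1$bands))
  expect_equal(as.data.frame(r3$overall), as.data.frame(r1$overall))
})

test_that("locus subsampling at full size matches direct decoding trends", {
  res <- loci_subsample_experiment(seed = 2, n_loci_set = c(50, 1000),
                                   rd = 1000, ff_set = 0.10,
                                   n_loci_full = 1000, n_train = 40,
                                   n_test = 30, methods = c("mode", "tree"))
  expect_setequal(unique(res$condition), c("euploidy", "trisomy"))
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 1))
  # at FF 10% / RD 1000 the RC model is strong even with 50 loci
  best50 <- res |>
    dplyr::filter(n_loci == 50) |>
    dplyr::group_by(method) |>
    dplyr::summarise(acc = mean(accuracy))
  expect_gte(max(best50$acc), 0.95)
  # accuracy does not collapse when all loci are used
  full <- dplyr::filter(res, n_loci == 1000)
  expect_gte(mean(full$accuracy), 0.95)
})

test_that("informative fractions: theory matches oracle and simulation", {
  for (cond in c("euploidy", "maternal_trisomy", "paternal_trisomy")) {
    for (m in c(0.05, 0.2, 0.5)) {
      expect_equal(informative_fraction_theory(m, cond),
                   oracle_informative_fraction(m, cond), tolerance = 1e-12)
    }
  }
  expect_equal(informative_fraction_theory(0.5, "maternal_trisomy"), 0.75)
  expect_equal(informative_fraction_theory(0.5, "paternal_trisomy"), 0.875)
  # monomorphic limit
  expect_lt(informative_fraction_theory(1e-4, "euploidy"), 1e-3)

  res <- maf_informative_experiment(maf_set = c(0.05, 0.2, 0.5),
                                    n_variants = 1000, n_reps = 30,
                                    seed = 3)
  expect_true(all(abs(res$simulated - res$theoretical) < 0.02))
  # informative fraction increases with MAF
  for (cond in unique(res$condition)) {
    sims <- res$simulated[res$condition == cond]
    expect_true(all(diff(sims) > 0))
  }
})
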