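test_that("parental haplotypes follow the configured allele frequency", {
  # degenerate MAF: no minor alleles at all
  p0 <- simulate_parent(sim_config(n_loci = 200, maf = 0, seed = 1))
  expect_true(all(p0$hap1 == "A") && all(p0$hap2 == "A"))

  # heterozygosity matches 2 m (1 - m) for intermediate and maximal MAF
  for (m in c(0.2, 0.5)) {
    p <- simulate_parent(sim_config(n_loci = 1e5, maf = m, seed = 11))
    het <- mean(p$hap1 != p$hap2)
    expect_equal(het, 2 * m * (1 - m), tolerance = 0.02)
  }
})

test_that("recombination swaps a suffix and conserves allele multisets", {
  cfg <- sim_config(n_loci = 50, seed = 3)
  p <- simulate_parent(cfg)

  expect_identical(recombine(p, breakpoint = 0), p)

  full <- recombine(p, breakpoint = 50)
  expect_identical(full$hap1, p$hap2)
  expect_identical(full$hap2, p$hap1)

  # breakpoint = number of exchanged terminal alleles
  part <- recombine(p, breakpoint = 20)
  expect_identical(part$hap1[1:30], p$hap1[1:30])
  expect_identical(part$hap1[31:50], p$hap2[31:50])
  expect_identical(part$hap2[31:50], p$hap1[31:50])

  # per-locus multiset conservation for random breakpoints, both modes
  set.seed(42)
  for (mode in c("suffix", "subset")) {
    for (rep in 1:5) {
      r <- recombine(p, crossover = mode)
      expect_identical(pmin(r$hap1, r$hap2), pmin(p$hap1, p$hap2))
      expect_identical(pmax(r$hap1, r$hap2), pmax(p$hap1, p$hap2))
    }
  }
})

test_that("fetal chromosome sets respect the condition's parental origin", {
  cfg <- sim_config(n_loci = 30, seed = 5)
  mother <- recombine(simulate_parent(cfg))
  father <- recombine(simulate_parent(sim_config(n_loci = 30, seed = 6)))

  eu <- form_fetus(mother, father, "euploidy")
  expect_equal(sort(unique(eu$hap_id)), c("m1", "p1"))

  mt <- form_fetus(mother, father, "maternal_trisomy")
  expect_equal(sort(unique(mt$hap_id)), c("m1", "m2", "p1"))
  # meiosis-I heterodisomy: where the mother is heterozygous, the fetus
  # carries both her alleles
  mat_alleles <- tidyr::pivot_wider(
    dplyr::filter(mt, origin == "maternal"),
    id_cols = "locus", names_from = "hap_id", values_from = "allele")
  het <- mother$hap1 != mother$hap2
  expect_true(all((mat_alleles$m1 != mat_alleles$m2)[het]))

  pt <- form_fetus(mother, father, "paternal_trisomy")
  expect_equal(sort(unique(pt$hap_id)), c("m1", "p1", "p2"))

  expect_error(form_fetus(mother, father, "tetrasomy"))
})

test_that("count draws follow the dosage model with the configured overdispersion", {
  cfg <- sim_config(read_depth = 1000, fetal_fraction = 0.10, seed = 8)
  n <- 2e4
  g_tri <- tibble::tibble(maternal_genotype = rep("AB", n),
                          fetal_genotype = rep("AAB", n))
  tri <- draw_counts(g_tri, cfg)
  # E[total] = RD * (1 + FF/2) at a trisomic locus
  expect_equal(mean(tri$total), 1050, tolerance = 0.01)

  g_eu <- tibble::tibble(maternal_genotype = rep("AB", n),
                         fetal_genotype = rep("AB", n))
  eu <- draw_counts(g_eu, cfg)
  expect_equal(mean(eu$total), 1000, tolerance = 0.01)

  # variance-to-mean ratio of a single allele stream at mu = 500
  expect_equal(var(eu$count_a) / mean(eu$count_a), 3, tolerance = 0.06)

  # zero-mean alleles are deterministically zero
  g0 <- tibble::tibble(maternal_genotype = "AA", fetal_genotype = "AA")
  z <- draw_counts(g0, sim_config(read_depth = 1000,
                                  fetal_fraction = 0.1, seed = 9))
  expect_identical(z$count_b, 0L)

  expect_error(draw_counts(
    tibble::tibble(maternal_genotype = "AAB", fetal_genotype = "AB"), cfg),
    class = "niptsim_genotype_error")
})

test_that("a vanishing fetal fraction erases the trisomy depth signal", {
  # expected allele means coincide when FF -> 0, by the dosage formula
  mu_tri <- niptsim:::dosage_means(1, 2, 3, 1000, 1e-12)
  mu_eu <- niptsim:::dosage_means(1, 1, 2, 1000, 1e-12)
  expect_equal(mu_tri$mu_a + mu_tri$mu_b, mu_eu$mu_a + mu_eu$mu_b,
               tolerance = 1e-9)
})

test_that("simulated samples carry contract fields and are seed-reproducible", {
  cfg <- sim_config(n_loci = 100, condition = "maternal_trisomy", seed = 21)
  s1 <- simulate_sample(cfg)
  s2 <- simulate_sample(cfg)
  expect_identical(s1, s2)

  expect_setequal(unique(s1$role), c("studied", "reference"))
  ref <- dplyr::filter(s1, role == "reference")
  expect_true(all(ref$condition == "euploidy"))
  expect_true(all(nchar(ref$fetal_genotype) == 2))
  stu <- dplyr::filter(s1, role == "studied")
  expect_true(all(stu$condition == "maternal_trisomy"))
  expect_true(all(nchar(stu$fetal_genotype) == 3))

  eu <- simulate_sample(sim_config(n_loci = 50, seed = 22))
  expect_true(all(nchar(eu$fetal_genotype) == 2))
})

test_that("sample tables round-trip through TSV", {
  s <- simulate_cohort(sim_config(n_loci = 20, seed = 30), n = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sample_table(s, path, seed = 30)
  back <- read_sample_table(path)
  expect_equal(as.data.frame(back), as.data.frame(s[names(back)]))
})

test_that("informative-locus fractions match genotype enumeration", {
  fracs <- c(euploidy = NA, maternal_trisomy = NA, paternal_trisomy = NA)
  for (cond in names(fracs)) {
    s <- simulate_cohort(sim_config(n_loci = 1000, condition = cond,
                                    seed = 33), n = 10)
    s <- dplyr::filter(s, role == "studied")
    fracs[cond] <- mean(informative_loci(s)$informative)
  }
  expect_equal(unname(fracs["euploidy"]),
               oracle_informative_fraction(0.5, "euploidy"),
               tolerance = 0.03)
  expect_equal(unname(fracs["maternal_trisomy"]), 0.75, tolerance = 0.03)
  expect_equal(unname(fracs["paternal_trisomy"]), 0.875, tolerance = 0.03)
})
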