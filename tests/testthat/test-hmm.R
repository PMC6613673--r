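test_that("expected allelic ratios per state match dosage enumeration", {
  expect_equal(expected_allelic_ratio("E1", 0.05), 1)
  expect_equal(expected_allelic_ratio("E1", 0.19), 1)
  expect_equal(expected_allelic_ratio("E3", 0.1), 19)
  expect_equal(expected_allelic_ratio(c("T3", "P1"), 0.1), c(20, 9.5))

  # enumeration oracle: state-defining genotype pairs reproduce the formulas
  pairs <- list(E1 = c("AB", "AB"), E2 = c("AB", "AA"), E3 = c("AA", "AB"),
                T1 = c("AB", "AAB"), T2 = c("AB", "AAA"),
                T3 = c("AA", "AAB"), P1 = c("AA", "ABB"))
  for (ff in c(0.03, 0.1, 0.18)) {
    for (st in names(pairs)) {
      mu <- oracle_expected_counts(pairs[[st]][1], pairs[[st]][2], 1, ff)
      expect_equal(expected_allelic_ratio(st, ff),
                   max(mu) / min(mu), tolerance = 1e-12, label = st)
    }
  }
  expect_error(expected_allelic_ratio("E1", 0), class = "niptsim_hmm_error")
  expect_error(expected_allelic_ratio("X9", 0.1), class = "niptsim_hmm_error")
})

test_that("transition matrices implement the stay-switch rule", {
  rc <- hmm_transitions("RC")
  expect_equal(unname(rc), matrix(c(10, 1, 1, 10) / 11, 2, 2))

  m7 <- hmm_transitions("AR")
  expect_equal(rowSums(m7), rep(1, 7), ignore_attr = TRUE)
  # row for a euploid state: same-condition states weighted 10, others 1
  expect_equal(unname(m7["E1", ]), c(10, 10, 10, 1, 1, 1, 1) / 34)
  expect_equal(unname(m7["P1", ]), c(1, 1, 1, 1, 1, 1, 10) / 16)
  expect_equal(unname(m7["T2", ]), c(1, 1, 1, 10, 10, 10, 1) / 34)

  m3 <- hmm_transitions("RC", stay_switch_ratio = 3)
  expect_equal(unname(m3[1, ]), c(3, 1) / 4)
  expect_error(hmm_transitions("RC", stay_switch_ratio = 0),
               class = "niptsim_hmm_error")
})

test_that("ground-truth state labels partition informative loci", {
  tr <- training_cohort()
  lab <- true_states(dplyr::filter(informative_loci(tr), informative), "AR")
  expect_false(anyNA(lab$state))
  # P1 occurs only under paternal trisomy
  expect_true(all(lab$condition[lab$state == "P1"] == "paternal_trisomy"))
  # euploid samples only produce E states
  expect_true(all(lab$state[lab$condition == "euploidy"] %in%
                    c("E1", "E2", "E3")))
  # non-informative loci stay unlabelled
  lab_all <- true_states(informative_loci(tr), "AR")
  expect_true(all(is.na(lab_all$state[!lab_all$informative])))
})

test_that("emission moments fit the negative binomial dosage model", {
  tr <- training_cohort()  # RD 1000, FF 0.10
  rc <- fit_hmm(true_states(tr, "RC"), "RC", rd = 1000, ff = 0.1)
  expect_equal(rc$mean["EUP", "total"], 1000, tolerance = 0.02)
  expect_equal(rc$mean["TRI", "total"], 1050, tolerance = 0.02)
  expect_equal(rc$var["EUP", "total"], 3000, tolerance = 0.10)
  expect_equal(rc$var["TRI", "total"], 3150, tolerance = 0.10)

  ar_train <- true_states(dplyr::filter(informative_loci(tr), informative),
                          "AR")
  ar <- fit_hmm(ar_train, "AR")
  expect_equal(ar$mean["E1", "ratio"], 1, tolerance = 0.15)
  # mother-homozygous states keep their ordering T3 > E3 > P1 at FF 10%
  expect_gt(ar$mean["T3", "ratio"], ar$mean["E3", "ratio"])
  expect_gt(ar$mean["E3", "ratio"], ar$mean["P1", "ratio"])

  rcar <- fit_hmm(ar_train, "RCAR")
  expect_identical(colnames(rcar$mean), c("total", "ratio"))
  expect_true(all(rcar$var > 0))

  # scale consistency: doubling RD doubles RC state means
  tr2 <- dplyr::mutate(tr, count_a = 2L * count_a, count_b = 2L * count_b,
                       total = 2L * total)
  rc2 <- fit_hmm(true_states(tr2, "RC"), "RC")
  expect_equal(rc2$mean[, "total"], 2 * rc$mean[, "total"],
               tolerance = 1e-12)

  # a state with < 2 training loci is a named error
  few <- true_states(utils::head(dplyr::filter(tr, condition == "euploidy"),
                                 50), "RC")
  expect_error(fit_hmm(few, "RC"), "TRI", class = "niptsim_hmm_error")
})

test_that("viterbi decoding matches exhaustive path enumeration", {
  set.seed(99)
  for (rep in 1:25) {
    K <- sample(2:3, 1)
    T_ <- sample(2:8, 1)
    D <- sample(1:2, 1)
    mean_m <- matrix(stats::rnorm(K * D, sd = 3), K, D)
    var_m <- matrix(stats::runif(K * D, 0.5, 2), K, D)
    trans <- matrix(stats::runif(K * K, 0.05, 1), K, K)
    trans <- trans / rowSums(trans)
    init <- rep(1 / K, K)
    obs <- matrix(stats::rnorm(T_ * D, sd = 3), T_, D)
    fast <- niptsim:::viterbi_gaussian(obs, mean_m, var_m, log(trans),
                                       log(init))
    slow <- brute_force_viterbi(obs, mean_m, var_m, trans, init)
    expect_identical(fast, as.integer(slow))
  }
})

test_that("batched decoding equals sequence-by-sequence decoding", {
  set.seed(7)
  mean_m <- matrix(c(0, 4), 2, 1)
  var_m <- matrix(c(1, 1), 2, 1)
  lt <- log(matrix(c(.9, .1, .1, .9), 2, 2))
  li <- log(c(.5, .5))
  lens <- c(5L, 9L, 3L)
  seqs <- lapply(lens, function(L) matrix(stats::rnorm(L, 2), ncol = 1))
  single <- unlist(lapply(seqs, function(o) {
    niptsim:::viterbi_gaussian(o, mean_m, var_m, lt, li)
  }))
  batch <- niptsim:::viterbi_gaussian_batch(do.call(rbind, seqs),
                                            c(0L, cumsum(lens)), mean_m,
                                            var_m, lt, li)
  expect_identical(batch, single)
})

test_that("decoding localizes a depth change and flags bad input", {
  tr <- training_cohort()
  rc <- fit_hmm(true_states(tr, "RC"), "RC")
  # first half euploid-mean, second half trisomy-mean: one switch at middle
  obs <- tibble::tibble(locus = 1:100,
                        count_a = c(rep(500L, 50), rep(525L, 50)),
                        count_b = c(rep(500L, 50), rep(525L, 50)))
  dec <- decode_sample(obs, rc)
  expect_identical(dec$state[1:48], rep("EUP", 48))
  expect_identical(dec$state[53:100], rep("TRI", 48))
  switches <- sum(dec$state[-1] != dec$state[-100])
  expect_identical(switches, 1L)

  expect_error(decode_sample(dplyr::mutate(obs, count_a = NA_integer_), rc))
})

test_that("state frequencies normalize and pass through to profiles", {
  f <- state_frequencies(rep(c("EUP", "TRI"), c(600, 400)), kind = "RC")
  expect_equal(f$freq_EUP, 0.6)
  expect_equal(f$freq_TRI, 0.4)
  expect_identical(f$n_loci, 1000L)

  set.seed(1)
  random <- sample(hmm_states("AR")$state, 500, replace = TRUE)
  f7 <- state_frequencies(random, kind = "AR")
  expect_equal(sum(unlist(f7[grepl("^freq_", names(f7))])), 1)
  expect_error(state_frequencies(character(0), kind = "RC"),
               class = "niptsim_hmm_error")
})
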