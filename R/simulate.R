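#' @title Simulating cfDNA sequencing data
#' @description Internal matrix engine plus tidy wrappers. The engine works
#'   on `n_samples x n_loci` matrices of B-allele dosages and counts so that
#'   whole grid cells are simulated in vectorized form; the exported
#'   functions present single samples as tibbles.
#' @name simulate-engine
#' @keywords internal
NULL

# n x L logical matrix: TRUE where the haplotype carries the minor (B) allele
sim_hap_matrix <- function(n, n_loci, maf) {
  matrix(runif(n * n_loci) < maf, nrow = n, ncol = n_loci)
}

# Single crossover: per row draw k in 0..L, the number of exchanged
# homologous alleles, and swap the terminal suffix of that length between
# the two homologs (k = 0 leaves the pair untouched, k = L swaps the
# homologs entirely). "subset" mode swaps a uniformly chosen random set of
# k positions instead.
recombine_matrices <- function(h1, h2, crossover = "suffix",
                               breakpoints = NULL) {
  n <- nrow(h1); L <- ncol(h1)
  stopifnot(identical(dim(h1), dim(h2)))
  if (crossover == "suffix") {
    k <- if (is.null(breakpoints)) sample.int(L + 1L, n, replace = TRUE) - 1L
         else as.integer(breakpoints)
    mask <- outer(k, seq_len(L), function(ki, j) j > L - ki)
  } else {
    k <- sample.int(L + 1L, n, replace = TRUE) - 1L
    mask <- matrix(FALSE, n, L)
    for (i in seq_len(n)) {
      if (k[i] > 0) mask[i, sample.int(L, k[i])] <- TRUE
    }
  }
  r1 <- h1; r2 <- h2
  r1[mask] <- h2[mask]
  r2[mask] <- h1[mask]
  list(r1, r2)
}

# Fetal B-allele dosage matrix for one condition. Maternal meiosis-I
# nondisjunction transmits both (recombined) maternal homologs; paternal
# likewise for the father.
fetal_dosage <- function(mh, ph, condition) {
  n <- nrow(mh[[1]])
  pick <- function(pair) {
    sel <- runif(n) < 0.5
    out <- pair[[1]]
    out[sel, ] <- pair[[2]][sel, , drop = FALSE]
    out
  }
  switch(condition,
    euploidy = pick(mh) + pick(ph),
    maternal_trisomy = mh[[1]] + mh[[2]] + pick(ph),
    paternal_trisomy = pick(mh) + ph[[1]] + ph[[2]]
  )
}

# Negative binomial draws with E = mu, Var = vmr * mu (p = 1/vmr,
# r = mu * p / (1 - p) = mu / (vmr - 1)); mu = 0 short-circuits to 0.
draw_nb <- function(mu, vmr) {
  out <- numeric(length(mu))
  pos <- mu > 0
  if (any(pos)) {
    out[pos] <- rnbinom(sum(pos), size = mu[pos] / (vmr - 1), mu = mu[pos])
  }
  dim(out) <- dim(mu)
  out
}

# Per-allele negative binomial counts from maternal/fetal B dosages.
# mu_x = RD * ((1 - FF) * d_m(x) / 2 + FF * d_f(x) / 2).
dosage_means <- function(d_m, d_f, ploidy, rd, ff) {
  mu_b <- rd * ((1 - ff) * d_m / 2 + ff * d_f / 2)
  mu_a <- rd * ((1 - ff) * (2 - d_m) / 2 + ff * (ploidy - d_f) / 2)
  list(mu_a = mu_a, mu_b = mu_b)
}

# One simulated chromosome for n samples: parental haplotypes, recombination,
# fetal dosages and allele counts. Returns matrices keyed by sample row.
sim_chromosome <- function(n, config, condition = config$condition) {
  L <- config$n_loci
  mh <- recombine_matrices(sim_hap_matrix(n, L, config$maf),
                           sim_hap_matrix(n, L, config$maf),
                           config$crossover)
  ph <- recombine_matrices(sim_hap_matrix(n, L, config$maf),
                           sim_hap_matrix(n, L, config$maf),
                           config$crossover)
  d_m <- mh[[1]] + mh[[2]]
  d_f <- fetal_dosage(mh, ph, condition)
  ploidy <- if (condition == "euploidy") 2L else 3L
  mu <- dosage_means(d_m, d_f, ploidy, config$read_depth,
                     config$fetal_fraction)
  list(d_m = d_m, d_f = d_f, ploidy = ploidy,
       count_a = draw_nb(mu$mu_a, config$vmr),
       count_b = draw_nb(mu$mu_b, config$vmr),
       condition = condition)
}

# Studied chromosome under config$condition plus a euploid reference
# chromosome with the same locus count, depth and fetal fraction.
sim_cell <- function(n, config) {
  list(studied = sim_chromosome(n, config),
       reference = sim_chromosome(n, config, condition = "euploidy"),
       config = config)
}

dosage_to_genotype <- function(dosage, ploidy) {
  paste0(strrep("A", ploidy - dosage), strrep("B", dosage))
}

chromosome_tibble <- function(chrom, role, sample_row = 1L) {
  L <- ncol(chrom$count_a)
  tibble::tibble(
    role = role,
    locus = seq_len(L),
    count_a = as.integer(chrom$count_a[sample_row, ]),
    count_b = as.integer(chrom$count_b[sample_row, ]),
    total = as.integer(chrom$count_a[sample_row, ] +
                         chrom$count_b[sample_row, ]),
    maternal_genotype = dosage_to_genotype(chrom$d_m[sample_row, ], 2L),
    fetal_genotype = dosage_to_genotype(chrom$d_f[sample_row, ],
                                        chrom$ploidy),
    condition = chrom$condition
  )
}

#' Simulate a pair of parental haplotypes
#'
#' Draws one pair of homologous chromosomes for a parent: at each biallelic
#' SNP each haplotype independently carries the minor allele B with
#' probability `maf`, and the major allele A otherwise.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `locus`, `hap1`, `hap2` (values `"A"`/`"B"`).
#' @examples
#' parent <- simulate_parent(sim_config(n_loci = 10, seed = 1))
#' @export
simulate_parent <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  h <- sim_hap_matrix(2L, config$n_loci, config$maf)
  tibble::tibble(locus = seq_len(config$n_loci),
                 hap1 = ifelse(h[1, ], "B", "A"),
                 hap2 = ifelse(h[2, ], "B", "A"))
}

#' Recombine a pair of homologous haplotypes
#'
#' Applies one chromosomal crossover: a count `k` of exchanged homologous
#' alleles is drawn uniformly in `0..n_loci` (or supplied) and the terminal
#' suffix of that length is exchanged between the two homologs. The
#' per-locus allele multiset is conserved exactly.
#'
#' @param parent A tibble as returned by [simulate_parent()].
#' @param breakpoint Optional fixed exchange count; `0` leaves the pair
#'   untouched, `n_loci` swaps the homologs entirely.
#' @param crossover `"suffix"` (single contiguous crossover) or `"subset"`
#'   (swap a random subset of positions).
#' @return A tibble of the same shape as `parent`.
#' @examples
#' p <- simulate_parent(sim_config(n_loci = 10, seed = 1))
#' recombine(p, breakpoint = 5)
#' @export
recombine <- function(parent, breakpoint = NULL,
                      crossover = c("suffix", "subset")) {
  crossover <- match.arg(crossover)
  stopifnot(all(c("hap1", "hap2") %in% names(parent)))
  h1 <- matrix(parent$hap1 == "B", nrow = 1)
  h2 <- matrix(parent$hap2 == "B", nrow = 1)
  r <- recombine_matrices(h1, h2, crossover, breakpoints = breakpoint)
  tibble::tibble(locus = parent$locus,
                 hap1 = ifelse(r[[1]][1, ], "B", "A"),
                 hap2 = ifelse(r[[2]][1, ], "B", "A"))
}

#' Form a fetal chromosome set from recombined parental pairs
#'
#' Under euploidy one homolog is drawn uniformly from each parent. A
#' meiosis-I maternal trisomy transmits both (recombined) maternal homologs
#' plus one paternal homolog; a paternal trisomy transmits one maternal and
#' both paternal homologs.
#'
#' @param mother,father Recombined haplotype pairs ([recombine()] output).
#' @param condition Fetal condition (see [sim_config()]).
#' @return A tibble with columns `locus`, `origin` (`"maternal"`/
#'   `"paternal"`), `hap_id`, `allele`; the condition is attached as the
#'   `"condition"` attribute.
#' @export
form_fetus <- function(mother, father, condition) {
  condition <- match_condition(condition)
  pick1 <- function(p) if (runif(1) < 0.5) p$hap1 else p$hap2
  haps <- switch(condition,
    euploidy = list(maternal = list(pick1(mother)),
                    paternal = list(pick1(father))),
    maternal_trisomy = list(maternal = list(mother$hap1, mother$hap2),
                            paternal = list(pick1(father))),
    paternal_trisomy = list(maternal = list(pick1(mother)),
                            paternal = list(father$hap1, father$hap2))
  )
  rows <- purrr::imap(haps, function(hs, origin) {
    purrr::imap(hs, function(alleles, i) {
      tibble::tibble(locus = mother$locus, origin = origin,
                     hap_id = paste0(substr(origin, 1, 1), i),
                     allele = alleles)
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  attr(out, "condition") <- condition
  out
}

#' Draw over-dispersed allele counts for genotyped loci
#'
#' For each allele `x` the expected count is
#' `RD * ((1 - FF) * d_m(x) / 2 + FF * d_f(x) / 2)` where `d_m`, `d_f` are
#' the allele copy numbers in the maternal and fetal genotypes; counts are
#' negative binomial with variance `vmr` times the mean, independent across
#' alleles and loci. A trisomic locus therefore has expected total
#' `RD * (1 + FF / 2)`.
#'
#' @param genotypes Tibble with columns `maternal_genotype` (two-allele
#'   string such as `"AB"`) and `fetal_genotype` (two- or three-allele
#'   string such as `"AAB"`).
#' @param config A [sim_config()]; `read_depth`, `fetal_fraction` and `vmr`
#'   are used.
#' @return `genotypes` with columns `count_a`, `count_b`, `total` added.
#' @examples
#' g <- tibble::tibble(maternal_genotype = "AA", fetal_genotype = "AAB")
#' draw_counts(g, sim_config(read_depth = 1000, fetal_fraction = 0.1, seed = 1))
#' @export
draw_counts <- function(genotypes, config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  count_allele <- function(g, allele) {
    vapply(strsplit(g, ""), function(a) sum(a == allele), integer(1))
  }
  d_m <- count_allele(genotypes$maternal_genotype, "B")
  d_f <- count_allele(genotypes$fetal_genotype, "B")
  ploidy <- nchar(genotypes$fetal_genotype)
  if (any(nchar(genotypes$maternal_genotype) != 2L)) {
    abort("maternal genotypes must have exactly two alleles.",
          class = "niptsim_genotype_error")
  }
  if (any(!ploidy %in% 2:3)) {
    abort("fetal genotypes must have two or three alleles.",
          class = "niptsim_genotype_error")
  }
  mu <- dosage_means(d_m, d_f, ploidy, config$read_depth,
                     config$fetal_fraction)
  dplyr::mutate(genotypes,
                count_a = as.integer(draw_nb(mu$mu_a, config$vmr)),
                count_b = as.integer(draw_nb(mu$mu_b, config$vmr)),
                total = .data$count_a + .data$count_b)
}

#' Simulate one cfDNA sample
#'
#' Generates a studied chromosome under the configured fetal condition plus
#' a euploid reference chromosome (same locus count, read depth and fetal
#' fraction) used for fetal-fraction estimation. Ground-truth maternal and
#' fetal genotypes are retained per locus.
#'
#' @param config A [sim_config()]; `config$seed` (when set) makes the sample
#'   reproducible.
#' @param sample_id Identifier stored in the output.
#' @return A tibble with one row per (chromosome role, locus): columns
#'   `sample_id`, `role` (`"studied"`/`"reference"`), `locus`, `count_a`,
#'   `count_b`, `total`, `maternal_genotype`, `fetal_genotype`, `condition`,
#'   `ff_true`, `rd`.
#' @examples
#' s <- simulate_sample(sim_config(n_loci = 50, seed = 7,
#'                                 condition = "maternal_trisomy"))
#' dplyr::count(s, role, condition)
#' @export
simulate_sample <- function(config, sample_id = "S1") {
  if (!is.null(config$seed)) set.seed(config$seed)
  cell <- sim_cell(1L, config)
  out <- dplyr::bind_rows(
    chromosome_tibble(cell$studied, "studied"),
    chromosome_tibble(cell$reference, "reference")
  )
  dplyr::mutate(out, sample_id = sample_id,
                ff_true = config$fetal_fraction, rd = config$read_depth,
                .before = 1)
}

#' Simulate a cohort of cfDNA samples
#'
#' @param config A [sim_config()].
#' @param n Number of samples; defaults to `config$n_test`.
#' @param id_prefix Prefix for generated sample identifiers.
#' @return A tibble stacking [simulate_sample()] outputs.
#' @export
simulate_cohort <- function(config, n = config$n_test, id_prefix = "S") {
  if (!is.null(config$seed)) set.seed(config$seed)
  cell <- sim_cell(n, config)
  purrr::map_dfr(seq_len(n), function(i) {
    out <- dplyr::bind_rows(
      chromosome_tibble(cell$studied, "studied", i),
      chromosome_tibble(cell$reference, "reference", i)
    )
    dplyr::mutate(out, sample_id = sprintf("%s%04d", id_prefix, i),
                  ff_true = config$fetal_fraction,
                  rd = config$read_depth, .before = 1)
  })
}

#' Write simulated samples to a tab-separated table
#'
#' Columns: `sample_id`, `chromosome_role`, `locus_index` (0-based),
#' `count_a`, `count_b`, `maternal_genotype`, `fetal_genotype`, `condition`,
#' `ff_true`, `rd`, `seed`. Paths ending in `.gz` are compressed
#' transparently.
#'
#' @param samples Output of [simulate_sample()] / [simulate_cohort()].
#' @param path Destination TSV path.
#' @param seed Seed recorded in the table (metadata only).
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(samples, path, seed = NA_integer_) {
  out <- dplyr::transmute(samples,
    sample_id = .data$sample_id, chromosome_role = .data$role,
    locus_index = .data$locus - 1L, count_a = .data$count_a,
    count_b = .data$count_b, maternal_genotype = .data$maternal_genotype,
    fetal_genotype = .data$fetal_genotype, condition = .data$condition,
    ff_true = .data$ff_true, rd = .data$rd, seed = seed)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a simulated sample table written by [write_sample_table()]
#'
#' @param path TSV path (gzip transparent).
#' @return A tibble in [simulate_sample()] layout.
#' @export
read_sample_table <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("sample_id", "chromosome_role", "locus_index", "count_a",
            "count_b", "condition", "ff_true", "rd")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    abort(paste0("missing columns: ", paste(missing, collapse = ", ")),
          class = "niptsim_io_error")
  }
  dplyr::transmute(raw,
    sample_id = .data$sample_id, role = .data$chromosome_role,
    locus = .data$locus_index + 1L, count_a = .data$count_a,
    count_b = .data$count_b, total = .data$count_a + .data$count_b,
    maternal_genotype = if ("maternal_genotype" %in% names(raw))
      .data$maternal_genotype else NA_character_,
    fetal_genotype = if ("fetal_genotype" %in% names(raw))
      .data$fetal_genotype else NA_character_,
    condition = .data$condition, ff_true = .data$ff_true, rd = .data$rd)
}
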