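#' Flag informative SNPs
#'
#' A targeted SNP is informative when the mother and/or the fetus is
#' heterozygous; only such loci carry fetal signal in their allelic depth
#' imbalance. With ground-truth genotypes (simulated data) the rule is
#' applied literally (`mode = "truth"`). For real data without genotypes
#' (`mode = "observed"`) a locus is taken as informative when its minor
#' count clears a small absolute-plus-relative floor,
#' `min_i >= max(2, 0.005 * total)`, which rejects pure noise without
#' discarding low fetal-fraction signal.
#'
#' @param observations Tibble of locus observations with `count_a`,
#'   `count_b` and, for truth mode, `maternal_genotype`/`fetal_genotype`.
#' @param mode `"truth"` or `"observed"`.
#' @return `observations` with a logical `informative` column added.
#' @examples
#' s <- simulate_sample(sim_config(n_loci = 20, seed = 1))
#' informative_loci(s)
#' @export
informative_loci <- function(observations, mode = c("truth", "observed")) {
  mode <- match.arg(mode)
  if (mode == "truth") {
    if (!all(c("maternal_genotype", "fetal_genotype") %in%
               names(observations)) ||
        anyNA(observations$maternal_genotype)) {
      abort("truth mode requires maternal and fetal genotype columns.",
            class = "niptsim_feature_error")
    }
    het <- function(g) {
      vapply(strsplit(g, ""), function(a) length(unique(a)) > 1, logical(1))
    }
    inf <- het(observations$maternal_genotype) |
      het(observations$fetal_genotype)
  } else {
    mn <- pmin(observations$count_a, observations$count_b)
    tot <- observations$count_a + observations$count_b
    inf <- mn >= pmax(2, 0.005 * tot)
  }
  dplyr::mutate(observations, informative = inf)
}

#' Allelic ratios at informative SNPs
#'
#' The allelic ratio of a SNP is the read count of its major allele divided
#' by the read count of its minor allele (major/minor defined per locus, so
#' the ratio is at least 1). Loci whose minor count is zero get ratio `Inf`;
#' downstream consumers either tolerate the sentinel (fetal-fraction
#' estimation) or clamp it (Gaussian HMM emissions). The minor fraction
#' `2 * min / (max + min)` is carried alongside.
#'
#' @param observations Locus observations; if no `informative` column is
#'   present, [informative_loci()] is applied first (truth mode when
#'   genotypes are available, observed mode otherwise).
#' @param mode Passed to [informative_loci()] when the mask is missing.
#' @return Tibble with columns `locus`, `count_major`, `count_minor`,
#'   `ratio`, `minor_fraction`, restricted to informative loci in
#'   chromosomal order.
#' @examples
#' s <- simulate_sample(sim_config(n_loci = 20, seed = 1))
#' allelic_ratios(dplyr::filter(s, role == "studied"))
#' @export
allelic_ratios <- function(observations, mode = NULL) {
  if (!"informative" %in% names(observations)) {
    if (is.null(mode)) {
      mode <- if ("maternal_genotype" %in% names(observations) &&
                    !anyNA(observations$maternal_genotype)) "truth"
              else "observed"
    }
    observations <- informative_loci(observations, mode)
  }
  out <- dplyr::filter(observations, .data$informative)
  mx <- pmax(out$count_a, out$count_b)
  mn <- pmin(out$count_a, out$count_b)
  tibble::tibble(
    locus = if ("locus" %in% names(out)) out$locus else seq_len(nrow(out)),
    count_major = mx, count_minor = mn,
    ratio = ifelse(mn > 0, mx / mn, Inf),
    minor_fraction = ifelse(mx + mn > 0, 2 * mn / (mx + mn), NA_real_)
  )
}

# Vectorized fetal-fraction estimate from reference-chromosome count
# matrices (one row per sample); informative mask supplied by the caller.
estimate_ff_matrix <- function(count_a, count_b, informative,
                               ar_threshold = 2.5) {
  mx <- pmax(count_a, count_b)
  mn <- pmin(count_a, count_b)
  ratio <- ifelse(mn > 0, mx / mn, Inf)
  sel <- informative & ratio > ar_threshold & (mx + mn) > 0
  mf <- 2 * mn / (mx + mn)
  mf[!sel] <- NA_real_
  apply(mf, 1, median, na.rm = TRUE)
}

#' Estimate the fetal fraction from reference-chromosome allele counts
#'
#' Informative SNPs on the sample's (euploid) reference chromosome where the
#' mother is homozygous and the fetus heterozygous are selected by requiring
#' an allelic ratio above 2.5; loci with a zero minor count pass the filter
#' (ratio treated as infinite) and contribute 0 to the median. The fetal
#' fraction is then the median of `2 * min_i / (max_i + min_i)` over the
#' selected loci: at such loci the minor depth is half the fetal
#' contribution, so twice its share of the total estimates the fetal
#' fraction.
#'
#' @param observations Locus observations of the reference chromosome. If a
#'   `role` column is present, rows with `role == "reference"` are used.
#' @param mode Informativeness mode (see [informative_loci()]); `NULL`
#'   selects truth mode when genotypes are present.
#' @param ar_threshold Allelic-ratio selection threshold (default 2.5).
#' @return One-row tibble: `ff_hat`, `n_loci_used`, `status` (`"ok"` or
#'   `"no_loci"`, the latter with `ff_hat = NA`).
#' @examples
#' s <- simulate_sample(sim_config(read_depth = 5000, fetal_fraction = 0.1,
#'                                 seed = 3))
#' estimate_ff(s)
#' @export
estimate_ff <- function(observations, mode = NULL, ar_threshold = 2.5) {
  if (nrow(observations) == 0) {
    abort("no reference observations supplied.",
          class = "niptsim_feature_error")
  }
  if ("role" %in% names(observations) &&
        any(observations$role == "reference")) {
    observations <- dplyr::filter(observations, .data$role == "reference")
  }
  ars <- allelic_ratios(observations, mode = mode)
  sel <- dplyr::filter(ars, .data$ratio > ar_threshold,
                       .data$count_major + .data$count_minor > 0)
  if (nrow(sel) == 0) {
    return(tibble::tibble(ff_hat = NA_real_, n_loci_used = 0L,
                          status = "no_loci"))
  }
  tibble::tibble(ff_hat = median(sel$minor_fraction),
                 n_loci_used = nrow(sel), status = "ok")
}
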