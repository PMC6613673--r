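#' HMM state spaces
#'
#' The read-count (RC) model is a 2-state HMM over locus total counts with
#' states `EUP` and `TRI`. The allelic-ratio (AR) and combined (RCAR)
#' models are 7-state HMMs over informative SNPs; each state is one allelic
#' pattern, a combination of fetal condition with maternal/fetal genotype
#' class:
#'
#' * `E1` euploid, mother and fetus heterozygous (ratio 1);
#' * `E2` euploid, mother heterozygous, fetus homozygous;
#' * `E3` euploid, mother homozygous, fetus heterozygous;
#' * `T1` trisomic, mother heterozygous, fetus heterozygous (2:1);
#' * `T2` trisomic, mother heterozygous, fetus homozygous;
#' * `T3` trisomic, mother homozygous, fetus carrying two maternal-allele
#'   copies plus one other;
#' * `P1` trisomic, mother homozygous, fetus carrying one maternal allele
#'   plus two non-maternal copies -- a pattern only a paternally originated
#'   meiosis-I trisomy can produce.
#'
#' `T*` states are associated with maternally originated trisomy (the
#' shared patterns are assigned to the maternal group to avoid over-calling
#' paternal trisomy); `P1` with paternal trisomy.
#'
#' @param kind `"RC"`, `"AR"` or `"RCAR"`.
#' @return A tibble with columns `state` and `condition` (the fetal
#'   condition group of the state: `"euploidy"`, `"maternal_trisomy"` or
#'   `"paternal_trisomy"`).
#' @examples
#' hmm_states("RC")
#' hmm_states("AR")
#' @export
hmm_states <- function(kind = c("RC", "AR", "RCAR")) {
  kind <- match.arg(kind)
  if (kind == "RC") {
    tibble::tibble(state = c("EUP", "TRI"),
                   condition = c("euploidy", "maternal_trisomy"))
  } else {
    tibble::tibble(
      state = c("E1", "E2", "E3", "T1", "T2", "T3", "P1"),
      condition = c(rep("euploidy", 3), rep("maternal_trisomy", 3),
                    "paternal_trisomy"))
  }
}

#' Noise-free expected allelic ratio per 7-state allelic pattern
#'
#' Derived by dosage enumeration: the expected depth of allele `x` is
#' proportional to `(1 - ff) * d_m(x) / 2 + ff * d_f(x) / 2`, and the ratio
#' is the larger over the smaller allele mean.
#'
#' @param state Character vector of states among
#'   `E1, E2, E3, T1, T2, T3, P1`.
#' @param ff Fetal fraction in `(0, 1)`.
#' @return Numeric vector of expected major/minor ratios.
#' @examples
#' expected_allelic_ratio(c("E3", "T3", "P1"), ff = 0.1)
#' @export
expected_allelic_ratio <- function(state, ff) {
  if (!is.numeric(ff) || any(ff <= 0) || any(ff >= 1)) {
    abort("`ff` must lie in (0, 1).", class = "niptsim_hmm_error")
  }
  unname(vapply(state, function(s) {
    switch(s,
      E1 = 1,
      E2 = (1 + ff) / (1 - ff),
      E3 = (2 - ff) / ff,
      T1 = 1 + ff,
      T2 = (1 + 2 * ff) / (1 - ff),
      T3 = 2 / ff,
      P1 = (2 - ff) / (2 * ff),
      abort(paste0("unknown state: ", s), class = "niptsim_hmm_error"))
  }, numeric(1)))
}

#' Transition matrix with a stay-switch ratio
#'
#' Staying within the current fetal condition is `stay_switch_ratio` times
#' more likely than switching to a state of a different condition:
#' unnormalized row weights give the current state and every same-condition
#' state weight `stay_switch_ratio` and every different-condition state
#' weight 1, then rows are normalized. Within one condition the allelic
#' pattern legitimately changes at nearly every informative SNP, so
#' same-condition moves carry no penalty. For the 2-state RC model this
#' reduces to `[[10/11, 1/11], [1/11, 10/11]]`.
#'
#' @param states State-space tibble from [hmm_states()] (or a kind string).
#' @param stay_switch_ratio Positive stay-switch weight (default 10).
#' @return Row-stochastic transition matrix with state dimnames.
#' @examples
#' hmm_transitions("RC")
#' @export
hmm_transitions <- function(states, stay_switch_ratio = 10) {
  if (is.character(states) && length(states) == 1) {
    states <- hmm_states(states)
  }
  if (!is.numeric(stay_switch_ratio) || stay_switch_ratio <= 0) {
    abort("`stay_switch_ratio` must be positive.",
          class = "niptsim_hmm_error")
  }
  same <- outer(states$condition, states$condition, `==`)
  w <- ifelse(same, stay_switch_ratio, 1)
  m <- w / rowSums(w)
  dimnames(m) <- list(states$state, states$state)
  m
}

# Integer state labels (index into hmm_states("AR")) for informative loci
# from ground-truth dosage matrices; NA for non-informative loci.
state_label_matrix <- function(d_m, d_f, ploidy, condition) {
  mhet <- d_m == 1L
  lab <- matrix(NA_integer_, nrow(d_m), ncol(d_m))
  if (condition == "euploidy") {
    fhet <- d_f == 1L
    lab[mhet & fhet] <- 1L                     # E1
    lab[mhet & !fhet] <- 2L                    # E2
    lab[!mhet & fhet] <- 3L                    # E3
  } else {
    fhet <- d_f == 1L | d_f == 2L
    lab[mhet & fhet] <- 4L                     # T1
    lab[mhet & !fhet] <- 5L                    # T2
    q <- ifelse(d_m == 0L, d_f, 3L - d_f)      # fetal dosage of the
    lab[!mhet & q == 1L] <- 6L                 # non-maternal allele
    lab[!mhet & q == 2L] <- 7L                 # P1: two non-maternal copies
  }
  lab
}

#' Ground-truth HMM state labels for simulated loci
#'
#' Maps the simulated maternal/fetal genotypes of each locus to the HMM
#' state it realises: for the RC model every locus of a euploid sample is
#' `EUP` and of a trisomic sample `TRI`; for the 7-state models informative
#' loci get their allelic-pattern state (see [hmm_states()]) and
#' non-informative loci get `NA`.
#'
#' @param observations Simulated locus observations (with genotype columns
#'   and `condition`).
#' @param kind Model kind.
#' @return `observations` with a `state` column added.
#' @export
true_states <- function(observations, kind = c("RC", "AR", "RCAR")) {
  kind <- match.arg(kind)
  if (kind == "RC") {
    return(dplyr::mutate(observations, state = ifelse(
      .data$condition == "euploidy", "EUP", "TRI")))
  }
  d_m <- vapply(strsplit(observations$maternal_genotype, ""),
                function(a) sum(a == "B"), integer(1))
  d_f <- vapply(strsplit(observations$fetal_genotype, ""),
                function(a) sum(a == "B"), integer(1))
  states7 <- hmm_states("AR")$state
  lab <- rep(NA_integer_, nrow(observations))
  for (cond in unique(observations$condition)) {
    i <- observations$condition == cond
    lab[i] <- state_label_matrix(matrix(d_m[i], 1), matrix(d_f[i], 1),
                                 if (cond == "euploidy") 2L else 3L,
                                 cond)[1, ]
  }
  dplyr::mutate(observations, state = states7[lab])
}

new_nipt_hmm <- function(kind, mean, var, stay_switch_ratio, ratio_cap,
                         rd = NA_real_, ff = NA_real_, n_train = NA_integer_) {
  states <- hmm_states(kind)
  trans <- hmm_transitions(states, stay_switch_ratio)
  structure(
    list(kind = kind, states = states, mean = mean, var = var,
         transitions = trans, log_trans = log(trans),
         log_init = rep(-log(nrow(states)), nrow(states)),
         ratio_cap = ratio_cap, rd = rd, ff = ff, n_train = n_train,
         stay_switch_ratio = stay_switch_ratio),
    class = "nipt_hmm")
}

obs_dims <- function(kind) {
  switch(kind, RC = "total", AR = "ratio", RCAR = c("total", "ratio"))
}

# Moment fit shared by the tidy and matrix paths. obs: numeric matrix
# (loci x dims); labels: integer state indices.
fit_hmm_moments <- function(labels, obs, kind, stay_switch_ratio, rd, ff,
                            n_train) {
  states <- hmm_states(kind)
  K <- nrow(states)
  dims <- obs_dims(kind)
  ratio_cap <- NA_real_
  if ("ratio" %in% dims) {
    rcol <- match("ratio", dims)
    finite <- obs[, rcol][is.finite(obs[, rcol])]
    if (length(finite) == 0) {
      abort("no finite allelic ratios in training data.",
            class = "niptsim_hmm_error")
    }
    ratio_cap <- 2 * quantile(finite, 0.99, names = FALSE)
    obs[, rcol] <- pmin(obs[, rcol], ratio_cap)
  }
  mean_m <- matrix(NA_real_, K, length(dims),
                   dimnames = list(states$state, dims))
  var_m <- mean_m
  for (k in seq_len(K)) {
    rows <- which(labels == k)
    if (length(rows) < 2) {
      abort(sprintf("state %s has fewer than 2 training loci.",
                    states$state[k]), class = "niptsim_hmm_error")
    }
    for (d in seq_along(dims)) {
      mean_m[k, d] <- mean(obs[rows, d])
      var_m[k, d] <- var(obs[rows, d])
    }
  }
  new_nipt_hmm(kind, mean_m, var_m, stay_switch_ratio, ratio_cap,
               rd = rd, ff = ff, n_train = n_train)
}

#' Fit HMM emission parameters from labelled training loci
#'
#' Emission distributions are Gaussian (diagonal for the bivariate RCAR
#' model), with per-state mean and variance estimated from the training
#' loci carrying that ground-truth state. Infinite allelic ratios (zero
#' minor count) are clamped to twice the 99th percentile of the finite
#' training ratios before fitting; the cap is stored in the model and
#' applied again at decoding time. The initial state distribution is
#' uniform and transitions follow the stay-switch rule
#' ([hmm_transitions()]).
#'
#' @param train Tibble of training loci with a `state` column (see
#'   [true_states()]) and the observation columns the model needs: `total`
#'   for RC, `ratio` for AR, both for RCAR. For the 7-state models the rows
#'   must be informative loci (non-`NA` state).
#' @param kind Model kind.
#' @param stay_switch_ratio Transition stay-switch weight (default 10).
#' @param rd,ff Training condition metadata stored in the model.
#' @return An object of class `nipt_hmm`.
#' @examples
#' cfg <- sim_config(n_loci = 200, read_depth = 1000, fetal_fraction = 0.1,
#'                   condition = "maternal_trisomy", seed = 1)
#' tr <- dplyr::bind_rows(
#'   simulate_cohort(sim_config(n_loci = 200, read_depth = 1000,
#'                              fetal_fraction = 0.1, seed = 2), n = 5),
#'   simulate_cohort(cfg, n = 5))
#' tr <- dplyr::filter(tr, role == "studied")
#' m <- fit_hmm(true_states(tr, "RC"), "RC")
#' tidy(m)
#' @export
fit_hmm <- function(train, kind = c("RC", "AR", "RCAR"),
                    stay_switch_ratio = 10, rd = NA_real_, ff = NA_real_) {
  kind <- match.arg(kind)
  dims <- obs_dims(kind)
  if ("ratio" %in% dims && !"ratio" %in% names(train)) {
    mx <- pmax(train$count_a, train$count_b)
    mn <- pmin(train$count_a, train$count_b)
    train$ratio <- ifelse(mn > 0, mx / mn, Inf)
  }
  if (!all(dims %in% names(train))) {
    abort(paste0("training data must provide columns: ",
                 paste(dims, collapse = ", ")),
          class = "niptsim_hmm_error")
  }
  train <- dplyr::filter(train, !is.na(.data$state))
  labels <- match(train$state, hmm_states(kind)$state)
  obs <- as.matrix(train[, dims, drop = FALSE])
  fit_hmm_moments(labels, obs, kind, stay_switch_ratio, rd, ff,
                  n_train = length(unique(train$sample_id %||% "1")))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Core decoder: obs matrix (loci x dims) -> integer path.
viterbi_path <- function(obs, model) {
  if (!is.matrix(obs)) obs <- matrix(obs, ncol = 1)
  if (!is.na(model$ratio_cap)) {
    rcol <- match("ratio", obs_dims(model$kind))
    obs[, rcol] <- pmin(obs[, rcol], model$ratio_cap)
  }
  viterbi_gaussian(obs, model$mean, model$var, model$log_trans,
                   model$log_init)
}

#' Viterbi-decode a sample's locus observations
#'
#' Finds the maximum-a-posteriori state path under the fitted HMM using
#' log-space Viterbi decoding with a uniform initial distribution; ties
#' break deterministically to the lowest-index state. For the RC model the
#' observation sequence is the total count at every locus; for AR/RCAR it
#' is the (clamped) allelic ratio, with the total count alongside for RCAR,
#' at informative loci in chromosomal order.
#'
#' @param observations Locus observations of one chromosome (one sample).
#'   If a `role` column is present, `role == "studied"` rows are used.
#' @param model A fitted `nipt_hmm`.
#' @param mode Informativeness mode for the 7-state models (see
#'   [informative_loci()]); `NULL` picks truth mode when genotypes exist.
#' @return Tibble of the decoded loci: `locus`, the observation column(s),
#'   `state`, and the state's fetal-condition group `condition_call`.
#' @export
decode_sample <- function(observations, model, mode = NULL) {
  if ("role" %in% names(observations) &&
        any(observations$role == "studied")) {
    observations <- dplyr::filter(observations, .data$role == "studied")
  }
  if ("locus" %in% names(observations)) {
    observations <- dplyr::arrange(observations, .data$locus)
  }
  if (model$kind == "RC") {
    obs <- matrix(observations$count_a + observations$count_b, ncol = 1)
    loci <- observations$locus %||% seq_len(nrow(observations))
    dec <- tibble::tibble(locus = loci, total = obs[, 1])
  } else {
    ars <- allelic_ratios(observations, mode = mode)
    if (nrow(ars) == 0) {
      abort("no informative loci to decode.", class = "niptsim_hmm_error")
    }
    if (model$kind == "AR") {
      obs <- matrix(ars$ratio, ncol = 1)
    } else {
      obs <- cbind(total = ars$count_major + ars$count_minor,
                   ratio = ars$ratio)
    }
    dec <- tibble::tibble(locus = ars$locus, ratio = ars$ratio)
    if (model$kind == "RCAR") dec$total <- ars$count_major + ars$count_minor
  }
  path <- viterbi_path(obs, model)
  dec$state <- model$states$state[path]
  dec$condition_call <- model$states$condition[path]
  dec
}

#' State frequencies of a decoded path
#'
#' Normalized histogram of decoded states -- the per-sample feature vector
#' consumed by the chromosome-level classifiers.
#'
#' @param decoded A [decode_sample()] result, or a character vector of
#'   states.
#' @param kind Model kind (used to fix the state order when `decoded` is a
#'   bare vector; inferred otherwise).
#' @return One-row tibble with `freq_<state>` columns (summing to 1) and
#'   `n_loci`.
#' @examples
#' state_frequencies(c("EUP", "EUP", "TRI"), kind = "RC")
#' @export
state_frequencies <- function(decoded, kind = NULL) {
  states <- if (is.data.frame(decoded)) decoded$state else decoded
  if (length(states) == 0) {
    abort("empty state path.", class = "niptsim_hmm_error")
  }
  if (is.null(kind)) {
    kind <- if (all(states %in% c("EUP", "TRI"))) "RC" else "AR"
  }
  space <- hmm_states(kind)$state
  freq <- as.numeric(table(factor(states, levels = space))) / length(states)
  out <- tibble::as_tibble(setNames(as.list(freq), paste0("freq_", space)))
  out$n_loci <- length(states)
  out
}

#' @export
print.nipt_hmm <- function(x, ...) {
  cat(sprintf("<nipt_hmm: %s, %d states>\n", x$kind, nrow(x$states)))
  cat(sprintf("  trained at RD %s, FF %s (stay-switch %g)\n",
              format(x$rd), format(x$ff), x$stay_switch_ratio))
  print(tidy(x))
  invisible(x)
}

#' @rdname fit_hmm
#' @param x A fitted `nipt_hmm`.
#' @param ... Unused.
#' @export
tidy.nipt_hmm <- function(x, ...) {
  dims <- colnames(x$mean)
  purrr::map_dfr(seq_along(dims), function(d) {
    tibble::tibble(state = x$states$state,
                   condition = x$states$condition,
                   dimension = dims[d], mean = x$mean[, d],
                   variance = x$var[, d])
  })
}

#' @rdname fit_hmm
#' @export
glance.nipt_hmm <- function(x, ...) {
  tibble::tibble(kind = x$kind, n_states = nrow(x$states),
                 n_dims = ncol(x$mean), rd = x$rd, ff = x$ff,
                 stay_switch_ratio = x$stay_switch_ratio,
                 ratio_cap = x$ratio_cap)
}
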