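#' Chromosome-level call by the modal decoded condition
#'
#' Sums the decoded state frequencies within each fetal-condition group and
#' calls the condition with the strict maximum; an exact tie yields
#' `"unclassified"`. For the 2-state RC model the call is `"euploidy"` or
#' `"trisomy"`; for the 7-state models the `T*` group is reported as
#' maternally originated trisomy and `P1` as paternal trisomy.
#'
#' @param profile A [state_frequencies()] row, a named numeric vector of
#'   `freq_<state>` (or state-named) frequencies, or a [decode_sample()]
#'   result.
#' @param kind Model kind; inferred from the state names when `NULL`.
#' @return One-row tibble: `call`, `method = "mode"`, and the per-condition
#'   frequency mass columns.
#' @examples
#' mode_call(c(freq_EUP = 0.9, freq_TRI = 0.1))
#' mode_call(c(freq_EUP = 0.5, freq_TRI = 0.5))
#' @export
mode_call <- function(profile, kind = NULL) {
  if (is.data.frame(profile) && "state" %in% names(profile)) {
    profile <- state_frequencies(profile, kind = kind)
  }
  if (is.data.frame(profile)) {
    profile <- unlist(profile[1, grepl("^freq_", names(profile))])
  }
  names(profile) <- sub("^freq_", "", names(profile))
  if (is.null(kind)) {
    kind <- if (all(names(profile) %in% c("EUP", "TRI"))) "RC" else "AR"
  }
  states <- hmm_states(kind)
  freq <- profile[states$state]
  if (anyNA(freq)) {
    abort("profile does not cover the model's state space.",
          class = "niptsim_classify_error")
  }
  mass <- tapply(freq, states$condition, sum)
  groups <- if (kind == "RC") c("euploidy", "trisomy")
            else nipt_conditions
  names(mass) <- if (kind == "RC") {
    ifelse(names(mass) == "euploidy", "euploidy", "trisomy")
  } else names(mass)
  mass <- tapply(as.numeric(mass), names(mass), sum)[groups]
  top <- which(mass == max(mass))
  call <- if (length(top) > 1) "unclassified" else names(mass)[top]
  out <- tibble::tibble(call = call, method = "mode")
  out[paste0("mass_", names(mass))] <- as.list(as.numeric(mass))
  out
}

# Vectorized modal call over a samples x states frequency matrix.
mode_call_matrix <- function(freq, kind) {
  states <- hmm_states(kind)
  groups <- if (kind == "RC") c("euploidy", "trisomy") else nipt_conditions
  cond <- if (kind == "RC") {
    ifelse(states$condition == "euploidy", "euploidy", "trisomy")
  } else states$condition
  mass <- vapply(groups, function(g) {
    rowSums(freq[, cond == g, drop = FALSE])
  }, numeric(nrow(freq)))
  if (!is.matrix(mass)) mass <- matrix(mass, nrow = 1,
                                       dimnames = list(NULL, groups))
  top <- max.col(mass, ties.method = "first")
  tied <- rowSums(mass == mass[cbind(seq_len(nrow(mass)), top)]) > 1
  out <- groups[top]
  out[tied] <- "unclassified"
  out
}

meta_feature_matrix <- function(data, feature_names = NULL) {
  if (is.null(feature_names)) {
    feature_names <- intersect(
      c("rd", "ff", grep("^freq_", names(data), value = TRUE)), names(data))
  }
  missing <- setdiff(feature_names, names(data))
  if (length(missing) > 0) {
    abort(paste0("missing feature columns: ",
                 paste(missing, collapse = ", ")),
          class = "niptsim_classify_error")
  }
  as.matrix(data[, feature_names, drop = FALSE])
}

#' Fit the depth-3 decision tree on HMM state-frequency features
#'
#' An axis-aligned binary classification tree (Gini impurity splits) with
#' maximum depth 3 and no cost-complexity pruning, fitted on the features
#' read depth, fetal fraction and decoded state frequencies. The fit is
#' deterministic for a fixed seed, data and feature order.
#'
#' @param data Tibble of per-sample features: `rd`, `ff` and `freq_*`
#'   columns (additional columns are ignored).
#' @param labels Character/factor vector of true chromosome-level labels.
#' @param max_depth Maximum tree depth (default 3).
#' @param seed RNG seed set before fitting (default 123).
#' @return An object of class `nipt_tree`.
#' @examples
#' d <- tibble::tibble(rd = 1000, ff = 0.1,
#'                     freq_EUP = c(0.9, 0.8, 0.2, 0.1),
#'                     freq_TRI = c(0.1, 0.2, 0.8, 0.9))
#' fit <- fit_tree(d, c("euploidy", "euploidy", "trisomy", "trisomy"))
#' predict(fit, d)
#' @export
fit_tree <- function(data, labels, max_depth = 3, seed = 123) {
  x <- meta_feature_matrix(data)
  df <- data.frame(x, check.names = FALSE)
  df$.label <- factor(labels)
  if (nlevels(df$.label) < 2) {
    # degenerate single-class tree: a bare root predicting that class
    return(structure(list(fit = NULL, features = colnames(x),
                          levels = levels(df$.label),
                          max_depth = max_depth, seed = seed),
                     class = "nipt_tree"))
  }
  set.seed(seed)
  fit <- rpart::rpart(
    .label ~ ., data = df, method = "class",
    parms = list(split = "gini"),
    control = rpart::rpart.control(maxdepth = max_depth, cp = 0,
                                   minsplit = 2, minbucket = 1, xval = 0))
  structure(list(fit = fit, features = colnames(x),
                 levels = levels(df$.label), max_depth = max_depth,
                 seed = seed),
            class = "nipt_tree")
}

#' @rdname fit_tree
#' @param object A fitted `nipt_tree`.
#' @param new_data Feature tibble with the training feature columns.
#' @param ... Unused.
#' @export
predict.nipt_tree <- function(object, new_data, ...) {
  x <- meta_feature_matrix(new_data, object$features)
  if (is.null(object$fit)) {
    return(rep(object$levels, nrow(x)))
  }
  cls <- predict(object$fit, data.frame(x, check.names = FALSE),
                 type = "class")
  as.character(cls)
}

# Depth of a fitted rpart tree (root = depth 0).
tree_depth <- function(x) {
  fit <- if (inherits(x, "nipt_tree")) x$fit else x
  if (is.null(fit)) return(0L)
  nodes <- as.integer(rownames(fit$frame))
  as.integer(max(floor(log2(nodes))))
}

#' Fit the soft-margin kernel classifier on HMM state-frequency features
#'
#' A soft-margin support-vector classifier with radial basis kernel,
#' regularization constant 1, kernel width `1 / n_features`, one-vs-one
#' multiclass handling and no feature standardization, fitted on read
#' depth, fetal fraction and decoded state frequencies.
#'
#' @inheritParams fit_tree
#' @return An object of class `nipt_margin`.
#' @examples
#' d <- tibble::tibble(rd = 1000, ff = 0.1,
#'                     freq_EUP = c(0.9, 0.8, 0.2, 0.1),
#'                     freq_TRI = c(0.1, 0.2, 0.8, 0.9))
#' fit <- fit_margin(d, c("euploidy", "euploidy", "trisomy", "trisomy"))
#' predict(fit, d)
#' @export
fit_margin <- function(data, labels, seed = 123) {
  x <- meta_feature_matrix(data)
  y <- factor(labels)
  if (nlevels(y) < 2) {
    abort("margin classifier needs at least two classes.",
          class = "niptsim_classify_error")
  }
  set.seed(seed)
  fit <- e1071::svm(x = x, y = y, kernel = "radial", cost = 1,
                    gamma = 1 / ncol(x), scale = FALSE)
  structure(list(fit = fit, features = colnames(x), levels = levels(y),
                 seed = seed),
            class = "nipt_margin")
}

#' @rdname fit_margin
#' @param object A fitted `nipt_margin`.
#' @param new_data Feature tibble with the training feature columns.
#' @param ... Unused.
#' @export
predict.nipt_margin <- function(object, new_data, ...) {
  x <- meta_feature_matrix(new_data, object$features)
  as.character(predict(object$fit, x))
}

#' @export
print.nipt_tree <- function(x, ...) {
  cat(sprintf("<nipt_tree: depth %d, classes %s>\n", tree_depth(x),
              paste(x$levels, collapse = "/")))
  invisible(x)
}

#' @export
print.nipt_margin <- function(x, ...) {
  cat(sprintf("<nipt_margin: RBF, %d support vectors, classes %s>\n",
              x$fit$tot.nSV, paste(x$levels, collapse = "/")))
  invisible(x)
}

#' @rdname fit_tree
#' @param x A fitted `nipt_tree`.
#' @export
tidy.nipt_tree <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble::tibble(node = 1L, variable = "<leaf>", n = NA_integer_,
                          is_leaf = TRUE, class = x$levels))
  }
  fr <- x$fit$frame
  tibble::tibble(node = as.integer(rownames(fr)),
                 variable = as.character(fr$var),
                 n = fr$n, is_leaf = fr$var == "<leaf>",
                 class = x$levels[fr$yval])
}

#' @rdname fit_tree
#' @export
glance.nipt_tree <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble::tibble(depth = 0L, n_leaves = 1L,
                          n_train = NA_integer_, n_classes = 1L))
  }
  tibble::tibble(depth = tree_depth(x),
                 n_leaves = sum(x$fit$frame$var == "<leaf>"),
                 n_train = x$fit$frame$n[1], n_classes = length(x$levels))
}

#' @rdname fit_margin
#' @param x A fitted `nipt_margin`.
#' @export
glance.nipt_margin <- function(x, ...) {
  tibble::tibble(n_support_vectors = x$fit$tot.nSV,
                 n_train = length(x$fit$fitted),
                 cost = x$fit$cost, gamma = x$fit$gamma,
                 n_classes = length(x$levels))
}
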