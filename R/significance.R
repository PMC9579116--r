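#' Permutation-test configuration
#'
#' @param shuffles_per_fold_per_method label-shuffled models trained per fold
#'   and per selection method (default 25); the chance distribution then has
#'   `k * shuffles * 4` entries.
#' @param percentile candidate-collection threshold: features only enter the
#'   per-feature test when they appear in a model whose holdout accuracy
#'   exceeds this percentile of the chance distribution (default 99,
#'   compensating for the four selection methods).
#' @param classifier classifier id for the shuffled models.
#' @return a list of class `perm_config`.
#' @export
perm_config <- function(shuffles_per_fold_per_method = 25L, percentile = 99,
                        classifier = "linear_svm") {
  structure(list(shuffles = as.integer(shuffles_per_fold_per_method),
                 percentile = percentile, classifier = classifier),
            class = "perm_config")
}

selection_methods <- c("filter", "wrapper", "random", "pseudorandom")

#' Holdout performance of the four selections plus the full model
#'
#' Per fold, trains five classifiers — one per selection method and one on
#' all features (the full model, a reference for how decodable the categories
#' are overall) — on the fold's class-balanced non-holdout data and scores
#' them on the untouched holdout examples.
#'
#' @param x numeric feature matrix.
#' @param labels class labels.
#' @param selections list (one entry per fold) as produced by [featscreen()]:
#'   each entry has per-method feature index vectors.
#' @param plan the [make_fold_plan()] plan the selections were built on.
#' @param classifier classifier id.
#' @return a `k x 5` matrix of holdout accuracies with columns
#'   `filter, wrapper, random, pseudorandom, full`.
#' @export
evaluate_selections <- function(x, labels, selections, plan,
                                classifier = "linear_svm") {
  k <- plan$k
  perf <- matrix(NA_real_, k, 5L,
                 dimnames = list(NULL, c(selection_methods, "full")))
  for (f in seq_len(k)) {
    nh <- non_holdout(plan, f)
    tr <- balanced_subsample(nh, labels)
    te <- plan$holdout[[f]]
    for (m in selection_methods)
      perf[f, m] <- fit_accuracy(x, labels, selections[[f]][[m]], tr, te,
                                 classifier)
    perf[f, "full"] <- fit_accuracy(x, labels, seq_len(ncol(x)), tr, te,
                                    classifier)
  }
  perf
}

#' Build the label-permutation chance distribution
#'
#' For each fold and each method's feature selection,
#' `shuffles_per_fold_per_method` models are trained and tested under freshly
#' shuffled category labels: the labels of the fold's training and holdout
#' examples are permuted jointly, the model is trained on the permuted
#' training labels and scored against the permuted holdout labels. (Scoring
#' against *true* holdout labels would make the null bimodal on strongly
#' clustered data, since a chance model can align with the cluster boundary.)
#' The pooled `k * shuffles * 4` accuracies form the chance distribution of
#' the screening procedure.
#'
#' @inheritParams evaluate_selections
#' @param cfg a [perm_config()].
#' @return numeric vector of chance accuracies with attributes `fold` and
#'   `method` recording each entry's provenance.
#' @export
build_null_distribution <- function(x, labels, selections, plan,
                                    cfg = perm_config()) {
  k <- plan$k
  S <- cfg$shuffles
  acc <- numeric(0); fold_id <- integer(0); meth_id <- character(0)
  for (f in seq_len(k)) {
    nh <- non_holdout(plan, f)
    tr <- balanced_subsample(nh, labels)
    te <- plan$holdout[[f]]
    for (m in selection_methods) {
      sel <- selections[[f]][[m]]
      a <- vapply(seq_len(S), function(s) {
        perm <- sample(labels[c(tr, te)])
        fit_accuracy(x, labels, sel, tr, te, cfg$classifier,
                     y_train = perm[seq_along(tr)],
                     y_test = perm[length(tr) + seq_along(te)])
      }, 0)
      acc <- c(acc, a)
      fold_id <- c(fold_id, rep(f, S))
      meth_id <- c(meth_id, rep(m, S))
    }
  }
  attr(acc, "fold") <- fold_id
  attr(acc, "method") <- meth_id
  acc
}

#' Permutation probability of each selection method
#'
#' For every method, the fold-mean holdout accuracy is referred to the chance
#' distribution: `p = (b + 1) / (B + 1)` where `b` counts chance values at or
#' above the observed mean (the add-one convention avoids zero p-values).
#'
#' @param method_performance matrix from [evaluate_selections()].
#' @param null_distribution vector from [build_null_distribution()].
#' @return named numeric vector of p-values (one per performance column).
#' @export
method_significance <- function(method_performance, null_distribution) {
  B <- length(null_distribution)
  vapply(colnames(method_performance), function(m) {
    obs <- mean(method_performance[, m])
    (sum(null_distribution >= obs) + 1) / (B + 1)
  }, 0)
}

#' Flag individually relevant features
#'
#' Two-stage criterion. (1) Candidate collection: a feature qualifies only if
#' it appeared in at least one evaluated model whose holdout accuracy exceeds
#' the `percentile`-th percentile of the chance distribution. (2)
#' Regression-to-the-mean control: for a feature used `m` times, a control
#' distribution is built by resampling `length(null)` averages of `m` chance
#' values; the feature is flagged when its mean associated accuracy exceeds
#' the *maximum* of that control distribution. A feature used once therefore
#' has to beat the raw chance maximum, while consistently re-selected
#' features face the appropriately contracted criterion for means.
#'
#' @param feature_stats data.frame with per-feature `usage`, `mean_perf`,
#'   `max_perf` (appearances in the four evaluated selections across folds).
#' @param null_distribution vector from [build_null_distribution()].
#' @param cfg a [perm_config()].
#' @return `feature_stats` with columns `candidate`, `criterion` (the control
#'   maximum each feature had to exceed) and `relevant` appended.
#' @export
feature_significance <- function(feature_stats, null_distribution,
                                 cfg = perm_config()) {
  B <- length(null_distribution)
  thr <- stats::quantile(null_distribution, cfg$percentile / 100, names = FALSE)
  feature_stats$candidate <- feature_stats$usage > 0 &
    feature_stats$max_perf > thr
  feature_stats$criterion <- NA_real_
  feature_stats$relevant <- FALSE
  for (m in sort(unique(feature_stats$usage[feature_stats$candidate]))) {
    cmax <- if (m == 1L) max(null_distribution) else
      max(colMeans(matrix(sample(null_distribution, B * m, replace = TRUE),
                          nrow = m)))
    rows <- feature_stats$candidate & feature_stats$usage == m
    feature_stats$criterion[rows] <- cmax
    feature_stats$relevant[rows] <- feature_stats$mean_perf[rows] > cmax
  }
  feature_stats
}

#' Search for feature pairs with super-additive performance
#'
#' For every unordered pair of relevant features, cross-validated accuracy of
#' the pair is compared with the first feature alone; pairs whose combined
#' accuracy exceeds the mean of all tested combinations by more than two
#' standard deviations are flagged. Pairs are tested in isolation (no other
#' features present).
#'
#' @param x numeric feature matrix.
#' @param labels class labels.
#' @param relevant integer indices of relevant features (from
#'   [feature_significance()]).
#' @param plan a [make_fold_plan()] plan.
#' @param classifier classifier id.
#' @return data.frame with one row per pair: the two feature indices, the
#'   pair's cross-validated accuracy, each member's solo accuracy, and a
#'   `flagged` indicator; empty when fewer than 2 relevant features exist.
#' @export
find_feature_combinations <- function(x, labels, relevant, plan,
                                      classifier = "linear_svm") {
  empty <- data.frame(feature_a = integer(0), feature_b = integer(0),
                      acc_pair = numeric(0), acc_a = numeric(0),
                      acc_b = numeric(0), flagged = logical(0))
  if (length(relevant) < 2L) return(empty)
  cv_acc <- function(sel) {
    mean(vapply(seq_len(plan$k), function(f) {
      tr <- balanced_subsample(non_holdout(plan, f), labels)
      fit_accuracy(x, labels, sel, tr, plan$holdout[[f]], classifier)
    }, 0))
  }
  solo <- vapply(relevant, function(i) cv_acc(i), 0)
  names(solo) <- relevant
  pr <- utils::combn(relevant, 2L)
  acc_pair <- vapply(seq_len(ncol(pr)), function(p) cv_acc(pr[, p]), 0)
  out <- data.frame(feature_a = pr[1L, ], feature_b = pr[2L, ],
                    acc_pair = acc_pair,
                    acc_a = solo[as.character(pr[1L, ])],
                    acc_b = solo[as.character(pr[2L, ])])
  out$flagged <- acc_pair > mean(acc_pair) + 2 * stats::sd(acc_pair)
  if (all(is.na(out$flagged))) out$flagged <- FALSE
  rownames(out) <- NULL
  out
}
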