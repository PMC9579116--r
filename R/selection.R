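#' Wrapper (stepwise inclusion) configuration
#'
#' @param search_space_factor the wrapper only searches the top
#'   `search_space_factor * target_size` ranked features (default 2).
#' @param include_fraction per-iteration inclusion cap, as a fraction of the
#'   target feature count (default 0.25).
#' @param prune_trigger fraction of the target size at which the one-off
#'   pruning pass runs (default 0.75).
#' @param repeats number of fresh training/validation splits over which each
#'   candidate's performance change is averaged (default 4).
#' @param classifier inner classifier id (see [classifier_fit()]); the
#'   wrapper's scoring classifier need not equal the final one.
#' @return a list of class `wrapper_config`.
#' @export
wrapper_config <- function(search_space_factor = 2, include_fraction = 0.25,
                           prune_trigger = 0.75, repeats = 4L,
                           classifier = "linear_svm") {
  if (search_space_factor < 1) stop("search_space_factor must be >= 1")
  if (include_fraction <= 0 || include_fraction > 1)
    stop("include_fraction must be in (0, 1]")
  if (prune_trigger <= 0 || prune_trigger >= 1)
    stop("prune_trigger must be in (0, 1)")
  if (repeats < 1L) stop("repeats must be >= 1")
  structure(list(search_space_factor = search_space_factor,
                 include_fraction = include_fraction,
                 prune_trigger = prune_trigger, repeats = as.integer(repeats),
                 classifier = classifier), class = "wrapper_config")
}

cluster_features <- function(clusters, ids) {
  if (length(ids) == 0L) return(integer(0))
  sort(unlist(clusters$clusters[ids], use.names = FALSE))
}

#' Filter feature selection
#'
#' Selects every feature cluster whose best member reaches `p < alpha` on the
#' fold's Kruskal-Wallis ranking. If no cluster passes, a fallback picks a
#' prefix of the ranking instead: candidate prefix lengths (`n_grid`) are
#' scored by inner 5-fold cross-validated accuracy on the fold's non-holdout
#' data and the best (smallest on ties) is used — the selection is then still
#' a set of monotonically decreasing chi-square scores.
#'
#' @param x numeric matrix of feature values (examples x features).
#' @param labels class labels.
#' @param ranking a [rank_features()] result for this fold.
#' @param clusters a [cluster_correlated()] result for this fold.
#' @param plan a [make_fold_plan()] plan.
#' @param fold fold index.
#' @param alpha cluster admission threshold on the Kruskal-Wallis p-value
#'   (default 0.01).
#' @param classifier classifier id used by the fallback's inner CV.
#' @param n_grid prefix lengths tried by the fallback.
#' @return list with `cluster_ids`, `target_size` (total feature count, which
#'   sets the size of all other selections), and `fallback`.
#' @export
filter_select <- function(x, labels, ranking, clusters, plan, fold,
                          alpha = 0.01, classifier = "linear_svm",
                          n_grid = c(1L, 2L, 3L, 5L, 8L, 13L, 21L, 34L, 55L)) {
  if (nrow(x) == 0L || ncol(x) == 0L) stop("empty feature matrix")
  cl_p <- vapply(clusters$clusters, function(m) min(ranking$p_value[m]), 0)
  ids <- which(cl_p < alpha)
  fallback <- FALSE
  if (length(ids) == 0L) {
    fallback <- TRUE
    nh <- non_holdout(plan, fold)
    n_grid <- unique(pmin(n_grid, ncol(x)))
    acc <- vapply(n_grid, function(n) {
      sel <- ranking$order[seq_len(n)]
      inner_cv_accuracy(x, labels, sel, nh, classifier)
    }, 0)
    acc[!is.finite(acc)] <- -Inf
    best <- if (all(acc == -Inf)) n_grid[1L] else
      n_grid[which.max(acc)]         # which.max takes the first (smallest) tie
    ids <- sort(unique(clusters$assignment[ranking$order[seq_len(best)]]))
  }
  list(cluster_ids = ids,
       target_size = length(cluster_features(clusters, ids)),
       fallback = fallback)
}

# stratified 5-fold CV accuracy of a fixed feature subset within `idx`
inner_cv_accuracy <- function(x, labels, sel, idx, classifier = "linear_svm",
                              k = 5L) {
  y <- labels[idx]
  k <- max(2L, min(k, min(table(y))))
  fold_of <- integer(length(idx))
  for (cl in unique(y)) {
    w <- which(y == cl)
    fold_of[sample(w)] <- rep(seq_len(k), length.out = length(w))
  }
  mean(vapply(seq_len(k), function(f) {
    te <- idx[fold_of == f]; tr <- idx[fold_of != f]
    fit_accuracy(x, labels, sel, tr, te, classifier)
  }, 0), na.rm = TRUE)
}

#' Wrapper (stepwise) feature selection
#'
#' Iterative forward inclusion of feature clusters, scored by validation
#' accuracy: at each iteration a reference accuracy is measured for the
#' current selection (1 / #classes when empty), the performance change from
#' adding each candidate cluster of the search space is averaged over
#' `repeats` fresh balanced training/validation splits, and improving
#' clusters (sorted by average gain, ranking order on ties) are admitted up
#' to `include_fraction * target_size` features per iteration. When the
#' selection first exceeds `prune_trigger * target_size` features, each
#' cluster is tested once (largest first) and removed if removal increases
#' performance. The procedure stops at `target_size` features (the filter
#' selection's size) or when no candidate improves.
#'
#' @inheritParams filter_select
#' @param target_size feature-count budget, from [filter_select()].
#' @param cfg a [wrapper_config()].
#' @return list with `cluster_ids` and a provenance `log` (one row per
#'   iteration: reference accuracy, candidates tested, features admitted).
#' @export
wrapper_select <- function(x, labels, plan, fold, ranking, clusters,
                           target_size, cfg = wrapper_config()) {
  if (target_size <= 0L) stop("target_size must be positive")
  n_classes <- length(unique(labels))
  space_n <- min(ceiling(cfg$search_space_factor * target_size), ncol(x))
  space_clusters <- unique(clusters$assignment[ranking$order[seq_len(space_n)]])
  selection <- integer(0)
  pruned <- FALSE
  log <- list()
  budget <- max(1L, floor(cfg$include_fraction * target_size))
  repeat {
    nfeat <- length(cluster_features(clusters, selection))
    if (nfeat >= target_size) break
    cand <- setdiff(space_clusters, selection)
    if (length(cand) == 0L) break
    deltas <- matrix(0, cfg$repeats, length(cand))
    for (r in seq_len(cfg$repeats)) {
      sp <- fresh_training_split(plan, fold)
      sel_f <- cluster_features(clusters, selection)
      ref <- if (length(sel_f) == 0L) 1 / n_classes else
        fit_accuracy(x, labels, sel_f, sp$training, sp$validation,
                     cfg$classifier)
      for (ci in seq_along(cand)) {
        f2 <- cluster_features(clusters, c(selection, cand[ci]))
        deltas[r, ci] <- fit_accuracy(x, labels, f2, sp$training,
                                      sp$validation, cfg$classifier) - ref
      }
    }
    avg <- colMeans(deltas)
    improving <- cand[avg > 0]
    if (length(improving) == 0L) break
    improving <- improving[order(-avg[avg > 0], improving)]
    added <- 0L
    adm <- integer(0)
    for (ci in improving) {
      if (added >= budget ||
          length(cluster_features(clusters, selection)) >= target_size) break
      selection <- c(selection, ci)
      added <- added + length(clusters$clusters[[ci]])
      adm <- c(adm, ci)
    }
    log[[length(log) + 1L]] <- data.frame(
      iteration = length(log) + 1L, candidates = length(cand),
      admitted = length(adm), features = length(cluster_features(clusters, selection)))
    if (!pruned &&
        length(cluster_features(clusters, selection)) >
          cfg$prune_trigger * target_size) {
      pruned <- TRUE
      for (ci in selection[order(-clusters$sizes[selection])]) {
        if (length(selection) <= 1L) break
        sp <- fresh_training_split(plan, fold)
        with_c <- fit_accuracy(x, labels, cluster_features(clusters, selection),
                               sp$training, sp$validation, cfg$classifier)
        without <- fit_accuracy(x, labels,
                                cluster_features(clusters, setdiff(selection, ci)),
                                sp$training, sp$validation, cfg$classifier)
        if (without > with_c) selection <- setdiff(selection, ci)
      }
    }
  }
  list(cluster_ids = selection,
       log = if (length(log)) do.call(rbind, log) else NULL)
}

#' Random feature selection
#'
#' Draws clusters uniformly without replacement until the selected feature
#' count reaches `target_size` (the last admitted cluster may overshoot by
#' its granularity, mirroring the other methods).
#'
#' @param clusters a [cluster_correlated()] result.
#' @param target_size feature-count budget.
#' @param exclude cluster ids to exclude from the draw (used by
#'   [pseudorandom_select()]).
#' @return list with `cluster_ids`.
#' @export
random_select <- function(clusters, target_size, exclude = integer(0)) {
  pool <- setdiff(seq_along(clusters$clusters), exclude)
  total <- sum(clusters$sizes[pool])
  if (target_size > sum(clusters$sizes)) stop("target_size exceeds feature count")
  if (total < target_size) {
    warning("residual pool smaller than target size; selection shrunk to ",
            total, " features")
    return(list(cluster_ids = pool))
  }
  ord <- sample(pool)
  csum <- cumsum(clusters$sizes[ord])
  list(cluster_ids = ord[seq_len(which(csum >= target_size)[1L])])
}

#' Pseudorandom feature selection
#'
#' As [random_select()], but restricted to clusters outside the current
#' filter and wrapper selections — a random draw from the *residual*
#' features. If the residual pool is smaller than the target, the selection
#' shrinks to the pool with a warning.
#'
#' @inheritParams random_select
#' @param excluded cluster ids of the filter and wrapper selections.
#' @return list with `cluster_ids` (disjoint from `excluded`).
#' @export
pseudorandom_select <- function(clusters, excluded, target_size) {
  random_select(clusters, target_size, exclude = excluded)
}
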