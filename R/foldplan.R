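#' Cross-validation configuration
#'
#' @param k number of folds (default 10).
#' @param train_fraction fraction of the non-holdout data used for training
#'   in each pseudo-random balanced split (default 0.5).
#' @param small_data_mode when `TRUE`, instead of a `k`-fold partition, `k`
#'   independent 50/50 train/holdout partitions are drawn — useful when a
#'   1/k holdout would be too small to estimate performance.
#' @param seed optional integer seed recorded in the plan.
#' @return a list of class `cv_config`.
#' @export
cv_config <- function(k = 10L, train_fraction = 0.5, small_data_mode = FALSE,
                      seed = NULL) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  structure(list(k = k, train_fraction = train_fraction,
                 small_data_mode = isTRUE(small_data_mode), seed = seed),
            class = "cv_config")
}

#' Build a k-fold cross-validation plan
#'
#' Stratified assignment: within each class, examples are shuffled and dealt
#' round-robin over the `k` folds, so class ratios survive folding and every
#' example is held out exactly once. In `small_data_mode`, each "fold" is an
#' independent stratified 50/50 train/holdout partition instead.
#'
#' @param labels integer class labels (or a [feature_matrix()], whose labels
#'   are used).
#' @param cfg a [cv_config()].
#' @return an object of class `fold_plan` with the holdout index sets.
#' @export
make_fold_plan <- function(labels, cfg = cv_config()) {
  if (inherits(labels, "feature_matrix")) labels <- labels$labels
  labels <- as.integer(labels)
  n <- length(labels)
  k <- cfg$k
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least 2 classes")
  holdout <- vector("list", k)
  if (cfg$small_data_mode) {
    for (f in seq_len(k)) {
      ho <- integer(0)
      for (cl in classes) {
        idx <- which(labels == cl)
        ho <- c(ho, sample(idx, floor(length(idx) / 2)))
      }
      holdout[[f]] <- sort(ho)
    }
  } else {
    cnt <- table(labels)
    if (any(cnt < k))
      stop("class ", names(cnt)[which.min(cnt)], " has fewer than k = ", k,
           " examples; consider cv_config(small_data_mode = TRUE)")
    fold_of <- integer(n)
    for (cl in classes) {
      idx <- sample(which(labels == cl))
      fold_of[idx] <- rep(seq_len(k), length.out = length(idx))
    }
    for (f in seq_len(k)) holdout[[f]] <- which(fold_of == f)
  }
  structure(list(k = k, holdout = holdout, labels = labels,
                 train_fraction = cfg$train_fraction,
                 small_data_mode = cfg$small_data_mode, n = n),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> k = %d, n = %d%s\n", x$k, x$n,
              if (x$small_data_mode) " (small-data 50/50 mode)" else ""))
  cat("  holdout sizes:", paste(lengths(x$holdout), collapse = " "), "\n")
  invisible(x)
}

#' Non-holdout examples of a fold
#' @param plan a [make_fold_plan()] plan.
#' @param fold fold index in `1..k`.
#' @return integer vector of example indices.
#' @export
non_holdout <- function(plan, fold) {
  setdiff(seq_len(plan$n), plan$holdout[[fold]])
}

#' Draw a fresh balanced training/validation split
#'
#' Each call draws a *new* pseudo-random split of the fold's non-holdout
#' examples: `train_fraction` of the minority-class count is sampled from
#' every class without replacement (so training is exactly class-balanced);
#' all remaining non-holdout examples form the validation set. A fresh split
#' per selection step reduces overfitting to any one split.
#'
#' @inheritParams non_holdout
#' @return `list(training =, validation =)` of example indices.
#' @export
fresh_training_split <- function(plan, fold) {
  nh <- non_holdout(plan, fold)
  balanced_split(nh, plan$labels, plan$train_fraction)
}

balanced_split <- function(idx, labels, fraction) {
  cnt <- table(labels[idx])
  ntr <- floor(fraction * min(cnt))
  if (ntr < 1L) stop("not enough examples for a balanced training split")
  tr <- unlist(lapply(sort(unique(labels[idx])), function(cl)
    sample(idx[labels[idx] == cl], ntr)), use.names = FALSE)
  list(training = sort(tr), validation = sort(setdiff(idx, tr)))
}

# class-balanced subsample (min class count from each class), used when
# training evaluation models on all non-holdout data
balanced_subsample <- function(idx, labels) {
  cnt <- table(labels[idx])
  m <- min(cnt)
  sort(unlist(lapply(sort(unique(labels[idx])), function(cl) {
    pool <- idx[labels[idx] == cl]
    if (length(pool) == m) pool else sample(pool, m)
  }), use.names = FALSE))
}
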