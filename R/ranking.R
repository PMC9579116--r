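#' Univariate feature ranking by Kruskal-Wallis
#'
#' Scores every feature by the Kruskal-Wallis H statistic (the rank-based
#' analysis-of-variance chi-square score) for differences between categories,
#' computed on a given example subset only. Mid-rank ties with the standard
#' tie correction; a constant feature gets `H = 0`, `p = 1`.
#'
#' @param fm a [feature_matrix()] (or plain numeric matrix).
#' @param labels class labels; taken from `fm` when omitted.
#' @param subset integer vector of example indices to score on (default all).
#' @return a list of class `feature_ranking`: `statistic` and `p_value` per
#'   feature, and `order` (feature indices by decreasing statistic).
#' @export
rank_features <- function(fm, labels = NULL, subset = NULL) {
  x <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
  if (is.null(labels)) labels <- fm$labels
  if (is.null(subset)) subset <- seq_len(nrow(x))
  x <- x[subset, , drop = FALSE]
  y <- labels[subset]
  if (length(unique(y)) < 2L) stop("subset must contain at least 2 classes")
  n <- nrow(x)
  g <- sort(unique(y))
  ng <- vapply(g, function(cl) sum(y == cl), 0L)
  H <- vapply(seq_len(ncol(x)), function(j) {
    xj <- x[, j]
    r <- rank(xj)
    s <- vapply(g, function(cl) sum(r[y == cl]), 0)
    h <- 12 / (n * (n + 1)) * sum(s^2 / ng) - 3 * (n + 1)
    if (anyDuplicated(xj)) {
      ties <- tabulate(match(xj, xj))
      corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
      if (corr <= 0) 0 else h / corr
    } else h
  }, 0)
  H[H < 0] <- 0
  p <- stats::pchisq(H, df = length(g) - 1L, lower.tail = FALSE)
  structure(list(statistic = H, p_value = p,
                 order = order(H, decreasing = TRUE)),
            class = "feature_ranking")
}

#' Group correlated features into clusters
#'
#' Greedy seeded clustering: walking the ranking from the top, each
#' still-unassigned feature seeds a cluster and absorbs every unassigned
#' feature whose squared Pearson correlation with the seed (on the given
#' example subset) reaches `r2_threshold` — i.e. features that explain at
#' least that fraction of each other's variance. Membership is judged against
#' the seed only (not all members). Link groups are absorbed atomically:
#' when any member of a link group joins a cluster, the whole group does.
#'
#' @inheritParams rank_features
#' @param ranking a [rank_features()] result computed on the same subset.
#' @param r2_threshold shared-variance criterion (default 0.25).
#' @param link_groups per-feature link-group ids; taken from `fm` when it is
#'   a [feature_matrix()].
#' @return a list of class `feature_clusters`: `clusters` (list of feature
#'   index vectors, one per cluster, in seed-rank order), `assignment`
#'   (cluster id per feature), `sizes`, and `r2_threshold`.
#' @export
cluster_correlated <- function(fm, ranking, subset = NULL, r2_threshold = 0.25,
                               link_groups = NULL) {
  x <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
  if (is.null(link_groups))
    link_groups <- if (inherits(fm, "feature_matrix")) fm$link_groups
                   else seq_len(ncol(x))
  if (is.null(subset)) subset <- seq_len(nrow(x))
  x <- x[subset, , drop = FALSE]
  nf <- ncol(x)
  # standardize once; constant features get 0 columns (correlate with nothing)
  mu <- colMeans(x)
  z <- sweep(x, 2L, mu)
  ss <- sqrt(colSums(z^2))
  ok <- ss > 0
  z[, ok] <- sweep(z[, ok, drop = FALSE], 2L, ss[ok], "/")
  z[, !ok] <- 0
  assignment <- integer(nf)
  clusters <- list()
  for (j in ranking$order) {
    if (assignment[j] != 0L) next
    cid <- length(clusters) + 1L
    r2 <- as.numeric(crossprod(z, z[, j]))^2
    members <- which(assignment == 0L & (r2 >= r2_threshold | seq_len(nf) == j))
    # absorb whole link groups of any member
    members <- which(link_groups %in% link_groups[members] & assignment == 0L)
    assignment[members] <- cid
    clusters[[cid]] <- members
  }
  structure(list(clusters = clusters, assignment = assignment,
                 sizes = lengths(clusters), r2_threshold = r2_threshold),
            class = "feature_clusters")
}
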