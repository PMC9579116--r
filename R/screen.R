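#' Screen image features for category information
#'
#' The package's main fitting function. Given a feature matrix (or any
#' numeric matrix plus labels), it runs the full cross-validated screening
#' pipeline:
#'
#' 1. a stratified `k`-fold plan is built;
#' 2. per fold, features are ranked by Kruskal-Wallis score and correlated
#'    features are clustered (`r2 >= r2_threshold` against the cluster seed)
#'    on the fold's ranking basis (a balanced training split by default);
#' 3. four equal-size selections are formed — filter (`p < alpha`), wrapper
#'    (stepwise inclusion), random, and pseudorandom (random among features
#'    untouched by filter and wrapper);
#' 4. each selection plus the full feature set is trained on the balanced
#'    non-holdout data and scored on the holdout fold;
#' 5. a label-permutation chance distribution (`k * shuffles * 4` values)
#'    yields per-method p-values and, with a regression-to-the-mean-corrected
#'    control, per-feature relevance flags.
#'
#' @param x a [feature_matrix()] or numeric matrix (examples x features).
#' @param labels class labels (ignored when `x` is a feature matrix).
#' @param k number of cross-validation folds (default 10).
#' @param alpha filter threshold on the Kruskal-Wallis p-value (default 0.01).
#' @param r2_threshold shared-variance clustering criterion (default 0.25).
#' @param cv a [cv_config()]; overrides `k` when supplied.
#' @param wrapper a [wrapper_config()].
#' @param perm a [perm_config()].
#' @param classifier classifier id for the evaluated models (default
#'   `"linear_svm"`; see [classifier_fit()]).
#' @param ranking_data basis for ranking, clustering and the filter test:
#'   `"training"` (a fresh balanced training split of the fold, the default)
#'   or `"nonholdout"` (all `k - 1` remaining folds).
#' @param plan optionally, a pre-built [make_fold_plan()] plan (so other
#'   selectors can share the exact same folding); built from `cv` otherwise.
#' @param seed integer root seed; all fold-level randomness flows from
#'   per-fold substreams derived from it, so results are reproducible and
#'   independent of fold execution order.
#' @param verbose print per-fold progress lines.
#' @return An object of class `featscreen`: per-fold selections, the
#'   `k x 5` holdout performance matrix, the chance distribution, per-method
#'   p-values, the per-feature statistics table (usage, mean associated
#'   accuracy, criterion, relevance flag), and the configuration snapshot.
#' @seealso [summary.featscreen()], [weight_map()], [run_benchmark()]
#' @examples
#' sim <- generate_mock_dataset(mock_spec(n_features = 40, n_per_class = 30,
#'                                        n_relevant = 5), seed = 1)
#' fit <- featscreen(sim$features, k = 5, seed = 1)
#' print(fit)
#' @export
featscreen <- function(x, labels = NULL, k = 10L, alpha = 0.01,
                       r2_threshold = 0.25, cv = NULL,
                       wrapper = wrapper_config(), perm = perm_config(),
                       classifier = "linear_svm",
                       ranking_data = c("training", "nonholdout"),
                       plan = NULL, seed = 1L, verbose = FALSE) {
  ranking_data <- match.arg(ranking_data)
  fm <- NULL
  if (inherits(x, "feature_matrix")) {
    fm <- x
    labels <- x$labels
    x <- x$values
    link_groups <- fm$link_groups
  } else {
    x <- as.matrix(x)
    link_groups <- seq_len(ncol(x))
  }
  if (is.null(labels)) stop("labels are required")
  if (is.null(cv)) cv <- cv_config(k = k)
  set.seed(seed)
  if (is.null(plan)) plan <- make_fold_plan(labels, cv)
  k <- plan$k
  fold_seeds <- sample.int(.Machine$integer.max - 1L, k)
  sig_seed <- sample.int(.Machine$integer.max - 1L, 1L)
  wrapper$classifier <- classifier
  perm$classifier <- classifier

  selections <- vector("list", k)
  for (f in seq_len(k)) {
    set.seed(fold_seeds[f])
    basis <- if (ranking_data == "training")
      fresh_training_split(plan, f)$training else non_holdout(plan, f)
    ranking <- rank_features(x, labels, basis)
    clusters <- cluster_correlated(x, ranking, basis, r2_threshold,
                                   link_groups)
    filt <- filter_select(x, labels, ranking, clusters, plan, f, alpha,
                          classifier)
    wrap <- wrapper_select(x, labels, plan, f, ranking, clusters,
                           filt$target_size, wrapper)
    rnd <- random_select(clusters, filt$target_size)
    pse <- pseudorandom_select(clusters,
                               union(filt$cluster_ids, wrap$cluster_ids),
                               filt$target_size)
    selections[[f]] <- list(
      filter = cluster_features(clusters, filt$cluster_ids),
      wrapper = cluster_features(clusters, wrap$cluster_ids),
      random = cluster_features(clusters, rnd$cluster_ids),
      pseudorandom = cluster_features(clusters, pse$cluster_ids),
      target_size = filt$target_size, fallback = filt$fallback,
      wrapper_log = wrap$log, clusters = clusters$clusters)
    if (verbose)
      message(sprintf("fold %d/%d: target %d features%s", f, k,
                      filt$target_size,
                      if (filt$fallback) " (filter fallback)" else ""))
  }

  set.seed(sig_seed)
  perf <- evaluate_selections(x, labels, selections, plan, classifier)
  null <- build_null_distribution(x, labels, selections, plan, perm)
  p <- method_significance(perf, null)
  stats <- tally_feature_stats(selections, perf, ncol(x))
  stats <- feature_significance(stats, null, perm)
  if (!is.null(fm)) {
    stats$name <- feature_names(fm)
    stats$space <- fm$meta$space
  }
  structure(list(
    call = match.call(), n = nrow(x), n_features = ncol(x), labels = labels,
    plan = plan, selections = selections, method_performance = perf,
    null_distribution = null, method_p = p, feature_stats = stats,
    feature_meta = if (!is.null(fm)) fm$meta else NULL,
    sources = if (!is.null(fm)) fm$sources else NULL,
    config = list(k = k, alpha = alpha, r2_threshold = r2_threshold,
                  cv = cv, wrapper = wrapper, perm = perm,
                  classifier = classifier, ranking_data = ranking_data,
                  seed = seed)), class = "featscreen")
}

# per-feature usage / mean / max holdout accuracy over the evaluated
# (non-permuted) models of the four selection methods; the full model is a
# reference and does not enter feature-level accounting
tally_feature_stats <- function(selections, perf, n_features) {
  usage <- integer(n_features)
  s <- numeric(n_features)
  mx <- rep(-Inf, n_features)
  for (f in seq_along(selections)) {
    for (m in selection_methods) {
      sel <- selections[[f]][[m]]
      usage[sel] <- usage[sel] + 1L
      s[sel] <- s[sel] + perf[f, m]
      mx[sel] <- pmax(mx[sel], perf[f, m])
    }
  }
  data.frame(feature = seq_len(n_features), usage = usage,
             mean_perf = ifelse(usage > 0, s / pmax(usage, 1L), NA_real_),
             max_perf = ifelse(usage > 0, mx, NA_real_))
}

#' Relevant features of a screen
#' @param fit a [featscreen()] result.
#' @return integer indices of the flagged features.
#' @export
relevant_features <- function(fit) {
  fit$feature_stats$feature[fit$feature_stats$relevant]
}

#' @export
print.featscreen <- function(x, ...) {
  cat(sprintf("Feature screen: %d examples, %d features, %d classes, k = %d\n",
              x$n, x$n_features, length(unique(x$labels)), x$config$k))
  perf <- colMeans(x$method_performance)
  cat("Holdout accuracy (fold mean) and permutation p:\n")
  for (m in names(perf))
    cat(sprintf("  %-13s %.3f  p = %.4g\n", m, perf[m], x$method_p[m]))
  cat(sprintf("Chance distribution: %d values (max %.3f)\n",
              length(x$null_distribution), max(x$null_distribution)))
  nr <- sum(x$feature_stats$relevant)
  cat(sprintf("Relevant features: %d\n", nr))
  invisible(x)
}

#' Summarize a feature screen
#'
#' @param object a [featscreen()] result.
#' @param ... unused.
#' @return a list of class `summary.featscreen` with the per-method
#'   performance table and the relevant-feature table.
#' @export
summary.featscreen <- function(object, ...) {
  perf <- data.frame(method = colnames(object$method_performance),
                     accuracy = colMeans(object$method_performance),
                     sd = apply(object$method_performance, 2L, stats::sd),
                     p = object$method_p[colnames(object$method_performance)],
                     row.names = NULL)
  rel <- object$feature_stats[object$feature_stats$relevant, , drop = FALSE]
  rel <- rel[order(-rel$mean_perf), ]
  structure(list(performance = perf, relevant = rel,
                 n = object$n, k = object$config$k,
                 n_features = object$n_features), class = "summary.featscreen")
}

#' @export
print.summary.featscreen <- function(x, ...) {
  cat(sprintf("Feature screen of %d examples x %d features (k = %d)\n\n",
              x$n, x$n_features, x$k))
  print(x$performance, digits = 3, row.names = FALSE)
  cat(sprintf("\n%d relevant feature(s)\n", nrow(x$relevant)))
  if (nrow(x$relevant)) print(utils::head(x$relevant, 20L), digits = 3,
                              row.names = FALSE)
  invisible(x)
}

#' Relevant-feature table of a screen
#'
#' @param object a [featscreen()] result.
#' @param ... unused.
#' @return data.frame of flagged features with usage, mean associated
#'   accuracy and the criterion each exceeded.
#' @export
coef.featscreen <- function(object, ...) {
  object$feature_stats[object$feature_stats$relevant, , drop = FALSE]
}

#' Plot a feature screen
#'
#' With spatial feature metadata available, draws the weight map of the
#' requested feature space ([weight_map()]); otherwise plots per-method
#' holdout accuracy against the chance distribution.
#'
#' @param x a [featscreen()] result.
#' @param space feature-space id to map (default: first spatial space
#'   present).
#' @param ... passed to [graphics::image()].
#' @export
plot.featscreen <- function(x, space = NULL, ...) {
  spatial <- c("hog", "pixel", "fourier_phase", "fourier_mag")
  have <- if (!is.null(x$feature_meta)) intersect(spatial,
                                                  unique(x$feature_meta$space))
          else character(0)
  if (is.null(space) && length(have)) space <- have[1L]
  if (!is.null(space)) {
    wm <- weight_map(x, space)
    m <- if (length(dim(wm)) == 3L) apply(wm, 1:2, max) else wm
    graphics::image(t(m)[, nrow(m):1], col = grDevices::gray(seq(1, 0, length.out = 64)),
                    axes = FALSE, ...)
    graphics::title(main = paste("weight map:", space))
  } else {
    perf <- colMeans(x$method_performance)
    graphics::barplot(perf, ylim = c(0, 1), ylab = "holdout accuracy")
    graphics::title(main = sprintf("chance max = %.3f",
                                   max(x$null_distribution)))
  }
  invisible(x)
}
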