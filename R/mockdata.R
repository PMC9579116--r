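#' Mock-data simulation parameters
#'
#' Describes the synthetic ground-truth dataset used to validate the
#' screening procedure: `n_features` independent standard-normal features
#' over two classes, constructed as an *exact whole-set null* (both classes
#' receive the identical value multiset per feature, independently shuffled
#' over examples), after which `n_relevant` randomly chosen features get a
#' constant added to every class-1 value — effect sizes linearly spaced from
#' `effect_range[1]` down to `effect_range[2]` SD units.
#'
#' @param n_features total feature count (default 400).
#' @param n_per_class examples per class (default 250).
#' @param n_relevant number of manipulated features (default 25; the
#'   benchmark grid uses 25/50/100).
#' @param effect_range endpoints of the effect-size gradient in SD units
#'   (default `c(0.5, 0.25)`, descending).
#' @param n_iterations benchmark repetitions with fresh data (default 30).
#' @return a list of class `mock_spec`.
#' @export
mock_spec <- function(n_features = 400L, n_per_class = 250L,
                      n_relevant = min(25L, n_features),
                      effect_range = c(0.5, 0.25),
                      n_iterations = 30L) {
  if (n_relevant > n_features) stop("n_relevant must not exceed n_features")
  structure(list(n_features = as.integer(n_features),
                 n_per_class = as.integer(n_per_class),
                 n_relevant = as.integer(n_relevant),
                 effect_range = as.numeric(effect_range),
                 n_iterations = as.integer(n_iterations)),
            class = "mock_spec")
}

#' Generate one mock dataset
#'
#' Implements the exact-null construction of [mock_spec()]: for each feature,
#' `n_per_class` standard-normal values are drawn once and assigned to *both*
#' classes in independently shuffled example orders, so before manipulation
#' every feature's class value multisets are identical (whole-set rank tests
#' are exactly zero); the effect gradient is then added to the class-1 values
#' of `n_relevant` features chosen uniformly at random.
#'
#' @param spec a [mock_spec()].
#' @param seed optional integer seed for this draw.
#' @return list with `features` (a [feature_matrix()], labels 1/2),
#'   `relevant` (manipulated feature indices, in gradient order) and
#'   `deltas` (the per-feature effect sizes).
#' @export
generate_mock_dataset <- function(spec = mock_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_per_class
  vals <- matrix(stats::rnorm(n * spec$n_features), n, spec$n_features)
  x <- rbind(apply(vals, 2L, sample), apply(vals, 2L, sample))
  labels <- rep(1:2, each = n)
  relevant <- sample(spec$n_features, spec$n_relevant)
  deltas <- seq(spec$effect_range[1L], spec$effect_range[2L],
                length.out = spec$n_relevant)
  x[labels == 1L, relevant] <- sweep(x[labels == 1L, relevant, drop = FALSE],
                                     2L, deltas, "+")
  meta <- data.frame(space = "mock", layer = 1L,
                     coord1 = seq_len(spec$n_features),
                     coord2 = NA_integer_, coord3 = NA_integer_)
  list(features = feature_matrix(x, labels, meta), relevant = relevant,
       deltas = deltas)
}

two_sample_t_pvalues <- function(x, labels, idx, var_equal = TRUE) {
  x1 <- x[idx[labels[idx] == 1L], , drop = FALSE]
  x2 <- x[idx[labels[idx] == 2L], , drop = FALSE]
  n1 <- nrow(x1); n2 <- nrow(x2)
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- colSums(sweep(x1, 2L, m1)^2) / (n1 - 1L)
  v2 <- colSums(sweep(x2, 2L, m2)^2) / (n2 - 1L)
  if (var_equal) {
    sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tt <- (m1 - m2) / se
  tt[se == 0] <- 0
  2 * stats::pt(-abs(tt), df)
}

#' Baseline t-test feature selector
#'
#' Two-sample t-tests per feature, run per cross-validation fold on the
#' fold's class-balanced data, with a configurable aggregation rule turning
#' the per-fold significance patterns into a detection count:
#'
#' * `"fold_mean"` (default): each fold suggests its own significant set;
#'   hit/false-alarm counts are averaged over folds. The package uses this as
#'   its benchmark default because, among all the aggregation rules below, it
#'   comes closest to the validation-study detection rates (see the methods
#'   vignette); the rule is an interpretation, not a uniquely defined
#'   procedure.
#' * `"majority"` / `"any"` / `"all"`: one detected set — features
#'   significant in a strict majority / at least one / all of the `k` folds.
#' * `"whole"`: a single test on the full dataset, no folding.
#'
#' @param fm a [feature_matrix()] or numeric matrix.
#' @param labels class labels (two classes).
#' @param plan a [make_fold_plan()] plan (shared with the screening pipeline
#'   so both see the same folding).
#' @param alpha significance criterion (the benchmark uses .05/.01/.001,
#'   uncorrected).
#' @param rule aggregation rule, see above.
#' @param basis data each fold's test runs on: a fresh balanced `"training"`
#'   split (default) or the full `"nonholdout"` remainder.
#' @param var_equal classic equal-variance t-test (default); `FALSE` for
#'   Welch.
#' @return an object of class `ttest_selection`: `per_fold` detected index
#'   sets, `detected` (the aggregated set; `NULL` under `"fold_mean"`), and
#'   the settings.
#' @export
ttest_select <- function(fm, labels = NULL, plan, alpha = 0.05,
                         rule = c("fold_mean", "majority", "any", "all",
                                  "whole"),
                         basis = c("training", "nonholdout"),
                         var_equal = TRUE) {
  rule <- match.arg(rule)
  basis <- match.arg(basis)
  x <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
  if (is.null(labels)) labels <- fm$labels
  if (rule == "whole") {
    p <- two_sample_t_pvalues(x, labels, seq_len(nrow(x)), var_equal)
    det <- which(p < alpha)
    return(structure(list(per_fold = list(det), detected = det, alpha = alpha,
                          rule = rule, basis = basis),
                     class = "ttest_selection"))
  }
  per_fold <- vector("list", plan$k)
  for (f in seq_len(plan$k)) {
    idx <- if (basis == "training") fresh_training_split(plan, f)$training
           else balanced_subsample(non_holdout(plan, f), labels)
    p <- two_sample_t_pvalues(x, labels, idx, var_equal)
    per_fold[[f]] <- which(p < alpha)
  }
  counts <- tabulate(unlist(per_fold), nbins = ncol(x))
  detected <- switch(rule,
    fold_mean = NULL,
    majority = which(counts > plan$k / 2),
    any = which(counts >= 1L),
    all = which(counts == plan$k))
  structure(list(per_fold = per_fold, detected = detected, alpha = alpha,
                 rule = rule, basis = basis), class = "ttest_selection")
}

#' Score a detection against the ground truth
#'
#' @param detection a `ttest_selection`, or an integer vector of detected
#'   feature indices.
#' @param relevant indices of the truly manipulated features.
#' @return `c(hits =, fa =)`; under the `"fold_mean"` rule these are per-fold
#'   averages, otherwise counts for the single detected set.
#' @export
score_detection <- function(detection, relevant) {
  count <- function(det) c(hits = length(intersect(det, relevant)),
                           fa = length(setdiff(det, relevant)))
  if (inherits(detection, "ttest_selection")) {
    if (is.null(detection$detected))
      return(rowMeans(vapply(detection$per_fold, count, c(hits = 0, fa = 0))))
    return(count(detection$detected))
  }
  count(detection)
}

#' Run the mock-data benchmark
#'
#' For every condition (number of manipulated features) and iteration, a
#' fresh mock dataset is generated and every requested method is run on the
#' same data and the same folding: the full screening pipeline (method
#' `"screen"`, whose detections are its flagged relevant features) and/or the
#' t-test baselines at .05/.01/.001. Hits are detections among the
#' manipulated features; false alarms (FA) are detections outside them.
#'
#' @param conditions values of `n_relevant` to simulate (default
#'   `c(25, 50, 100)`).
#' @param iterations fresh datasets per condition (default
#'   `spec$n_iterations`).
#' @param methods subset of `"screen"`, `"ttest_0.05"`, `"ttest_0.01"`,
#'   `"ttest_0.001"`.
#' @param spec a [mock_spec()] (its `n_relevant` is overridden per
#'   condition).
#' @param k folds (default 10).
#' @param seed root seed; per-iteration seeds are derived from it.
#' @param ttest_rule aggregation rule for the baselines (see
#'   [ttest_select()]).
#' @param screen_args named list of extra arguments for [featscreen()].
#' @param verbose print one line per iteration.
#' @return an object of class `fs_benchmark`: `results` (one row per
#'   condition x iteration x method with hits, FA and percent found),
#'   `table` (condition x method means), and `overall` (per-method mean
#'   percent found with SD).
#' @export
run_benchmark <- function(conditions = c(25L, 50L, 100L), iterations = NULL,
                          methods = c("screen", "ttest_0.05", "ttest_0.01",
                                      "ttest_0.001"),
                          spec = mock_spec(), k = 10L, seed = 1L,
                          ttest_rule = "fold_mean", screen_args = list(),
                          verbose = FALSE) {
  if (is.null(iterations)) iterations <- spec$n_iterations
  if (any(conditions > spec$n_features))
    stop("conditions must not exceed n_features")
  alphas <- c("ttest_0.05" = 0.05, "ttest_0.01" = 0.01, "ttest_0.001" = 0.001)
  set.seed(seed)
  iter_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                  length(conditions) * iterations),
                       length(conditions), iterations)
  rows <- list()
  for (ci in seq_along(conditions)) {
    cond_spec <- spec
    cond_spec$n_relevant <- as.integer(conditions[ci])
    for (it in seq_len(iterations)) {
      s <- iter_seeds[ci, it]
      sim <- generate_mock_dataset(cond_spec, seed = s)
      set.seed(s + 1L)
      plan <- make_fold_plan(sim$features$labels, cv_config(k = k))
      for (m in methods) {
        if (m == "screen") {
          args <- c(list(x = sim$features, plan = plan, seed = s + 2L),
                    screen_args)
          fit <- do.call(featscreen, args)
          sc <- score_detection(relevant_features(fit), sim$relevant)
        } else {
          set.seed(s + 3L)
          det <- ttest_select(sim$features, plan = plan, alpha = alphas[[m]],
                              rule = ttest_rule)
          sc <- score_detection(det, sim$relevant)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          condition = conditions[ci], iteration = it, method = m,
          hits = sc[["hits"]], fa = sc[["fa"]],
          pct = 100 * sc[["hits"]] / conditions[ci])
        if (verbose)
          message(sprintf("n_relevant=%d it=%d %s: hits=%.2f fa=%.2f",
                          conditions[ci], it, m, sc[["hits"]], sc[["fa"]]))
      }
    }
  }
  results <- do.call(rbind, rows)
  tab <- stats::aggregate(cbind(hits, fa, pct) ~ condition + method, results,
                          mean)
  overall <- do.call(rbind, lapply(split(results, results$method), function(d)
    data.frame(method = d$method[1L], mean_pct = mean(d$pct),
               sd_pct = stats::sd(d$pct))))
  rownames(overall) <- NULL
  structure(list(results = results, table = tab, overall = overall,
                 conditions = conditions, iterations = iterations,
                 seed = seed), class = "fs_benchmark")
}

#' @export
print.fs_benchmark <- function(x, ...) {
  cat(sprintf("Mock-data benchmark: %d iteration(s) x conditions {%s}\n",
              x$iterations, paste(x$conditions, collapse = ", ")))
  tab <- x$table
  tab$hits <- round(tab$hits, 2); tab$fa <- round(tab$fa, 2)
  tab$pct <- round(tab$pct, 1)
  print(tab, row.names = FALSE)
  cat("\nOverall percent of manipulated features found:\n")
  ov <- x$overall
  ov$mean_pct <- round(ov$mean_pct, 2); ov$sd_pct <- round(ov$sd_pct, 2)
  print(ov, row.names = FALSE)
  invisible(x)
}
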