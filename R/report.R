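#' Write a methods-section text from a screen's settings
#'
#' Deterministic prose template filled from the configuration snapshot of a
#' [featscreen()] fit (or a bare config list with the same fields): feature
#' spaces, fold count, classifier, thresholds. Two runs with the same
#' configuration produce byte-identical text.
#'
#' @param fit a [featscreen()] result, or its `$config` list.
#' @param path optional file to write to.
#' @return the text, invisibly when written to `path`.
#' @export
write_methods_text <- function(fit, path = NULL) {
  cfg <- if (inherits(fit, "featscreen")) fit$config else fit
  spaces <- if (inherits(fit, "featscreen") && !is.null(fit$feature_meta))
    paste(unique(fit$feature_meta$space), collapse = ", ") else "supplied"
  cls <- c(linear_svm = "linear support vector machine",
           libsvm = "linear support vector machine (libsvm)")[cfg$classifier]
  txt <- paste0(
    "Feature screening was performed with ", cfg$k, "-fold cross-validation. ",
    "Feature spaces analyzed: ", spaces, ". Per fold, features were ranked ",
    "by the Kruskal-Wallis chi-square score and features explaining at ",
    "least ", round(100 * cfg$r2_threshold), "% of each other's variance ",
    "were clustered and selected together. Four selections were formed per ",
    "fold: a filter selection of all clusters with p < ", cfg$alpha,
    ", a stepwise wrapper selection of equal size scored by validation ",
    "accuracy, and equally sized random and pseudorandom selections. ",
    "Models were trained with a ", cls, " on class-balanced training data ",
    "and cross-validated on the holdout fold. Chance performance was ",
    "estimated from ", cfg$perm$shuffles, " label-shuffled models per fold ",
    "and method (", cfg$k, " x ", cfg$perm$shuffles, " x 4 values). ",
    "Individual features were flagged as relevant when they appeared in a ",
    "model above the ", cfg$perm$percentile, "th percentile of the chance ",
    "distribution and their mean associated accuracy exceeded the maximum ",
    "of a control distribution of equally sized averages resampled from ",
    "the chance distribution (correcting for regression to the mean).")
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

#' Write a results-overview text
#'
#' Per-method fold accuracies and permutation p-values, plus counts of
#' relevant features per feature space.
#'
#' @param fit a [featscreen()] result.
#' @param path optional file to write to.
#' @return the text lines, invisibly when written to `path`.
#' @export
write_results_text <- function(fit, path = NULL) {
  perf <- fit$method_performance
  lines <- c(sprintf("Feature screen of %d examples x %d features (k = %d).",
                     fit$n, fit$n_features, fit$config$k),
             "", "Holdout accuracy per fold:")
  for (m in colnames(perf))
    lines <- c(lines, sprintf("  %-13s %s  (mean %.3f, p = %.4g)", m,
                              paste(sprintf("%.2f", perf[, m]), collapse = " "),
                              mean(perf[, m]), fit$method_p[m]))
  rel <- fit$feature_stats[fit$feature_stats$relevant, , drop = FALSE]
  lines <- c(lines, "", sprintf("Relevant features: %d", nrow(rel)))
  if (nrow(rel) > 0L && "space" %in% names(rel)) {
    per_space <- table(rel$space)
    for (s in names(per_space))
      lines <- c(lines, sprintf("  %-13s %d", s, per_space[[s]]))
  }
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}

#' Write the significant-feature covariate table
#'
#' One row per image: its source filename, then its value on every relevant
#' feature — directly usable as covariates in a follow-up analysis of
#' behavioral or neural responses to the images.
#'
#' @param fm the [feature_matrix()] the screen was fitted on.
#' @param fit the [featscreen()] result.
#' @param path CSV output path.
#' @return the written data.frame, invisibly.
#' @export
write_feature_table <- function(fm, fit, path) {
  rel <- relevant_features(fit)
  if (length(rel) == 0L)
    warning("no relevant features; writing header-only table")
  d <- data.frame(filename = fm$sources)
  for (j in rel) d[[feature_names(fm)[j]]] <- fm$values[, j]
  write.csv(d, path, row.names = FALSE)
  invisible(d)
}

#' Feature-space weight map
#'
#' Arranges the per-feature mean associated accuracies of the flagged
#' features of one spatially organized feature space on that space's native
#' grid: HOG — cell row x cell column x orientation bin; pixel intensities
#' and Fourier phase — pixel row x column; Fourier magnitudes — spatial
#' frequency band x orientation band. Non-flagged positions hold the
#' background value.
#'
#' @param fit a [featscreen()] result fitted on a [feature_matrix()] with
#'   metadata.
#' @param space one of `"hog"`, `"pixel"`, `"fourier_phase"`,
#'   `"fourier_mag"`.
#' @param layer image layer to map (default 1).
#' @param background value for non-flagged positions (default `NA`).
#' @return a numeric matrix (or 3-D array for HOG).
#' @export
weight_map <- function(fit, space, layer = 1L, background = NA_real_) {
  if (is.null(fit$feature_meta)) stop("fit has no feature metadata")
  spatial <- c("hog", "pixel", "fourier_phase", "fourier_mag")
  if (!space %in% spatial)
    stop("feature space '", space, "' has no spatial/band layout; ",
         "use the tabular feature report instead")
  meta <- fit$feature_meta
  sel <- which(meta$space == space & meta$layer == layer)
  if (length(sel) == 0L) stop("no features of space '", space, "' in this fit")
  m <- meta[sel, ]
  st <- fit$feature_stats[sel, ]
  val <- ifelse(st$relevant, st$mean_perf, background)
  if (space == "hog") {
    out <- array(background, c(max(m$coord1), max(m$coord2), max(m$coord3)))
    out[cbind(m$coord1, m$coord2, m$coord3)] <- val
  } else {
    out <- matrix(background, max(m$coord1), max(m$coord2))
    out[cbind(m$coord1, m$coord2)] <- val
  }
  out
}
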