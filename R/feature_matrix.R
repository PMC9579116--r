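#' Construct a feature matrix
#'
#' The central container of the package: an examples-by-features numeric
#' matrix with per-example category labels, per-feature provenance metadata,
#' and link groups. Features sharing a link-group id are always selected
#' together (e.g. corresponding positions in different color layers, or a
#' phase/magnitude pair).
#'
#' @param values numeric matrix, one row per example, one column per feature.
#' @param labels integer vector of positive category labels, one per example.
#' @param meta `data.frame` with one row per feature. Must contain a `space`
#'   column (feature-space id); extractor functions add `layer` and
#'   coordinate columns (`coord1`, `coord2`, `coord3`). Defaults to a
#'   single-space "raw" description.
#' @param link_groups integer vector, one per feature; features with equal
#'   values form an atomic selection unit. Defaults to all-singleton.
#' @param sources character vector of per-example provenance (file paths or
#'   `"synthetic:<i>"`).
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, labels, meta = NULL, link_groups = NULL,
                           sources = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  labels <- as.integer(labels)
  if (nrow(values) != length(labels))
    stop("`labels` must have one entry per row of `values`")
  if (anyNA(values)) stop("feature values must not contain missing values")
  if (anyNA(labels) || any(labels < 1L))
    stop("labels must be positive integers")
  nf <- ncol(values)
  if (is.null(meta)) {
    meta <- data.frame(space = rep("raw", nf), layer = 1L,
                       coord1 = seq_len(nf), coord2 = NA_integer_,
                       coord3 = NA_integer_)
  }
  if (nrow(meta) != nf) stop("`meta` must have one row per feature")
  if (is.null(link_groups)) link_groups <- seq_len(nf)
  link_groups <- as.integer(link_groups)
  if (length(link_groups) != nf)
    stop("`link_groups` must have one entry per feature")
  if (is.null(sources)) sources <- paste0("synthetic:", seq_along(labels))
  structure(list(values = values, labels = labels, meta = meta,
                 link_groups = link_groups, sources = sources),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d examples x %d features\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$labels)
  cat("  classes: ", paste(sprintf("%s (n=%d)", names(tab), tab),
                           collapse = ", "), "\n", sep = "")
  sp <- table(x$meta$space)
  cat("  spaces:  ", paste(sprintf("%s [%d]", names(sp), sp),
                           collapse = ", "), "\n", sep = "")
  cat(sprintf("  link groups: %d\n", length(unique(x$link_groups))))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' @export
as.data.frame.feature_matrix <- function(x, ...) {
  d <- as.data.frame(x$values)
  names(d) <- feature_names(x)
  cbind(data.frame(label = x$labels), d)
}

#' Feature display names
#'
#' Compact per-feature names of the form `space.layer.coords`.
#' @param fm a [feature_matrix()].
#' @return character vector, one name per feature.
#' @export
feature_names <- function(fm) {
  m <- fm$meta
  co <- apply(cbind(m$coord1, m$coord2, m$coord3), 1L, function(v)
    paste(v[!is.na(v)], collapse = "."))
  paste0(m$space, ".", m$layer, ".", co)
}

#' Combine feature matrices column-wise
#'
#' Binds the feature blocks of several extractors (on identical example sets)
#' into one matrix, renumbering link groups so they stay disjoint.
#' @param ... `feature_matrix` objects over the same examples and labels.
#' @return a [feature_matrix()].
#' @export
combine_features <- function(...) {
  fms <- list(...)
  if (length(fms) == 1L && is.list(fms[[1L]]) &&
      !inherits(fms[[1L]], "feature_matrix")) fms <- fms[[1L]]
  stopifnot(length(fms) >= 1L)
  lab <- fms[[1L]]$labels
  for (fm in fms) {
    if (!identical(fm$labels, lab))
      stop("feature matrices to combine must share labels/examples")
  }
  vals <- do.call(cbind, lapply(fms, `[[`, "values"))
  meta <- do.call(rbind, lapply(fms, `[[`, "meta"))
  off <- 0L
  lg <- integer(0)
  for (fm in fms) {
    g <- match(fm$link_groups, unique(fm$link_groups))
    lg <- c(lg, g + off)
    off <- off + length(unique(g))
  }
  feature_matrix(vals, lab, meta, lg, fms[[1L]]$sources)
}

#' Per-pair feature differences
#'
#' Turns a feature matrix over single images into one over image *pairs*,
#' each pair contributing the element-wise difference `features(a) -
#' features(b)`. Used when the category is a behavioral response to a pair
#' (e.g. which of two images was chosen).
#'
#' @param fm a [feature_matrix()].
#' @param pairs a `data.frame` (or 3-column matrix) with columns `a`, `b`
#'   (example indices) and `label`.
#' @return a [feature_matrix()] with one example per pair; feature metadata
#'   and link groups are preserved.
#' @export
pairwise_feature_differences <- function(fm, pairs) {
  pairs <- as.data.frame(pairs)
  if (ncol(pairs) < 3L) stop("`pairs` needs columns a, b, label")
  names(pairs)[1:3] <- c("a", "b", "label")
  n <- nrow(fm$values)
  if (any(pairs$a < 1L | pairs$a > n | pairs$b < 1L | pairs$b > n))
    stop("pair index out of range")
  vals <- fm$values[pairs$a, , drop = FALSE] - fm$values[pairs$b, , drop = FALSE]
  feature_matrix(vals, pairs$label, fm$meta, fm$link_groups,
                 sources = paste0(fm$sources[pairs$a], "-", fm$sources[pairs$b]))
}

#' Write / read a feature matrix as delimited text
#'
#' The values go to `path` as CSV (`label`, then one column per feature); the
#' per-feature provenance (space, layer, coordinates, link group) goes to a
#' sidecar CSV at `meta_path`.
#' @param fm a [feature_matrix()].
#' @param path CSV file for the values.
#' @param meta_path CSV file for the metadata sidecar; defaults to
#'   `<path>` with a `_meta.csv` suffix.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path, meta_path = NULL) {
  if (is.null(meta_path)) meta_path <- sub("\\.csv$", "_meta.csv", path)
  d <- as.data.frame(fm)
  d <- cbind(data.frame(source = fm$sources), d)
  write.csv(d, path, row.names = FALSE)
  meta <- cbind(data.frame(feature = seq_len(ncol(fm$values)),
                           name = feature_names(fm)),
                fm$meta, data.frame(link_group = fm$link_groups))
  write.csv(meta, meta_path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path, meta_path = NULL) {
  if (is.null(meta_path)) meta_path <- sub("\\.csv$", "_meta.csv", path)
  d <- read.csv(path, check.names = FALSE)
  meta <- read.csv(meta_path)
  vals <- as.matrix(d[, -(1:2), drop = FALSE])
  feature_matrix(vals, d$label,
                 meta[, setdiff(names(meta), c("feature", "name", "link_group")),
                      drop = FALSE],
                 meta$link_group, sources = d$source)
}
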