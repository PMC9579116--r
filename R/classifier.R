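#' Train a classifier on a feature subset
#'
#' The package's classification models are linear soft-margin SVMs with unit
#' regularization (`C = 1`) on features standardized by training-set mean and
#' SD; multi-class problems are handled one-vs-one with majority voting.
#' Two interchangeable backends exist: `"linear_svm"` (the package's dual
#' coordinate-descent solver, used by default because the screening pipeline
#' trains many thousands of models) and `"libsvm"` (e1071/libsvm, identical
#' model family, useful as an independent cross-check).
#'
#' @param x numeric training matrix (rows = examples).
#' @param y training labels.
#' @param classifier `"linear_svm"` or `"libsvm"`.
#' @param cost soft-margin cost parameter `C` (default 1).
#' @return a model object of class `fs_classifier` for [predict()].
#' @export
classifier_fit <- function(x, y, classifier = "linear_svm", cost = 1) {
  if (!classifier %in% c("linear_svm", "libsvm"))
    stop("unknown classifier id: ", classifier)
  x <- as.matrix(x)
  y <- as.integer(y)
  mu <- colMeans(x)
  s <- sqrt(colSums(sweep(x, 2L, mu)^2) / max(1L, nrow(x) - 1L))
  s[s == 0] <- 1
  xs <- sweep(sweep(x, 2L, mu), 2L, s, "/")
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("training data must contain >= 2 classes")
  if (classifier == "libsvm") {
    fit <- e1071::svm(xs, factor(y, levels = classes), kernel = "linear",
                      cost = cost, scale = FALSE)
    return(structure(list(backend = "libsvm", fit = fit, mu = mu, s = s,
                          classes = classes), class = "fs_classifier"))
  }
  pairs <- utils::combn(classes, 2L)
  ws <- vector("list", ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1L, p]; b <- pairs[2L, p]
    sel <- y %in% c(a, b)
    yy <- ifelse(y[sel] == a, 1, -1)
    xa <- rbind(t(xs[sel, , drop = FALSE]), 1)   # regularized bias row
    ws[[p]] <- svm_linear_cd(xa, yy, C = cost)
  }
  structure(list(backend = "linear_svm", w = ws, pairs = pairs, mu = mu,
                 s = s, classes = classes), class = "fs_classifier")
}

#' @export
predict.fs_classifier <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  xs <- sweep(sweep(x, 2L, object$mu), 2L, object$s, "/")
  if (object$backend == "libsvm") {
    pr <- stats::predict(object$fit, xs)
    return(as.integer(as.character(pr)))
  }
  votes <- matrix(0L, nrow(x), length(object$classes))
  colnames(votes) <- object$classes
  xa <- cbind(xs, 1)
  for (p in seq_len(ncol(object$pairs))) {
    sc <- as.numeric(xa %*% object$w[[p]])
    a <- as.character(object$pairs[1L, p]); b <- as.character(object$pairs[2L, p])
    votes[, a] <- votes[, a] + (sc >= 0)
    votes[, b] <- votes[, b] + (sc < 0)
  }
  object$classes[max.col(votes, ties.method = "first")]
}

# train on (tr, features sel), return holdout accuracy on (te);
# y_train / y_test override the labels (used by the permutation scheme)
fit_accuracy <- function(x, y, sel, tr, te, classifier = "linear_svm",
                         y_train = NULL, y_test = NULL) {
  if (length(te) == 0L) return(NA_real_)
  if (length(sel) == 0L) return(1 / length(unique(y)))
  ytr <- if (is.null(y_train)) y[tr] else y_train
  yte <- if (is.null(y_test)) y[te] else y_test
  m <- classifier_fit(x[tr, sel, drop = FALSE], ytr, classifier)
  mean(predict(m, x[te, sel, drop = FALSE]) == yte)
}
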