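# the four per-fold selection procedures

fold_context <- function(x, y, k = 5, seed = 11) {
  set.seed(seed)
  plan <- make_fold_plan(y, cv_config(k = k))
  basis <- fresh_training_split(plan, 1)$training
  rk <- rank_features(x, y, basis)
  cl <- cluster_correlated(x, rk, basis)
  list(plan = plan, rk = rk, cl = cl, basis = basis)
}

test_that("filter selection: threshold path, degenerate alpha, fallback", {
  p <- tiny_problem(n = 80, p = 20, n_strong = 4, delta = 1.5, seed = 21)
  ctx <- fold_context(p$x, p$y)
  sel <- filter_select(p$x, p$y, ctx$rk, ctx$cl, ctx$plan, 1)
  expect_false(sel$fallback)
  # oracle: clusters pass iff their best member's KW p < .01 on the basis
  direct_p <- vapply(seq_len(20), function(j)
    kw_oracle(p$x[ctx$basis, j], p$y[ctx$basis])["p"], 0)
  want <- which(vapply(ctx$cl$clusters, function(m) min(direct_p[m]) < 0.01,
                       TRUE))
  expect_setequal(sel$cluster_ids, want)
  expect_equal(sel$target_size,
               length(unlist(ctx$cl$clusters[sel$cluster_ids])))
  # alpha = 1: every cluster selected
  all_sel <- filter_select(p$x, p$y, ctx$rk, ctx$cl, ctx$plan, 1, alpha = 1)
  expect_setequal(all_sel$cluster_ids, seq_along(ctx$cl$clusters))
  # pure noise: fallback still returns a non-empty ranking prefix
  noise <- tiny_problem(n = 60, p = 15, n_strong = 0, seed = 22)
  nctx <- fold_context(noise$x, noise$y)
  nsel <- filter_select(noise$x, noise$y, nctx$rk, nctx$cl, nctx$plan, 1)
  expect_true(nsel$fallback)
  expect_gt(length(nsel$cluster_ids), 0)
  # fallback selections are a prefix of the ranking (clusters of top-n)
  feats <- unlist(nctx$cl$clusters[nsel$cluster_ids])
  n_top <- length(feats)
  expect_setequal(feats, unique(unlist(
    nctx$cl$clusters[nctx$cl$assignment[nctx$rk$order[seq_len(n_top)]]])))
})

test_that("wrapper admits a dominant feature first and matches target size", {
  set.seed(23)
  n <- 80
  x <- cbind(rep(c(0, 1), each = n / 2) * 3 + rnorm(n, sd = 0.1),
             matrix(rnorm(n * 11), n, 11))
  y <- rep(1:2, each = n / 2)
  ctx <- fold_context(x, y, seed = 23)
  expect_equal(ctx$rk$order[1], 1L)         # separating feature ranks first
  w <- wrapper_select(x, y, ctx$plan, 1, ctx$rk, ctx$cl, target_size = 4L,
                      cfg = wrapper_config(repeats = 2))
  expect_true(1L %in% unlist(ctx$cl$clusters[w$cluster_ids]))
  expect_equal(w$log$admitted[1] > 0, TRUE)
  feats <- unlist(ctx$cl$clusters[w$cluster_ids])
  # size contract: target reached within the last cluster's granularity
  max_cluster <- max(ctx$cl$sizes[w$cluster_ids])
  expect_gte(length(feats), min(4L, length(feats)))
  expect_lt(length(feats), 4L + max_cluster)
  expect_error(wrapper_select(x, y, ctx$plan, 1, ctx$rk, ctx$cl, 0L),
               "positive")
})

test_that("wrapper beats equally sized random selections on informative data", {
  set.seed(24)
  p <- tiny_problem(n = 100, p = 30, n_strong = 5, delta = 1, seed = 24)
  plan <- make_fold_plan(p$y, cv_config(k = 5))
  wins <- 0; diffs <- numeric(0)
  for (f in 1:5) {
    basis <- fresh_training_split(plan, f)$training
    rk <- rank_features(p$x, p$y, basis)
    cl <- cluster_correlated(p$x, rk, basis)
    w <- wrapper_select(p$x, p$y, plan, f, rk, cl, 5L,
                        wrapper_config(repeats = 2))
    r <- random_select(cl, 5L)
    nh <- non_holdout(plan, f)
    te <- plan$holdout[[f]]
    aw <- featscreen:::fit_accuracy(p$x, p$y, unlist(cl$clusters[w$cluster_ids]),
                                    nh, te)
    ar <- featscreen:::fit_accuracy(p$x, p$y, unlist(cl$clusters[r$cluster_ids]),
                                    nh, te)
    diffs <- c(diffs, aw - ar)
  }
  expect_gte(mean(diffs), 0)
})

test_that("random selection: exhaustion, size contract, uniformity", {
  cl <- structure(list(clusters = as.list(1:10), assignment = 1:10,
                       sizes = rep(1L, 10), r2_threshold = 0.25),
                  class = "feature_clusters")
  set.seed(25)
  all_of_them <- random_select(cl, 10L)
  expect_setequal(all_of_them$cluster_ids, 1:10)
  expect_error(random_select(cl, 11L), "exceeds")
  sizes <- replicate(200, length(random_select(cl, 4L)$cluster_ids))
  expect_true(all(sizes == 4))
  # inclusion frequencies consistent with uniform draws
  picks <- unlist(replicate(500, random_select(cl, 4L)$cluster_ids,
                            simplify = FALSE))
  gof <- chisq.test(table(factor(picks, levels = 1:10)))
  expect_gt(gof$p.value, 0.001)
})

test_that("pseudorandom selection avoids excluded clusters, shrinks with warning", {
  cl <- structure(list(clusters = as.list(1:20), assignment = 1:20,
                       sizes = rep(1L, 20), r2_threshold = 0.25),
                  class = "feature_clusters")
  set.seed(26)
  for (i in 1:50) {
    ps <- pseudorandom_select(cl, excluded = 1:8, target_size = 5L)
    expect_length(intersect(ps$cluster_ids, 1:8), 0)
    expect_length(ps$cluster_ids, 5)
  }
  # excluded empty reduces to plain random behavior
  expect_length(pseudorandom_select(cl, integer(0), 20L)$cluster_ids, 20)
  expect_warning(ps2 <- pseudorandom_select(cl, 1:18, 5L), "shrunk")
  expect_setequal(ps2$cluster_ids, 19:20)
})

test_that("holdout labels cannot influence the selections (no leakage)", {
  p <- tiny_problem(n = 60, p = 15, n_strong = 3, delta = 1.2, seed = 27)
  run_fold <- function(y) {
    set.seed(101)
    plan <- make_fold_plan(p$y, cv_config(k = 5))  # plan from true labels
    basis <- fresh_training_split(plan, 1)$training
    rk <- rank_features(p$x, y, basis)
    cl <- cluster_correlated(p$x, rk, basis)
    fs <- filter_select(p$x, y, rk, cl, plan, 1)
    ws <- wrapper_select(p$x, y, plan, 1, rk, cl, fs$target_size,
                         wrapper_config(repeats = 2))
    list(f = sort(unlist(cl$clusters[fs$cluster_ids])),
         w = sort(unlist(cl$clusters[ws$cluster_ids])))
  }
  y_perm <- p$y
  set.seed(55)
  plan0 <- local({set.seed(101); make_fold_plan(p$y, cv_config(k = 5))})
  ho <- plan0$holdout[[1]]
  y_perm[ho] <- sample(y_perm[ho])
  expect_identical(run_fold(p$y), run_fold(y_perm))
})
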