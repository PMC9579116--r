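# evaluation, permutation null, method- and feature-level significance

small_screen <- function(n_strong = 2, delta = 2, seed = 41, k = 4,
                         shuffles = 5, n = 64, p = 16) {
  prob <- tiny_problem(n = n, p = p, n_strong = n_strong, delta = delta,
                       seed = seed)
  fit <- featscreen(prob$x, prob$y, cv = cv_config(k = k),
                    wrapper = wrapper_config(repeats = 2),
                    perm = perm_config(shuffles_per_fold_per_method = shuffles),
                    seed = seed)
  list(fit = fit, prob = prob)
}

test_that("a selection holding a perfectly separating feature scores 1.0", {
  set.seed(42)
  n <- 40
  x <- cbind(rep(c(-2, 2), each = n / 2), matrix(rnorm(n * 3), n, 3))
  y <- rep(1:2, each = n / 2)
  plan <- local({set.seed(1); make_fold_plan(y, cv_config(k = 4))})
  selections <- lapply(1:4, function(f)
    list(filter = 1L, wrapper = 1L, random = 2L, pseudorandom = 3:4))
  perf <- evaluate_selections(x, y, selections, plan)
  expect_equal(unname(perf[, "filter"]), rep(1, 4))
  expect_equal(unname(perf[, "wrapper"]), rep(1, 4))
  expect_equal(dim(perf), c(4L, 5L))       # four selections + full model
  expect_true(all(colnames(perf) ==
                    c("filter", "wrapper", "random", "pseudorandom", "full")))
})

test_that("label-shuffled evaluation sits at chance", {
  set.seed(43)
  p <- tiny_problem(n = 80, p = 10, n_strong = 3, delta = 2)
  y_shuf <- sample(p$y)
  plan <- make_fold_plan(y_shuf, cv_config(k = 5))
  selections <- lapply(1:5, function(f)
    list(filter = 1:3, wrapper = 4:6, random = 7:8, pseudorandom = 9:10))
  perf <- evaluate_selections(p$x, y_shuf, selections, plan)
  expect_lt(abs(mean(perf[, "filter"]) - 0.5), 0.15)
})

test_that("permutation null: bookkeeping and chance centering", {
  ss <- small_screen()
  null <- ss$fit$null_distribution
  expect_length(null, 4 * 5 * 4)           # k x shuffles x methods
  cells <- table(attr(null, "fold"), attr(null, "method"))
  expect_true(all(cells == 5))
  expect_lt(abs(mean(null) - 0.5), 0.08)
  # seed-reproducible
  ss2 <- small_screen()
  expect_equal(as.numeric(null), as.numeric(ss2$fit$null_distribution))
})

test_that("method p-values follow the smoothed permutation tail", {
  null <- seq(0.3, 0.7, length.out = 1000)
  perf <- matrix(c(rep(0.9, 3), rep(0.45, 3)), 3,
                 dimnames = list(NULL, c("filter", "wrapper")))
  p <- method_significance(perf, null)
  expect_equal(unname(p["filter"]), 1 / 1001)      # above every null value
  expect_gt(unname(p["wrapper"]), 0.5)             # below the null median
  # tail is counted with >=
  perf2 <- matrix(0.7, 1, 1, dimnames = list(NULL, "filter"))
  expect_equal(unname(method_significance(perf2, null)["filter"]), 2 / 1001)
})

test_that("feature relevance: m = 1 criterion equals the null maximum, and
           the control criterion contracts as usage grows", {
  set.seed(44)
  null <- rnorm(1000, 0.5, 0.07)
  usages <- c(1L, 2L, 5L, 10L, 25L)
  stats <- data.frame(feature = seq_along(usages), usage = usages,
                      mean_perf = 0.99, max_perf = 0.99)
  out <- feature_significance(stats, null)
  expect_equal(out$criterion[1], max(null))        # exactly the null max
  # contraction toward the mean: averaged over repeats, criteria decrease in m
  crits <- replicate(30, {
    o <- feature_significance(stats, null)
    o$criterion
  })
  avg <- rowMeans(crits)
  expect_true(all(diff(avg) < 0))
  # a feature below its criterion is not flagged; above, it is
  stats2 <- data.frame(feature = 1:2, usage = c(1L, 1L),
                       mean_perf = c(max(null) - 0.01, max(null) + 0.01),
                       max_perf = c(0.99, 0.99))
  out2 <- feature_significance(stats2, null)
  expect_equal(out2$relevant, c(FALSE, TRUE))
  # the percentile gate: low-performing appearances are never candidates
  stats3 <- data.frame(feature = 1L, usage = 3L, mean_perf = 0.99,
                       max_perf = as.numeric(quantile(null, 0.5)))
  expect_false(feature_significance(stats3, null)$candidate)
})

test_that("screening a separable problem flags its features, keeps nulls out", {
  ss <- small_screen(n_strong = 2, delta = 2.5, seed = 45, k = 5, n = 100)
  st <- ss$fit$feature_stats
  expect_equal(nrow(st), ss$fit$n_features)
  expect_true(any(st$relevant[1:2]))               # manipulated features found
  expect_lt(ss$fit$method_p["filter"], 0.05)
  # usage-restricted invariant: flagged implies used
  expect_true(all(st$usage[st$relevant] >= 1))
})

test_that("methods can miss while individual features are still flagged", {
  # needle case: 1 strong feature among many; random/pseudorandom selections
  # rarely contain it, so their p-values stay high, yet the feature itself is
  # flagged through the filter/wrapper models that carry it
  set.seed(46)
  n <- 80; p <- 60
  x <- matrix(rnorm(n * p), n, p)
  y <- rep(1:2, each = n / 2)
  x[y == 1, 1] <- x[y == 1, 1] + 2.5
  fit <- featscreen(x, y, cv = cv_config(k = 4),
                    wrapper = wrapper_config(repeats = 2),
                    perm = perm_config(shuffles_per_fold_per_method = 10),
                    seed = 46)
  expect_gt(fit$method_p["pseudorandom"], 0.1)
  expect_true(fit$feature_stats$relevant[1])
})

test_that("feature-combination search flags engineered complementary pairs", {
  set.seed(47)
  n <- 120
  sgn <- rep(c(-1, 1), each = n / 2)
  w <- rnorm(n, sd = 2)                      # strong shared nuisance
  x <- cbind(sgn * 0.8 + w, sgn * 0.8 - w,   # complementary pair: sum = signal
             matrix(rnorm(n * 4, sd = 1), n, 4))
  y <- ifelse(sgn < 0, 1, 2)
  plan <- local({set.seed(2); make_fold_plan(y, cv_config(k = 4))})
  res <- find_feature_combinations(x, y, relevant = 1:5, plan)
  expect_equal(nrow(res), 10)
  pair12 <- res[res$feature_a == 1 & res$feature_b == 2, ]
  expect_true(pair12$flagged)
  expect_gt(pair12$acc_pair, pair12$acc_a + 0.15)
  # fewer than two relevant features: empty result
  expect_equal(nrow(find_feature_combinations(x, y, 1L, plan)), 0)
  # homogeneous accuracies: nothing exceeds mean + 2 SD
  res2 <- find_feature_combinations(x, y, relevant = 3:6, plan)
  expect_false(any(res2$flagged))
})
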