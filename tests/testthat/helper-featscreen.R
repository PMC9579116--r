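# shared fixtures, all generated in code

# tiny two-class gaussian problem with `n_strong` separating features
tiny_problem <- function(n = 60, p = 12, n_strong = 2, delta = 2, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  y <- rep(1:2, length.out = n)
  if (n_strong > 0)
    x[y == 1, seq_len(n_strong)] <- x[y == 1, seq_len(n_strong)] + delta
  list(x = x, y = y)
}

# small in-memory image set: grayscale gradients plus class-2 bright square
tiny_image_set <- function(n_per_class = 3, size = 20, seed = 1) {
  set.seed(seed)
  imgs <- list()
  for (cl in 1:2) for (i in seq_len(n_per_class)) {
    im <- matrix(runif(size * size, 0.2, 0.4), size, size)
    if (cl == 2) im[5:10, 5:10] <- im[5:10, 5:10] + 0.5
    imgs[[length(imgs) + 1]] <- pmin(im, 1)
  }
  image_set(imgs, rep(1:2, each = n_per_class), color_mode = "gray")
}

# write a small PNG image set to disk: two directories, `n` files each
write_png_dirs <- function(root, n = 3, size = 16, seed = 1) {
  set.seed(seed)
  dirs <- file.path(root, c("catA", "catB"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  for (ci in 1:2) for (i in seq_len(n)) {
    im <- matrix(runif(size * size), size, size)
    if (ci == 2) im[1:5, 1:5] <- 1
    png::writePNG(im, file.path(dirs[ci], sprintf("img%02d.png", i)))
  }
  dirs
}

# independent brute-force Kruskal-Wallis via stats::kruskal.test
kw_oracle <- function(v, g) {
  k <- stats::kruskal.test(v, factor(g))
  c(H = unname(k$statistic), p = k$p.value)
}
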