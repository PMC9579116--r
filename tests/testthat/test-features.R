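# feature extraction: Fourier magnitude bands, phase, HOG, color, pixels

make_gray_set <- function(imgs) {
  image_set(imgs, rep(1:2, length.out = max(2, length(imgs))), color_mode = "gray")
}

test_that("Fourier magnitude banding: counts, DC handling, conservation", {
  set.seed(1)
  imgs <- replicate(4, matrix(runif(32 * 32), 32, 32), simplify = FALSE)
  fm <- extract_fourier_magnitude(make_gray_set(imgs))
  expect_equal(ncol(fm$values), 384)  # 24 x 16 sections
  # conservation: band sums partition the raw magnitude spectrum
  for (i in 1:4) {
    expect_equal(sum(fm$values[i, ]), sum(Mod(fft(imgs[[i]]))),
                 tolerance = 1e-10)
  }
  # constant image: all energy is the DC term, assigned to band 1 / sector 1
  cfm <- extract_fourier_magnitude(make_gray_set(
    list(matrix(0.5, 16, 16), matrix(0.25, 16, 16))))
  v <- cfm$values[1, ]
  expect_equal(v[1], 0.5 * 256)           # DC magnitude = mean * npix
  expect_true(all(v[-1] == 0))
})

test_that("Fourier band features match a brute-force mask-sum oracle", {
  set.seed(42)
  n <- 24
  cfg <- feature_config(sf_bands = 6, ori_bands = 4)
  # independent mask computation: loop over all coefficients
  oracle_bands <- function(m, sf_b, ori_b) {
    N <- nrow(m)
    mag <- Mod(fft(m))
    out <- matrix(0, sf_b, ori_b)
    f <- c(0:(N / 2), -(N / 2 - 1):-1)
    for (i in 1:N) for (j in 1:N) {
      fy <- f[i]; fx <- f[j]
      r <- sqrt(fx^2 + fy^2) / (N / 2)
      sf <- if (r == 0) 1 else min(max(ceiling(r * sf_b), 1), sf_b)
      th <- atan2(fy, fx) %% pi
      if (th >= pi - 1e-12) th <- 0
      ori <- if (r == 0) 1 else min(floor(th / (pi / ori_b)), ori_b - 1) + 1
      out[sf, ori] <- out[sf, ori] + mag[i, j]
    }
    as.numeric(out)
  }
  imgs <- replicate(10, matrix(runif(n * n), n, n), simplify = FALSE)
  fm <- extract_fourier_magnitude(make_gray_set(imgs), cfg)
  for (i in seq_along(imgs))
    expect_equal(unname(fm$values[i, ]), oracle_bands(imgs[[i]], 6, 4),
                 tolerance = 1e-10)
})

test_that("a pure grating concentrates energy in its frequency/orientation band", {
  N <- 32
  freq <- 6                                 # cycles per image, along columns
  g <- matrix(0.5 + 0.4 * sin(2 * pi * freq * (0:(N - 1)) / N), N, N,
              byrow = TRUE)                 # kept inside [0, 1]
  fm <- extract_fourier_magnitude(make_gray_set(list(g, 0.5 + (g - 0.5) / 2)))
  v <- matrix(fm$values[1, ], 24, 16)       # sf x orientation
  band <- ceiling(freq / (N / 2) * 24)
  # horizontal variation -> fx-axis -> orientation sector 1; all non-DC
  # energy in the grating's frequency band (DC sits in section [1, 1])
  expect_gt(v[band, 1], 0.99 * (sum(v) - v[1, 1]))
  expect_equal(v[1, 1], 0.5 * N^2)
})

test_that("phase features: count, DC phase, shift theorem", {
  set.seed(3)
  im <- matrix(runif(25 * 25, 0.1, 1), 25, 25)  # already at target size
  s <- image_set(list(im, im + 0.1), c(1, 2), color_mode = "gray")
  ph <- extract_fourier_phase(s, include_magnitude = FALSE)
  expect_equal(ncol(ph$values), 625)
  both <- extract_fourier_phase(s, include_magnitude = TRUE)
  expect_equal(ncol(both$values), 1250)
  # each phase/magnitude pair shares a link group
  expect_equal(both$link_groups[1:625], both$link_groups[626:1250])
  # constant positive image: DC phase 0
  cs <- image_set(list(matrix(0.7, 25, 25), matrix(0.3, 25, 25)), c(1, 2),
                  color_mode = "gray")
  cph <- extract_fourier_phase(cs, include_magnitude = FALSE)
  dc <- which(cph$meta$coord1 == 1 & cph$meta$coord2 == 1)
  expect_equal(cph$values[1, dc], 0)
  # circular shift by one row: phase shifts by the linear ramp, magnitudes fixed
  im2 <- im[c(25, 1:24), ]
  s2 <- image_set(list(im, im2), c(1, 2), color_mode = "gray")
  b2 <- extract_fourier_phase(s2, include_magnitude = TRUE)
  mags <- b2$values[, 626:1250]
  expect_equal(mags[1, ], mags[2, ], tolerance = 1e-9)
  f1 <- fft(im); f2 <- fft(im2)
  ky <- c(0:12, -12:-1)                     # cycles along rows
  ramp <- exp(-2i * pi * matrix(ky, 25, 25) / 25)
  expect_equal(f2, f1 * ramp, tolerance = 1e-8)
})

test_that("HOG features: geometry, zero gradient, step edge, gradient oracle", {
  s200 <- make_gray_set(list(matrix(runif(200 * 200), 200, 200),
                             matrix(runif(200 * 200), 200, 200)))
  fm <- extract_hog(s200)
  expect_equal(ncol(fm$values), 20 * 20 * 9)
  # constant image: all features zero
  cs <- make_gray_set(list(matrix(0.4, 30, 30), matrix(0.8, 30, 30)))
  expect_true(all(extract_hog(cs)$values == 0))
  # single vertical luminance step at column 15: only cells straddling the
  # step respond, in the horizontal-gradient bin (angle 0 -> bin 1)
  step <- matrix(0, 30, 30); step[, 16:30] <- 1
  sf <- extract_hog(make_gray_set(list(step, step)))
  v <- sf$values[1, ]
  m <- sf$meta
  hot <- v > 0
  expect_true(all(m$coord2[hot] == 2))      # middle cell column only
  expect_true(all(m$coord3[hot] == 1))      # unsigned horizontal orientation
  expect_gt(sum(hot), 0)
  # brute-force gradient histogram oracle on a random 30x30 image
  set.seed(9)
  im <- matrix(runif(900), 30, 30)
  got <- extract_hog(make_gray_set(list(im, im)))$values[1, ]
  oracle <- numeric(3 * 3 * 9)
  h <- w <- 30
  gx <- (im[, c(2:w, w)] - im[, c(1, 1:(w - 1))]) / 2
  gy <- (im[c(2:h, h), ] - im[c(1, 1:(h - 1)), ]) / 2
  for (r in 1:30) for (cl in 1:30) {
    mag <- sqrt(gx[r, cl]^2 + gy[r, cl]^2)
    ang <- atan2(gy[r, cl], gx[r, cl]) %% pi
    pos <- ang / (pi / 9); b0 <- floor(pos); fr <- pos - b0
    cellr <- ceiling(r / 10); cellc <- ceiling(cl / 10)
    base <- ((cellr - 1) + 3 * (cellc - 1)) * 9
    oracle[base + (b0 %% 9) + 1] <- oracle[base + (b0 %% 9) + 1] + mag * (1 - fr)
    oracle[base + ((b0 + 1) %% 9) + 1] <- oracle[base + ((b0 + 1) %% 9) + 1] + mag * fr
  }
  expect_equal(unname(got), oracle, tolerance = 1e-10)
})

test_that("color histograms are probability vectors with fixed bins, never linked", {
  set.seed(4)
  rgb1 <- array(runif(12 * 12 * 3), c(12, 12, 3))
  rgb2 <- array(runif(12 * 12 * 3), c(12, 12, 3))
  s <- image_set(list(rgb1, rgb2), c(1, 2), color_mode = "rgb")
  fm <- extract_color_histogram(s)
  expect_equal(ncol(fm$values), 75)
  for (l in 1:3) {
    block <- fm$values[, fm$meta$layer == l, drop = FALSE]
    expect_equal(unname(rowSums(block)), c(1, 1))
    expect_true(all(block >= 0))
  }
  expect_equal(length(unique(fm$link_groups)), 75)  # never linked
  # constant layer -> single bin holds everything
  cim <- array(0.5, c(8, 8, 3))
  cfm <- extract_color_histogram(image_set(list(cim, cim * 0.2), c(1, 2),
                                           color_mode = "rgb"))
  l1 <- cfm$values[1, cfm$meta$layer == 1]
  expect_equal(sum(l1 == 1), 1)
  expect_equal(sum(l1), 1)
  # two-value layer in different bins -> 0.5 / 0.5
  two <- matrix(c(0.1, 0.9), 8, 8)
  tfm <- extract_color_histogram(
    image_set(list(array(rep(two, 3), c(8, 8, 3)),
                   array(0.5, c(8, 8, 3))), c(1, 2), color_mode = "rgb"))
  l1 <- tfm$values[1, tfm$meta$layer == 1]
  expect_equal(sort(l1[l1 > 0]), c(0.5, 0.5))
  # lab requested on grayscale input is refused upstream
  expect_error(image_set(list(matrix(0.5, 8, 8), matrix(0.2, 8, 8)), c(1, 2),
                         color_mode = "lab"), "convert")
})

test_that("pixel intensities: identity at target size, row-major coordinates", {
  set.seed(5)
  im <- matrix(runif(625), 25, 25)
  fm <- extract_pixel_intensities(image_set(list(im, im * 0.5), c(1, 2),
                                            color_mode = "gray"))
  expect_equal(ncol(fm$values), 625)
  for (j in c(1, 30, 333, 625)) {
    expect_equal(fm$values[1, j], im[fm$meta$coord1[j], fm$meta$coord2[j]])
  }
  # row-major: first 25 features are row 1
  expect_equal(unname(fm$values[1, 1:25]), im[1, ])
})

test_that("downscaled pixels match an independent resampling oracle", {
  # 50x50 checkerboard of 2x2 blocks -> 25x25
  cb <- matrix(0, 50, 50)
  cb[(((row(cb) - 1) %/% 2) + ((col(cb) - 1) %/% 2)) %% 2 == 0] <- 1
  got <- resize_bicubic(cb, 25, 25)
  # brute-force oracle: same stated kernel (Keys a=-0.5, antialiased),
  # computed pointwise with explicit loops
  kernel <- function(x) {
    x <- abs(x)
    ifelse(x <= 1, 1.5 * x^3 - 2.5 * x^2 + 1,
           ifelse(x < 2, -0.5 * x^3 + 2.5 * x^2 - 4 * x + 2, 0))
  }
  oracle1d <- function(n_in, n_out) {
    sc <- n_out / n_in; k <- min(sc, 1)
    w <- matrix(0, n_out, n_in)
    for (i in 1:n_out) {
      u <- (i - 0.5) / sc + 0.5
      for (j in floor(u - 2 / k):ceiling(u + 2 / k)) {
        jj <- min(max(j, 1), n_in)
        w[i, jj] <- w[i, jj] + kernel((j - u) * k)
      }
      w[i, ] <- w[i, ] / sum(w[i, ])
    }
    w
  }
  expected <- oracle1d(50, 25) %*% cb %*% t(oracle1d(50, 25))
  expect_equal(got, expected, tolerance = 1e-12)
  # interpolation is exact at identical size
  set.seed(6)
  im <- matrix(runif(100), 10, 10)
  expect_equal(resize_bicubic(im, 10, 10), im, tolerance = 1e-12)
  # constant images stay constant under any resampling
  expect_equal(resize_bicubic(matrix(0.3, 37, 23), 25, 25),
               matrix(0.3, 25, 25), tolerance = 1e-12)
})

test_that("translation invariance holds exactly where claimed", {
  set.seed(7)
  im <- matrix(runif(40 * 40), 40, 40)
  shifted <- im[c(8:40, 1:7), c(31:40, 1:30)]    # circular shift
  s <- image_set(list(im, shifted), c(1, 2), color_mode = "gray")
  fmag <- extract_fourier_magnitude(s)
  expect_equal(fmag$values[1, ], fmag$values[2, ], tolerance = 1e-9)
  ch <- extract_color_histogram(s)
  expect_equal(ch$values[1, ], ch$values[2, ], tolerance = 1e-12)
  hog <- extract_hog(s, feature_config(hog_cell = 10))
  expect_false(isTRUE(all.equal(hog$values[1, ], hog$values[2, ])))
  px <- extract_pixel_intensities(s)
  expect_false(isTRUE(all.equal(px$values[1, ], px$values[2, ])))
})

test_that("output dimensions follow closed forms for random configurations", {
  set.seed(8)
  s <- make_gray_set(list(matrix(runif(900), 30, 30),
                          matrix(runif(900), 30, 30)))
  for (rep in 1:5) {
    sf <- sample(4:30, 1); ori <- sample(2:20, 1)
    hogo <- sample(3:12, 1); cell <- sample(c(5, 6, 10, 15), 1)
    bins <- sample(5:40, 1); ds <- sample(5:20, 1)
    cfg <- feature_config(sf_bands = sf, ori_bands = ori,
                          hog_orientations = hogo, hog_cell = cell,
                          color_bins = bins, downsample_size = ds)
    expect_equal(ncol(extract_fourier_magnitude(s, cfg)$values), sf * ori)
    expect_equal(ncol(extract_hog(s, cfg)$values),
                 (30 %/% cell)^2 * hogo)
    expect_equal(ncol(extract_pixel_intensities(s, cfg)$values), ds^2)
    expect_equal(ncol(extract_fourier_phase(s, cfg, FALSE)$values), ds^2)
  }
})

test_that("images smaller than the minimum sizes are rejected", {
  s <- make_gray_set(list(matrix(0.5, 1, 1), matrix(0.2, 1, 1)))
  expect_error(extract_fourier_magnitude(s), "2x2")
  s2 <- make_gray_set(list(matrix(0.5, 4, 4), matrix(0.2, 4, 4)))
  expect_error(extract_hog(s2), "cell")
})
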