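#' Feature extraction configuration
#'
#' Tunable parameters of the five feature spaces.
#'
#' @param sf_bands number of spatial-frequency bands for the Fourier
#'   magnitude space (default 24). Bands are equal-width annuli in normalized
#'   frequency radius from 0 (DC, exclusive) to Nyquist; coefficients beyond
#'   Nyquist (the spectrum corners) fall into the top band.
#' @param ori_bands number of orientation sectors partitioning `[0, 180)`
#'   degrees (default 16).
#' @param hog_orientations number of unsigned gradient-orientation bins over
#'   `[0, 180)` (default 9).
#' @param hog_cell side length, in pixels, of the non-overlapping HOG cells
#'   (default 10).
#' @param color_bins number of histogram bins per color layer (default 25).
#' @param downsample_size target size (pixels, square) for the Fourier-phase
#'   and pixel-intensity spaces (default 25).
#' @param link_layers when `TRUE` (default), corresponding features from
#'   different layers share a link group and are selected together. Ignored
#'   by the color-distribution space, where cross-layer linking is
#'   meaningless.
#' @return a list of class `feature_config`.
#' @export
feature_config <- function(sf_bands = 24L, ori_bands = 16L,
                           hog_orientations = 9L, hog_cell = 10L,
                           color_bins = 25L, downsample_size = 25L,
                           link_layers = TRUE) {
  cfg <- list(sf_bands = as.integer(sf_bands), ori_bands = as.integer(ori_bands),
              hog_orientations = as.integer(hog_orientations),
              hog_cell = as.integer(hog_cell), color_bins = as.integer(color_bins),
              downsample_size = as.integer(downsample_size),
              link_layers = isTRUE(link_layers))
  if (any(unlist(cfg[1:6]) < 1L)) stop("all feature_config counts must be >= 1")
  structure(cfg, class = "feature_config")
}

crop_center_square <- function(m) {
  h <- nrow(m); w <- ncol(m); s <- min(h, w)
  r0 <- floor((h - s) / 2); c0 <- floor((w - s) / 2)
  m[r0 + seq_len(s), c0 + seq_len(s), drop = FALSE]
}

# Band assignment of every FFT coefficient of an n x n spectrum:
# sf band = equal-width annuli of normalized radius (Nyquist = 1, corners
# clamped into the top band), DC -> band 1; orientation = equal sectors of
# [0, 180) using spectral symmetry, DC -> sector containing 0 degrees.
fourier_band_index <- function(n, sf_bands, ori_bands) {
  f <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[seq_len(n)]
  fx <- matrix(f, n, n, byrow = TRUE)   # frequency along image columns
  fy <- matrix(f, n, n)                 # frequency along image rows
  r <- sqrt(fx^2 + fy^2) / (n / 2)
  sf <- pmin(pmax(ceiling(r * sf_bands), 1L), sf_bands)
  theta <- atan2(fy, fx) %% pi
  theta[theta >= pi - 1e-12] <- 0
  ori <- pmin(floor(theta / (pi / ori_bands)), ori_bands - 1L) + 1L
  ori[r == 0] <- 1L
  list(sf = sf, ori = ori, section = (ori - 1L) * sf_bands + sf)
}

per_layer_extract <- function(images, cfg, space, layer_fun, meta_fun,
                              link = cfg$link_layers) {
  nl <- n_layers(images$images[[1L]])
  blocks <- vector("list", nl)
  for (l in seq_len(nl)) {
    vals <- t(vapply(images$images, function(im) layer_fun(get_layer(im, l)),
                     numeric(length(layer_fun(get_layer(images$images[[1L]], l))))))
    blocks[[l]] <- vals
  }
  per <- ncol(blocks[[1L]])
  meta <- do.call(rbind, lapply(seq_len(nl), function(l)
    cbind(data.frame(space = space, layer = l), meta_fun())))
  lg <- if (link) rep(seq_len(per), nl) else seq_len(per * nl)
  feature_matrix(do.call(cbind, blocks), images$labels, meta, lg,
                 sources = images$sources)
}

#' Fourier magnitude band features
#'
#' Per layer, the 2-D FFT magnitude spectrum is summed within
#' `sf_bands x ori_bands` spatial-frequency/orientation sections (default
#' 24 x 16 = 384 features per layer). Because phase is discarded and
#' magnitudes are pooled over bands, these features are position-invariant
#' and describe global contrast structure. Non-square images are cropped
#' centrally to the largest square first.
#'
#' @param images an [image_set()].
#' @param cfg a [feature_config()].
#' @return a [feature_matrix()]; `meta` columns `coord1`/`coord2` give the
#'   spatial-frequency and orientation band of each feature.
#' @export
extract_fourier_magnitude <- function(images, cfg = feature_config()) {
  dims <- vapply(images$images, function(im) min(dim(im)[1:2]), 1L)
  if (any(dims < 2L)) stop("images must be at least 2x2 pixels")
  cache <- new.env(parent = emptyenv())
  nsec <- cfg$sf_bands * cfg$ori_bands
  layer_fun <- function(m) {
    m <- crop_center_square(m)
    key <- as.character(nrow(m))
    if (is.null(cache[[key]]))
      cache[[key]] <- fourier_band_index(nrow(m), cfg$sf_bands, cfg$ori_bands)
    mag <- Mod(stats::fft(m))
    tabulate_sum(as.numeric(mag), cache[[key]]$section, nsec)
  }
  meta_fun <- function() data.frame(
    coord1 = rep(seq_len(cfg$sf_bands), cfg$ori_bands),
    coord2 = rep(seq_len(cfg$ori_bands), each = cfg$sf_bands),
    coord3 = NA_integer_)
  per_layer_extract(images, cfg, "fourier_mag", layer_fun, meta_fun)
}

# sum `x` within integer groups 1..n (dense, keeps empty groups as 0)
tabulate_sum <- function(x, g, n) {
  out <- numeric(n)
  s <- rowsum(x, as.integer(g))
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

#' Fourier phase (and linked magnitude) features
#'
#' Each layer is downscaled to `downsample_size` squared pixels (bicubic) and
#' 2-D FFT phase angles are taken per coefficient (625 features per layer at
#' defaults). With `include_magnitude`, the matching magnitudes are appended
#' and each phase/magnitude pair shares a link group, so the pair enters or
#' leaves selections together.
#'
#' @inheritParams extract_fourier_magnitude
#' @param include_magnitude also extract the linked magnitudes (default
#'   `TRUE`).
#' @return a [feature_matrix()] with spaces `fourier_phase` (and
#'   `fourier_phase_mag`).
#' @export
extract_fourier_phase <- function(images, cfg = feature_config(),
                                  include_magnitude = TRUE) {
  ds <- cfg$downsample_size
  grid_meta <- function() data.frame(
    coord1 = rep(seq_len(ds), each = ds),
    coord2 = rep(seq_len(ds), ds), coord3 = NA_integer_)
  fft_small <- function(m) stats::fft(resize_bicubic(m, ds, ds))
  ph <- per_layer_extract(images, cfg, "fourier_phase",
                          function(m) as.numeric(t(Arg(fft_small(m)))),
                          grid_meta)
  if (!include_magnitude) return(ph)
  mg <- per_layer_extract(images, cfg, "fourier_phase_mag",
                          function(m) as.numeric(t(Mod(fft_small(m)))),
                          grid_meta)
  out <- combine_features(ph, mg)
  # phase/magnitude pairs (same layer, same coefficient) are one unit
  out$link_groups <- rep(ph$link_groups, 2L)
  out
}

#' Histogram-of-oriented-gradients features
#'
#' Gradients by centered finite differences (replicated borders), unsigned
#' orientation over `[0, 180)` degrees, gradient magnitude linearly
#' interpolated between the two adjacent orientation bins, summed within
#' non-overlapping square cells. No block normalization is applied, so each
#' feature reads as the edge energy of one orientation in one cell. Rows and
#' columns beyond the last full cell are cropped (bottom/right).
#'
#' @inheritParams extract_fourier_magnitude
#' @return a [feature_matrix()]; `meta` columns give cell row (`coord1`),
#'   cell column (`coord2`) and orientation bin (`coord3`).
#' @export
extract_hog <- function(images, cfg = feature_config()) {
  cell <- cfg$hog_cell; B <- cfg$hog_orientations
  d0 <- dim(images$images[[1L]])[1:2]
  if (any(d0 < cell)) stop("image smaller than one HOG cell (", cell, " px)")
  layer_fun <- function(m) {
    h <- nrow(m); w <- ncol(m)
    ch <- h %/% cell; cw <- w %/% cell
    m <- m[seq_len(ch * cell), seq_len(cw * cell), drop = FALSE]
    h <- nrow(m); w <- ncol(m)
    gx <- (m[, c(2:w, w)] - m[, c(1, 1:(w - 1))]) / 2
    gy <- (m[c(2:h, h), ] - m[c(1, 1:(h - 1)), ]) / 2
    mag <- sqrt(gx^2 + gy^2)
    ang <- atan2(gy, gx) %% pi
    pos <- ang / (pi / B)
    b0 <- floor(pos); frac <- pos - b0
    cell_id <- (((row(m) - 1L) %/% cell)) + ch * ((col(m) - 1L) %/% cell)
    idx0 <- cell_id * B + (b0 %% B) + 1L
    idx1 <- cell_id * B + ((b0 + 1) %% B) + 1L
    tabulate_sum(c(mag * (1 - frac), mag * frac), c(idx0, idx1), ch * cw * B)
  }
  meta_fun <- function() {
    ch <- d0[1L] %/% cell; cw <- d0[2L] %/% cell
    data.frame(coord1 = rep(seq_len(ch), each = B, times = cw),
               coord2 = rep(seq_len(cw), each = ch * B),
               coord3 = rep(seq_len(B), ch * cw))
  }
  per_layer_extract(images, cfg, "hog", layer_fun, meta_fun)
}

#' Color value distribution features
#'
#' Per layer, the probability of pixel values falling into each of
#' `color_bins` fixed bins (so bins are comparable across images). Bin ranges
#' are `[0, 1]` for gray/RGB input, and `[0, 100]` (L*) / `[-128, 127]`
#' (a*, b*) for CIELAB. Features of different layers are never linked:
#' cross-layer linking of distribution bins is meaningless.
#'
#' @inheritParams extract_fourier_magnitude
#' @return a [feature_matrix()]; each layer's bins sum to 1 per image.
#' @export
extract_color_histogram <- function(images, cfg = feature_config()) {
  nb <- cfg$color_bins
  nl <- n_layers(images$images[[1L]])
  ranges <- if (images$colorspace == "lab") {
    if (nl < 2L) stop("lab color histograms need the multi-layer lab image")
    list(c(0, 100), c(-128, 127), c(-128, 127))[seq_len(nl)]
  } else rep(list(c(0, 1)), nl)
  blocks <- vector("list", nl)
  for (l in seq_len(nl)) {
    rg <- ranges[[l]]
    blocks[[l]] <- t(vapply(images$images, function(im) {
      v <- as.numeric(get_layer(im, l))
      b <- pmin(pmax(floor((v - rg[1L]) / diff(rg) * nb), 0), nb - 1L) + 1L
      tabulate(b, nb) / length(v)
    }, numeric(nb)))
  }
  meta <- do.call(rbind, lapply(seq_len(nl), function(l)
    data.frame(space = "color_hist", layer = l, coord1 = seq_len(nb),
               coord2 = NA_integer_, coord3 = NA_integer_)))
  feature_matrix(do.call(cbind, blocks), images$labels, meta,
                 seq_len(nb * nl), sources = images$sources)
}

#' Downscaled pixel-intensity features
#'
#' Each layer is downscaled (bicubic) to `downsample_size` squared pixels and
#' vectorized row-major; no other transformation. These features are fully
#' position-specific.
#'
#' @inheritParams extract_fourier_magnitude
#' @return a [feature_matrix()]; `coord1`/`coord2` give the pixel row/column
#'   in the downscaled grid.
#' @export
extract_pixel_intensities <- function(images, cfg = feature_config()) {
  ds <- cfg$downsample_size
  layer_fun <- function(m) {
    if (all(dim(m) == c(ds, ds))) as.numeric(t(m))
    else as.numeric(t(resize_bicubic(m, ds, ds)))
  }
  meta_fun <- function() data.frame(
    coord1 = rep(seq_len(ds), each = ds),
    coord2 = rep(seq_len(ds), ds), coord3 = NA_integer_)
  per_layer_extract(images, cfg, "pixel", layer_fun, meta_fun)
}

#' Extract several feature spaces at once
#'
#' Runs the requested extractors and binds the results into one
#' [feature_matrix()] with disjoint link groups.
#'
#' @inheritParams extract_fourier_magnitude
#' @param spaces character subset of `"fourier_mag"`, `"fourier_phase"`,
#'   `"hog"`, `"color_hist"`, `"pixel"`.
#' @return a [feature_matrix()].
#' @export
extract_features <- function(images, spaces = c("fourier_mag", "hog"),
                             cfg = feature_config()) {
  known <- c("fourier_mag", "fourier_phase", "hog", "color_hist", "pixel")
  bad <- setdiff(spaces, known)
  if (length(bad)) stop("unknown feature space(s): ", paste(bad, collapse = ", "))
  fms <- lapply(spaces, function(s) switch(s,
    fourier_mag = extract_fourier_magnitude(images, cfg),
    fourier_phase = extract_fourier_phase(images, cfg),
    hog = extract_hog(images, cfg),
    color_hist = extract_color_histogram(images, cfg),
    pixel = extract_pixel_intensities(images, cfg)))
  if (length(fms) == 1L) fms[[1L]] else combine_features(fms)
}
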