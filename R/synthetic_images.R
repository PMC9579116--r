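#' Generate a synthetic two-category image set with a localized difference
#'
#' A fully synthetic stand-in for face-photograph experiments (e.g. open
#' versus closed mouths): both categories share the same face-like layout —
#' a bright oval on a dark background with two dark "eye" blobs — and differ
#' only inside a localized lower-central "mouth" region, where category 1
#' carries a thin dark line and category 2 a filled dark ellipse. Images are
#' generated as matched pairs: the i-th image of each category shares the
#' identical noise field, position jitter, amplitude and brightness draw, so
#' outside the mouth region the two categories are *exactly* identical (the
#' controlled-stimulus analogue of the mock data's exact whole-set null) and
#' the region is the only difference, systematic or sampled. Useful for
#' checking that spatially specific features (HOG, pixel intensities)
#' concentrate their relevance inside the differing region.
#'
#' @param n_per_class images per category (default 80).
#' @param size image side length in pixels (default 60).
#' @param noise_sd pixel noise SD on the `[0, 1]` intensity scale (default
#'   0.16, which puts holdout decoding in the hard-but-decodable regime
#'   typical of natural-image category pairs).
#' @param seed optional integer seed.
#' @return list with `images` (an [image_set()], grayscale, labels 1/2) and
#'   `region` (`list(rows =, cols =)` — the pixel rows/columns of the
#'   differing mouth region).
#' @export
synthetic_face_set <- function(n_per_class = 80L, size = 60L,
                               noise_sd = 0.16, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- size
  cx <- s / 2; cy <- s / 2
  rr <- matrix(seq_len(s), s, s); cc <- t(rr)
  oval <- exp(-(((rr - cy) / (0.42 * s))^2 + ((cc - cx) / (0.33 * s))^2)^2)
  eye <- function(ex, ey) exp(-(((rr - ey) / (0.035 * s))^2 +
                                  ((cc - ex) / (0.05 * s))^2))
  eyes <- eye(0.35 * s, 0.38 * s) + eye(0.65 * s, 0.38 * s)
  mouth_rows <- round(0.62 * s):round(0.78 * s)
  mouth_cols <- round(0.28 * s):round(0.72 * s)
  imgs <- vector("list", 2L * n_per_class)
  labels <- rep(1:2, each = n_per_class)
  base <- 0.25 + 0.55 * oval - 0.35 * eyes
  for (i in seq_len(n_per_class)) {
    jx <- stats::runif(1, -0.015, 0.015) * s
    jy <- stats::runif(1, -0.015, 0.015) * s
    amp <- stats::runif(1, 0.85, 1)
    bright <- stats::runif(1, -0.03, 0.03)
    noise <- matrix(stats::rnorm(s * s, sd = noise_sd), s, s)
    # closed mouth: thin dark horizontal line
    line <- exp(-(((rr - (0.70 * s + jy)) / (0.012 * s))^2 +
                    ((cc - (cx + jx)) / (0.19 * s))^4))
    # open mouth: filled dark ellipse
    open_m <- exp(-(((rr - (0.70 * s + jy)) / (0.055 * s))^2 +
                      ((cc - (cx + jx)) / (0.16 * s))^2)^2)
    for (cl in 1:2) {
      im <- base - 0.5 * amp * (if (cl == 1L) line else open_m) +
        bright + noise
      im[im < 0] <- 0; im[im > 1] <- 1
      imgs[[(cl - 1L) * n_per_class + i]] <- im
    }
  }
  list(images = image_set(imgs, labels, color_mode = "gray"),
       region = list(rows = mouth_rows, cols = mouth_cols))
}
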