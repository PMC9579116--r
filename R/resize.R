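#' Bicubic image resampling
#'
#' Separable bicubic interpolation with the Keys kernel (a = -0.5). When
#' shrinking, the kernel support is widened by the scale factor (antialiasing,
#' the behavior of mainstream image-processing resizers), which averages over
#' the source pixels that map into each target pixel; set `antialias = FALSE`
#' for plain interpolation. Border handling replicates edge pixels.
#'
#' @param im numeric matrix or multi-layer array.
#' @param out_h,out_w target height and width in pixels.
#' @param antialias widen the kernel when downscaling (default `TRUE`).
#' @return resampled matrix / array of size `out_h x out_w`.
#' @export
resize_bicubic <- function(im, out_h, out_w, antialias = TRUE) {
  if (length(dim(im)) == 3L) {
    out <- array(0, c(out_h, out_w, dim(im)[3L]))
    for (l in seq_len(dim(im)[3L]))
      out[, , l] <- resize_bicubic(im[, , l], out_h, out_w, antialias)
    return(out)
  }
  wr <- cubic_weights(nrow(im), out_h, antialias)
  wc <- cubic_weights(ncol(im), out_w, antialias)
  wr %*% im %*% t(wc)
}

# Keys cubic convolution kernel, a = -0.5
cubic_kernel <- function(x) {
  x <- abs(x)
  ifelse(x <= 1, 1.5 * x^3 - 2.5 * x^2 + 1,
         ifelse(x < 2, -0.5 * x^3 + 2.5 * x^2 - 4 * x + 2, 0))
}

# Dense out_n x in_n weight matrix mapping source samples to target samples.
# Pixel centers sit at (i - 0.5) / n in unit coordinates; rows are normalized
# to sum to one so constant images are preserved exactly.
cubic_weights <- function(in_n, out_n, antialias = TRUE) {
  scale <- out_n / in_n
  k <- if (antialias && scale < 1) scale else 1
  support <- 2 / k
  u <- ((seq_len(out_n) - 0.5) / scale) + 0.5   # target center in source coords
  w <- matrix(0, out_n, in_n)
  for (i in seq_len(out_n)) {
    lo <- max(1L, floor(u[i] - support))
    hi <- min(in_n, ceiling(u[i] + support))
    j <- lo:hi
    w[i, j] <- cubic_kernel((j - u[i]) * k)
    # replicate borders: fold weight of out-of-range taps onto edge pixels
    jr <- floor(u[i] - support):ceiling(u[i] + support)
    outside <- jr[jr < 1L | jr > in_n]
    if (length(outside)) {
      wt <- cubic_kernel((outside - u[i]) * k)
      w[i, 1L] <- w[i, 1L] + sum(wt[outside < 1L])
      w[i, in_n] <- w[i, in_n] + sum(wt[outside > in_n])
    }
    s <- sum(w[i, ])
    if (s != 0) w[i, ] <- w[i, ] / s
  }
  w
}
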