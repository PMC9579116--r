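#' Read a raster image from disk
#'
#' Supports PNG, JPEG, TIFF (via the png/jpeg/tiff packages) and uncompressed
#' 8/24/32-bit BMP (built-in reader). Intensities are returned in `[0, 1]` as
#' a matrix (grayscale) or an `h x w x 3` array (color); an alpha channel, if
#' present, is dropped.
#'
#' @param path path to an image file.
#' @return numeric matrix or 3-layer array with values in `[0, 1]`.
#' @export
read_raster_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    bmp  = read_bmp(path),
    stop("unsupported image format '", ext, "' for file: ", path))
  if (length(dim(img)) == 3L && dim(img)[3L] >= 4L)
    img <- img[, , 1:3, drop = FALSE]
  if (length(dim(img)) == 3L && dim(img)[3L] == 1L) img <- img[, , 1L]
  img
}

# Minimal BMP reader: uncompressed (BI_RGB) 8-bit palette or 24/32-bit files,
# the variants produced by common scientific tooling.
read_bmp <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  u16 <- function(i) sum(as.integer(raw[i + 0:1]) * c(1, 256))
  u32 <- function(i) sum(as.integer(raw[i + 0:3]) * 256^(0:3))
  if (rawToChar(raw[1:2]) != "BM") stop("not a BMP file: ", path)
  off <- u32(11L); hdr <- u32(15L)
  w <- u32(19L); h <- u32(23L); bpp <- u16(29L); comp <- u32(31L)
  if (comp != 0) stop("compressed BMP not supported: ", path)
  if (!bpp %in% c(8L, 24L, 32L)) stop("unsupported BMP depth: ", bpp)
  bypp <- bpp %/% 8L
  stride <- ((w * bypp + 3L) %/% 4L) * 4L
  if (bpp == 8L) {
    pal_n <- (off - 14L - hdr) %/% 4L
    pal <- matrix(as.integer(raw[14L + hdr + seq_len(pal_n * 4L)]), 4L)[3:1, ,
                                                                        drop = FALSE]
    out <- array(0, c(h, w, 3L))
    for (r in seq_len(h)) {
      row <- as.integer(raw[off + (h - r) * stride + seq_len(w)]) + 1L
      out[r, , ] <- t(pal[, row]) / 255
    }
  } else {
    out <- array(0, c(h, w, 3L))
    for (r in seq_len(h)) {
      row <- as.integer(raw[off + (h - r) * stride + seq_len(w * bypp)])
      px <- matrix(row, nrow = bypp)
      out[r, , ] <- t(px[3:1, , drop = FALSE]) / 255
    }
  }
  if (all(out[, , 1L] == out[, , 2L]) && all(out[, , 2L] == out[, , 3L]))
    out[, , 1L] else out
}

#' Load a categorized image set
#'
#' Builds an `image_set` from either (a) a vector of directories, one per
#' category, with the directory order defining label numbering; or (b) a
#' delimited label-list file with header `label,filepath` (one numeric label
#' and one image path per row), mirroring the two-column list convention used
#' for behavior-based categories.
#'
#' @param paths character vector of directories (one category each). Ignored
#'   when `label_file` is given.
#' @param label_file CSV file with columns `label` (numeric) and `filepath`.
#' @param color_mode `"gray"`, `"rgb"` or `"lab"`; color conversion applied
#'   after loading. Grayscale input is accepted only for `"gray"`.
#' @param layers optional integer subset of layers to keep after conversion
#'   (e.g. `c(2, 3)` for a*, b* under `"lab"`).
#' @param pattern filename filter passed to [list.files()].
#' @return An object of class `image_set`: list of per-image intensity arrays
#'   plus `labels`, `sources` and `colorspace`.
#' @export
load_image_set <- function(paths = NULL, label_file = NULL,
                           color_mode = c("gray", "rgb", "lab"),
                           layers = NULL,
                           pattern = "\\.(png|jpe?g|tiff?|bmp)$") {
  color_mode <- match.arg(color_mode)
  if (!is.null(label_file)) {
    tab <- read.csv(label_file)
    if (!all(c("label", "filepath") %in% names(tab)))
      stop("label file must have columns 'label' and 'filepath'")
    if (!is.numeric(tab$label))
      stop("label file contains non-numeric labels")
    files <- tab$filepath
    labels <- as.integer(tab$label)
  } else {
    if (is.null(paths)) stop("supply `paths` or `label_file`")
    files <- character(0); labels <- integer(0)
    for (i in seq_along(paths)) {
      fs <- sort(list.files(paths[i], pattern = pattern, full.names = TRUE,
                            ignore.case = TRUE))
      if (length(fs) == 0L) stop("no image files found in: ", paths[i])
      files <- c(files, fs)
      labels <- c(labels, rep(i, length(fs)))
    }
  }
  if (length(unique(labels)) < 2L)
    stop("need at least 2 categories of images")
  imgs <- lapply(files, read_raster_image)
  image_set(imgs, labels, sources = files, color_mode = color_mode,
            layers = layers)
}

#' Construct an image set from in-memory arrays
#'
#' @param images list of matrices (grayscale) or `h x w x 3` arrays (RGB in
#'   `[0, 1]`).
#' @param labels positive integer category labels, one per image.
#' @param sources optional provenance strings.
#' @param color_mode target colorspace, as in [load_image_set()].
#' @param layers optional layer subset applied after conversion.
#' @return An `image_set`.
#' @export
image_set <- function(images, labels, sources = NULL,
                      color_mode = c("gray", "rgb", "lab"), layers = NULL) {
  color_mode <- match.arg(color_mode)
  labels <- as.integer(labels)
  if (length(images) != length(labels))
    stop("every image needs exactly one label")
  if (length(unique(labels)) < 2L)
    stop("need at least 2 distinct labels")
  if (is.null(sources)) sources <- paste0("synthetic:", seq_along(images))
  images <- lapply(images, convert_image, color_mode = color_mode)
  if (!is.null(layers)) {
    images <- lapply(images, function(im) {
      if (length(dim(im)) == 2L) {
        if (!identical(as.integer(layers), 1L))
          stop("layer subset ", paste(layers, collapse = ","),
               " invalid for single-layer image")
        im
      } else {
        if (any(layers < 1L | layers > dim(im)[3L]))
          stop("layer index out of range")
        out <- im[, , layers, drop = FALSE]
        if (dim(out)[3L] == 1L) out[, , 1L] else out
      }
    })
  }
  nl <- vapply(images, n_layers, 1L)
  if (length(unique(nl)) != 1L)
    stop("all images must have the same number of layers after layer selection")
  structure(list(images = images, labels = labels, sources = sources,
                 colorspace = color_mode),
            class = "image_set")
}

#' @export
print.image_set <- function(x, ...) {
  dims <- vapply(x$images, function(im) paste(dim(im)[1:2], collapse = "x"), "")
  cat(sprintf("<image_set> %d images (%s), %d layer(s), colorspace %s\n",
              length(x$images), paste(unique(dims), collapse = ", "),
              n_layers(x$images[[1L]]), x$colorspace))
  print(table(labels = x$labels))
  invisible(x)
}

n_layers <- function(im) if (length(dim(im)) == 2L) 1L else dim(im)[3L]

get_layer <- function(im, l) if (length(dim(im)) == 2L) im else im[, , l]

convert_image <- function(im, color_mode) {
  im[im < 0] <- 0; im[im > 1] <- 1
  gray_wt <- c(0.299, 0.587, 0.114)
  if (length(dim(im)) == 2L) {
    if (color_mode != "gray")
      stop("grayscale input cannot be converted to ", color_mode)
    return(im)
  }
  switch(color_mode,
    gray = {
      g <- im[, , 1L] * gray_wt[1L] + im[, , 2L] * gray_wt[2L] +
        im[, , 3L] * gray_wt[3L]
      g
    },
    rgb = im,
    lab = rgb_to_lab(im))
}

# sRGB (D65) -> CIELAB via grDevices::convertColor.
rgb_to_lab <- function(im) {
  d <- dim(im)
  px <- matrix(im, ncol = 3L)
  lab <- grDevices::convertColor(px, from = "sRGB", to = "Lab")
  array(lab, d)
}
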