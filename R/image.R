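#' Read an 8-bit RGB leaf image
#'
#' Reads PNG or TIFF into a `height x width x 3` numeric array of channel
#' intensities on the 0--255 scale (values are integers as stored in the
#' 8-bit file). Grayscale input is replicated across channels; an alpha
#' channel, if present, is dropped.
#'
#' @param path Image file; format chosen by extension (.png, .tif/.tiff).
#' @return Numeric array `h x w x 3`, channels ordered R, G, B.
#' @export
read_rgb <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext)
  )
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]
  if (dim(a)[3] < 3) stop("expected 3 channels, got ", dim(a)[3])
  round(a * 255)
}

#' @rdname read_rgb
#' @param img Numeric array `h x w x 3`, intensities in 0--255.
#' @export
write_rgb <- function(img, path) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  ext <- tolower(tools::file_ext(path))
  a <- pmin(pmax(img, 0), 255) / 255
  switch(ext,
    png = png::writePNG(a, path),
    tif = ,
    tiff = tiff::writeTIFF(a, path, bits.per.sample = 8L),
    stop("unsupported image format: ", ext)
  )
  invisible(path)
}

.check_rgb <- function(img) {
  if (length(dim(img)) != 3 || dim(img)[3] != 3) {
    stop("image must be an h x w x 3 array")
  }
  if (min(img) < 0 || max(img) > 255) stop("intensities must lie in [0, 255]")
  invisible(TRUE)
}

#' Segment the leaf from a bright background
#'
#' Leaves are photographed on a bright plane, so background pixels are the
#' bright class: a pixel is foreground when its minimum channel intensity is
#' at or below `bright_threshold`. Of the foreground, only the largest
#' 4-connected component is kept (stray dark specks are discarded).
#'
#' @param img RGB array as from [read_rgb()].
#' @param bright_threshold Pixels whose minimum channel exceeds this are
#'   background (default 240 on the 0--255 scale).
#' @param min_pixels Minimum foreground size required for downstream
#'   resampling; fewer raises an error.
#' @return Logical matrix (`h x w`), `TRUE` on leaf pixels.
#' @export
segment_leaf <- function(img, bright_threshold = 240, min_pixels = 50L) {
  .check_rgb(img)
  fg <- pmin(img[, , 1], img[, , 2], img[, , 3]) <= bright_threshold
  if (!any(fg)) stop("segmentation found no leaf pixels (empty mask)")
  lab <- EBImage::bwlabel(fg * 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  mask <- lab == keep
  if (sum(mask) < min_pixels) {
    stop("largest foreground component has ", sum(mask),
         " pixels (< min_pixels = ", min_pixels, ")")
  }
  mask
}

.check_attrs <- function(attrs) {
  attrs <- as.character(attrs)
  if (length(attrs) == 0 || !all(attrs %in% c("R", "G", "B"))) {
    stop("attrs must be a nonempty subset of c(\"R\", \"G\", \"B\")")
  }
  attrs
}

# masked pixel values as an (n_pixels x n_attrs) matrix
.pixel_pool <- function(img, mask, attrs) {
  attrs <- .check_attrs(attrs)
  ch <- match(attrs, c("R", "G", "B"))
  out <- vapply(ch, function(k) img[, , k][mask], numeric(sum(mask)))
  colnames(out) <- attrs
  out
}

#' Mean band intensities over the leaf mask
#'
#' The attribute vector of an image: the arithmetic mean of each selected
#' channel over the masked (leaf) pixels.
#'
#' @param img RGB array.
#' @param mask Logical matrix from [segment_leaf()].
#' @param attrs Channels to use, a subset of `c("R", "G", "B")`.
#' @return Named numeric vector, one mean per channel.
#' @export
band_means <- function(img, mask, attrs = c("R", "G", "B")) {
  .check_rgb(img)
  if (!is.logical(mask) || !identical(dim(mask), dim(img)[1:2])) {
    stop("mask must be a logical matrix matching the image")
  }
  if (!any(mask)) stop("empty mask")
  colMeans(.pixel_pool(img, mask, attrs))
}

#' Draw a pixel-resampling image
#'
#' Samples `n` leaf pixels uniformly with replacement from the masked
#' region; the draw is a pseudo-image ("pixel-resampling image") used to
#' estimate within-image variability of the band means.
#'
#' @param img RGB array.
#' @param mask Logical leaf mask.
#' @param n Pixels to draw; must satisfy `1 <= n < sum(mask)`.
#' @param seed Optional integer seed for a reproducible draw.
#' @return Object of class `pixel_resample`: an `n x 3` matrix of channel
#'   intensities with attribute `n`.
#' @export
resample_pixels <- function(img, mask, n, seed = NULL) {
  .check_rgb(img)
  total <- sum(mask)
  n <- as.integer(n)
  if (is.na(n) || n < 1L || n >= total) {
    stop("n must satisfy 1 <= n < ", total, " (masked pixel count)")
  }
  pool <- .pixel_pool(img, mask, c("R", "G", "B"))
  draw <- function() pool[sample.int(total, n, replace = TRUE), , drop = FALSE]
  out <- if (is.null(seed)) draw() else with_seed(seed, draw())
  structure(out, n = n, class = "pixel_resample")
}

#' Mean attribute vector of a pixel resample
#'
#' @param resample A [resample_pixels()] result.
#' @param attrs Channels to average.
#' @return Named numeric vector of per-channel means.
#' @export
resample_mean <- function(resample, attrs = c("R", "G", "B")) {
  attrs <- .check_attrs(attrs)
  colMeans(unclass(resample)[, attrs, drop = FALSE])
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
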