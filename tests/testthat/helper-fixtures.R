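# small programmatic image fixtures shared across test files

const_img <- function(h, w, r, g, b) {
  arr <- array(0, c(h, w, 3))
  arr[, , 1] <- r; arr[, , 2] <- g; arr[, , 3] <- b
  arr
}

full_mask <- function(img) {
  matrix(TRUE, dim(img)[1], dim(img)[2])
}

ellipse_mask <- function(h, w, rx = 0.40, ry = 0.28) {
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((xx - (w + 1) / 2) / (rx * w))^2 + ((yy - (h + 1) / 2) / (ry * h))^2 <= 1
}

# leaf-like image: masked pixels ~ N(mean, sd) clipped to [0,255],
# bright background elsewhere
noise_leaf_img <- function(h, w, mean, sd, mask = ellipse_mask(h, w),
                           bg = 250) {
  arr <- array(bg, c(h, w, 3))
  for (c in 1:3) {
    plane <- matrix(bg, h, w)
    plane[mask] <- round(pmin(pmax(rnorm(sum(mask), mean, sd), 0), 255))
    arr[, , c] <- plane
  }
  arr
}

# spectra fixture on a small grid
toy_spectra <- function(values, wl = NULL) {
  values <- as.matrix(values)
  if (is.null(wl)) wl <- seq(900, 1700, length.out = ncol(values))
  spectra_matrix(values, wl)
}
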