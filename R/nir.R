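#' Samples-by-wavelengths absorbance matrix
#'
#' Container for a set of NIR spectra sharing one wavelength grid.
#'
#' @param values Numeric matrix, samples in rows, wavelengths in columns.
#' @param wavelengths Numeric vector (nm), strictly increasing, one per
#'   column.
#' @param sample_ids Optional row identifiers (default taken from rownames).
#' @return Object of class `spectra_matrix`: the matrix with a
#'   `wavelengths` attribute and sample ids as rownames.
#' @export
spectra_matrix <- function(values, wavelengths, sample_ids = rownames(values)) {
  values <- as.matrix(values)
  wavelengths <- as.numeric(wavelengths)
  if (ncol(values) != length(wavelengths)) {
    stop("ncol(values) must equal length(wavelengths)")
  }
  if (length(wavelengths) > 1 && any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing")
  }
  if (anyNA(values)) stop("spectra contain missing values")
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(nrow(values)))
  rownames(values) <- sample_ids
  colnames(values) <- format(wavelengths, trim = TRUE)
  structure(values, wavelengths = wavelengths, class = "spectra_matrix")
}

#' @export
print.spectra_matrix <- function(x, ...) {
  wl <- attr(x, "wavelengths")
  cat("Spectra matrix:", nrow(x), "samples x", ncol(x), "wavelengths (",
      min(wl), "-", max(wl), "nm )\n")
  invisible(x)
}

.as_spectra <- function(m) {
  if (!inherits(m, "spectra_matrix")) stop("expected a spectra_matrix")
  m
}

# rebuild the container around transformed values, keeping the grid
.respectra <- function(values, template) {
  spectra_matrix(values, attr(template, "wavelengths"), rownames(template))
}

#' Savitzky-Golay smoothing and derivatives
#'
#' Applies a local least-squares polynomial filter to each spectrum. With
#' `deriv > 0` the filter estimates the derivative of that order. Edges are
#' handled by evaluating the polynomial fitted to the first/last full
#' window at the edge positions (no row shortening), so the attribute
#' count is unchanged. Derivatives are scaled per channel step by default
#' (`delta = 1`); pass `delta = diff(wavelengths)[1]` for per-nm units --
#' a pure rescaling that does not affect standardized distances downstream.
#'
#' @param m A [spectra_matrix()].
#' @param window Odd window length, greater than `degree`.
#' @param degree Polynomial degree.
#' @param deriv Derivative order (0 = smoothing), at most `degree`.
#' @param delta Abscissa step used to scale derivatives.
#' @return A [spectra_matrix()] of the same shape.
#' @export
sg_filter <- function(m, window = 5L, degree = 2L, deriv = 0L, delta = 1) {
  m <- .as_spectra(m)
  window <- as.integer(window); degree <- as.integer(degree)
  deriv <- as.integer(deriv)
  if (window %% 2L == 0L) stop("window must be odd")
  if (window <= degree) stop("window must exceed degree")
  if (deriv < 0L || deriv > degree) stop("deriv must lie in 0..degree")
  if (ncol(m) < window) stop("spectra shorter than the filter window")
  vals <- t(apply(unclass(m), 1, signal::sgolayfilt,
                  p = degree, n = window, m = deriv, ts = delta))
  .respectra(vals, m)
}

#' Finite-difference spectral derivative
#'
#' Plain difference-quotient alternative to Savitzky-Golay derivatives:
#' central differences in the interior, one-sided at the edges, so row
#' length is preserved.
#'
#' @param m A [spectra_matrix()].
#' @param order 1 or 2.
#' @param delta Abscissa step (default 1: per channel index).
#' @return A [spectra_matrix()] of the same shape.
#' @export
fd_derivative <- function(m, order = 1L, delta = 1) {
  m <- .as_spectra(m)
  if (!order %in% c(1L, 2L)) stop("order must be 1 or 2")
  if (ncol(m) < 3) stop("need at least 3 channels")
  x <- unclass(m)
  d1 <- function(v) {
    n <- length(v)
    c(v[2] - v[1], (v[3:n] - v[1:(n - 2)]) / 2, v[n] - v[n - 1]) / delta
  }
  vals <- t(apply(x, 1, if (order == 1L) d1 else function(v) d1(d1(v))))
  .respectra(vals, m)
}

#' Multiplicative scatter correction
#'
#' Each spectrum is regressed on a reference spectrum by ordinary least
#' squares, `x_i = b_i + a_i * ref + e`, and corrected to
#' `(x_i - b_i) / a_i`. Removes per-sample multiplicative scatter (slope)
#' and additive offset relative to the reference.
#'
#' @param m A [spectra_matrix()].
#' @param reference `"mean"` (the column-mean spectrum of `m`, the usual
#'   convention) or a numeric vector of length `ncol(m)`.
#' @return A [spectra_matrix()] of corrected spectra.
#' @export
msc <- function(m, reference = "mean") {
  m <- .as_spectra(m)
  x <- unclass(m)
  if (identical(reference, "mean")) {
    if (nrow(x) < 2) stop("reference = \"mean\" needs at least 2 samples")
    ref <- colMeans(x)
  } else {
    ref <- as.numeric(reference)
    if (length(ref) != ncol(x)) stop("reference length must match ncol(m)")
  }
  vref <- stats::var(ref)
  if (vref < .Machine$double.eps) stop("reference spectrum has zero variance")
  rc <- ref - mean(ref)
  a <- as.numeric(x %*% rc) / sum(rc^2)   # OLS slope per row
  b <- rowMeans(x) - a * mean(ref)
  vals <- sweep(x, 1, b, "-") / as.numeric(a)
  .respectra(vals, m)
}

#' Mean centering
#'
#' Subtracts the column (wavelength-wise) mean from every spectrum, so each
#' wavelength has mean zero across samples.
#'
#' @param m A [spectra_matrix()].
#' @return A centered [spectra_matrix()].
#' @export
mean_center <- function(m) {
  m <- .as_spectra(m)
  if (nrow(m) < 2) {
    warning("mean centering a single spectrum returns zeros")
  }
  .respectra(scale(unclass(m), center = TRUE, scale = FALSE), m)
}

#' Pretreatment pipeline
#'
#' Parses a pipeline signature such as `"SG(5,2)+D1+MSC+MC"` into an ordered
#' list of steps. Recognised steps: `SG(window,degree)` (smoothing; bare
#' `SG` means `SG(5,2)`), `D1`/`D2` (first/second derivative, realised as
#' Savitzky-Golay derivatives sharing the pipeline's SG window and degree),
#' `MSC` and `MC`. Steps are applied left to right by [apply_pipeline()].
#'
#' @param signature Pipeline string, steps joined by `+`; `""` is the
#'   identity pipeline.
#' @param window,degree Savitzky-Golay parameters used when the signature
#'   contains no explicit `SG(w,d)`.
#' @param derivative_method `"sg"` (default) or `"fd"` for plain finite
#'   differences in `D1`/`D2`.
#' @return Object of class `nir_pipeline`.
#' @examples
#' nir_pipeline("SG(5,2)+D1+MSC+MC")
#' @export
nir_pipeline <- function(signature = "", window = 5L, degree = 2L,
                         derivative_method = c("sg", "fd")) {
  derivative_method <- match.arg(derivative_method)
  signature <- gsub("[[:space:]]", "", signature)
  toks <- if (nzchar(signature)) strsplit(signature, "+", fixed = TRUE)[[1]]
          else character(0)
  steps <- list()
  for (tk in toks) {
    if (grepl("^SG(\\([0-9]+,[0-9]+\\))?$", tk)) {
      if (grepl("\\(", tk)) {
        par <- as.integer(strsplit(gsub("^SG\\(|\\)$", "", tk), ",")[[1]])
        window <- par[1]; degree <- par[2]
      }
      steps <- c(steps, list(list(type = "SG")))
    } else if (tk %in% c("D1", "D2", "MSC", "MC")) {
      steps <- c(steps, list(list(type = tk)))
    } else {
      stop("unknown pipeline step: ", tk)
    }
  }
  window <- as.integer(window); degree <- as.integer(degree)
  if (window %% 2L == 0L || window <= degree) {
    stop("SG window must be odd and exceed the degree")
  }
  structure(
    list(steps = steps, window = window, degree = degree,
         derivative_method = derivative_method),
    class = "nir_pipeline"
  )
}

#' @rdname nir_pipeline
#' @param p An `nir_pipeline`.
#' @export
pipeline_signature <- function(p) {
  stopifnot(inherits(p, "nir_pipeline"))
  if (length(p$steps) == 0) return("")
  paste(vapply(p$steps, function(s) {
    if (s$type == "SG") sprintf("SG(%d,%d)", p$window, p$degree) else s$type
  }, character(1)), collapse = "+")
}

#' @export
print.nir_pipeline <- function(x, ...) {
  sig <- pipeline_signature(x)
  cat("NIR pretreatment pipeline:",
      if (nzchar(sig)) sig else "(identity)", "\n")
  invisible(x)
}

#' Apply a pretreatment pipeline
#'
#' Applies the pipeline's steps left to right. The result carries the
#' pipeline signature in its `"pipeline"` attribute.
#'
#' @param m A [spectra_matrix()].
#' @param p An [nir_pipeline()] or a signature string.
#' @return The pretreated [spectra_matrix()].
#' @export
apply_pipeline <- function(m, p) {
  m <- .as_spectra(m)
  if (is.character(p)) p <- nir_pipeline(p)
  stopifnot(inherits(p, "nir_pipeline"))
  out <- m
  for (k in seq_along(p$steps)) {
    s <- p$steps[[k]]
    out <- tryCatch(
      switch(s$type,
        SG = sg_filter(out, p$window, p$degree, 0L),
        D1 = if (p$derivative_method == "sg") {
          sg_filter(out, p$window, p$degree, 1L)
        } else fd_derivative(out, 1L),
        D2 = if (p$derivative_method == "sg") {
          sg_filter(out, p$window, p$degree, 2L)
        } else fd_derivative(out, 2L),
        MSC = msc(out),
        MC = mean_center(out)
      ),
      error = function(e) {
        stop("pipeline step ", k, " (", s$type, ") failed: ",
             conditionMessage(e), call. = FALSE)
      }
    )
  }
  attr(out, "pipeline") <- pipeline_signature(p)
  out
}

#' Read or write spectra as CSV
#'
#' Format: first column `sample_id`, remaining column headers the
#' wavelengths in nm. The reader validates a shared, strictly increasing
#' grid and the absence of missing values.
#'
#' @param path CSV path.
#' @return `read_spectra()` returns a [spectra_matrix()].
#' @export
read_spectra <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "sample_id") stop("first column must be sample_id")
  wl <- as.numeric(names(df)[-1])
  if (anyNA(wl)) stop("column headers after sample_id must be wavelengths")
  spectra_matrix(as.matrix(df[, -1, drop = FALSE]), wl, df$sample_id)
}

#' @rdname read_spectra
#' @param m A [spectra_matrix()] to serialise.
#' @export
write_spectra <- function(m, path) {
  m <- .as_spectra(m)
  df <- data.frame(sample_id = rownames(m), unclass(m), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
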