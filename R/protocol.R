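#' Configuration of the pixel-resampling Mahalanobis protocol
#'
#' @param n_pixels Pixels per resampling image. The default (`NULL`)
#'   resolves, per pair of images, to the harmonic mean of the two mask
#'   sizes (capped one below the smaller mask): with resamples of that
#'   size, the within-resample variance of a band mean matches the
#'   sampling variance of the full-image mean, which is what makes the
#'   D-squared statistic comparable to a chi-squared distribution under
#'   the null. Any explicit value `1 <= n < min(mask sizes)` is accepted.
#' @param n_resamples Number of pixel-resampling images per original image
#'   (`P`, default 100).
#' @param attrs Channels used as attributes, subset of `c("R","G","B")`
#'   (default `"R"`: the red band alone was found sufficient in the
#'   first-stage screening).
#' @param pairing How resampling images are paired for the "within"
#'   differences: `"within"` (default) pairs consecutive disjoint
#'   resamples of the SAME image (1-2, 3-4, ...) and pools both images,
#'   matching the ANOVA within-treatment reading; `"cross"` pairs resample
#'   i of image A with resample i of image B (literal reading, kept for
#'   auditability -- its within mean converges to the between difference,
#'   degenerating the statistic).
#' @param cov_mode `"within"` (default): the combined covariance is the
#'   sample covariance of the within differences; `"pooled"` additionally
#'   includes the single between-difference vector as one observation
#'   (literal reading of the combined-matrix step).
#' @param singular `"error"` (default) or `"pseudoinverse"`: what to do
#'   when the covariance is singular.
#' @param seed Optional integer seed making the resampling reproducible.
#' @return Object of class `protocol_config`.
#' @export
protocol_config <- function(n_pixels = NULL, n_resamples = 100L,
                            attrs = "R",
                            pairing = c("within", "cross"),
                            cov_mode = c("within", "pooled"),
                            singular = c("error", "pseudoinverse"),
                            seed = NULL) {
  pairing <- match.arg(pairing)
  cov_mode <- match.arg(cov_mode)
  singular <- match.arg(singular)
  n_resamples <- as.integer(n_resamples)
  if (is.na(n_resamples) || n_resamples < 2L) stop("n_resamples must be >= 2")
  if (!is.null(n_pixels)) {
    n_pixels <- as.integer(n_pixels)
    if (is.na(n_pixels) || n_pixels < 1L) stop("n_pixels must be >= 1")
  }
  structure(
    list(n_pixels = n_pixels, n_resamples = n_resamples,
         attrs = .check_attrs(attrs), pairing = pairing,
         cov_mode = cov_mode, singular = singular, seed = seed),
    class = "protocol_config"
  )
}

#' @export
print.protocol_config <- function(x, ...) {
  cat("Pixel-resampling protocol config:\n")
  cat("  n_pixels:", if (is.null(x$n_pixels)) "auto (harmonic mean of masks)"
      else x$n_pixels, "\n")
  cat("  n_resamples:", x$n_resamples, " attrs:",
      paste(x$attrs, collapse = ","), "\n")
  cat("  pairing:", x$pairing, " cov_mode:", x$cov_mode, "\n")
  invisible(x)
}

# resolve the per-pair resample size from the two mask sizes
.resolve_n_pixels <- function(cfg, n_a, n_b) {
  lim <- min(n_a, n_b)
  if (lim < 2L) stop("masks too small for resampling")
  n <- cfg$n_pixels
  if (is.null(n)) {
    n <- min(as.integer(floor(2 / (1 / n_a + 1 / n_b))), lim - 1L)
  }
  n <- as.integer(n)
  if (n < 1L || n >= lim) {
    stop("n_pixels must satisfy 1 <= n < ", lim, " (smaller mask size)")
  }
  n
}

# P resample mean vectors (P x p matrix) from a pixel pool
.resample_means <- function(pool, n, P) {
  idx <- sample.int(nrow(pool), n * P, replace = TRUE)
  out <- matrix(0, P, ncol(pool))
  for (j in seq_len(ncol(pool))) {
    out[, j] <- .colMeans(pool[idx, j], n, P)
  }
  colnames(out) <- colnames(pool)
  out
}

# within differences from per-image resample mean matrices
.within_from_means <- function(ma, mb, pairing) {
  P <- nrow(ma)
  if (pairing == "cross") return(ma - mb)
  half <- seq_len(floor(P / 2))
  odd <- 2 * half - 1; even <- 2 * half
  rbind(ma[odd, , drop = FALSE] - ma[even, , drop = FALSE],
        mb[odd, , drop = FALSE] - mb[even, , drop = FALSE])
}

#' Within-image attribute differences from pixel resampling
#'
#' Draws `P` pixel-resampling images from each original image, takes each
#' resample's mean attribute vector, and forms the "within" difference
#' vectors according to the configured pairing scheme (default: disjoint
#' consecutive resamples of the same image, pooled over both images,
#' giving `2 * floor(P / 2)` differences).
#'
#' @param img_a,img_b RGB arrays.
#' @param mask_a,mask_b Logical leaf masks.
#' @param config A [protocol_config()].
#' @return Matrix of within-difference vectors (rows), one column per
#'   attribute, with attribute `n_pixels` recording the resolved resample
#'   size.
#' @export
within_differences <- function(img_a, mask_a, img_b, mask_b,
                               config = protocol_config()) {
  pool_a <- .pixel_pool(img_a, mask_a, config$attrs)
  pool_b <- .pixel_pool(img_b, mask_b, config$attrs)
  n <- .resolve_n_pixels(config, nrow(pool_a), nrow(pool_b))
  P <- config$n_resamples
  draw <- function() {
    ma <- .resample_means(pool_a, n, P)
    mb <- .resample_means(pool_b, n, P)
    .within_from_means(ma, mb, config$pairing)
  }
  w <- if (is.null(config$seed)) draw() else with_seed(config$seed, draw())
  colnames(w) <- config$attrs
  attr(w, "n_pixels") <- n
  w
}

#' Between-image attribute difference
#'
#' The difference between the full-mask mean attribute vectors of the two
#' original images (image A minus image B).
#'
#' @inheritParams within_differences
#' @param attrs Channels to use.
#' @return Named numeric vector.
#' @export
between_difference <- function(img_a, mask_a, img_b, mask_b, attrs = "R") {
  band_means(img_a, mask_a, attrs) - band_means(img_b, mask_b, attrs)
}

#' Combined covariance of attribute differences
#'
#' Sample covariance (denominator `n - 1`) of the within-difference
#' vectors; in `"pooled"` mode the single between-difference vector is
#' appended as one more observation before taking the covariance.
#'
#' @param within Matrix of within-difference vectors (rows).
#' @param between Between-difference vector (used in `"pooled"` mode).
#' @param mode `"within"` or `"pooled"`.
#' @return A `p x p` covariance matrix.
#' @export
combined_covariance <- function(within, between = NULL,
                                mode = c("within", "pooled")) {
  mode <- match.arg(mode)
  within <- as.matrix(within)
  x <- if (mode == "pooled") {
    if (is.null(between)) stop("pooled mode needs the between difference")
    rbind(within, matrix(between, nrow = 1))
  } else within
  p <- ncol(x)
  if (nrow(x) < p + 1) {
    stop("need at least ", p + 1, " difference vectors for a nonsingular ",
         p, "x", p, " covariance; raise n_resamples")
  }
  stats::cov(x)
}

#' Mahalanobis statistic of the protocol
#'
#' `D^2 = (between - within_mean)' S^{-1} (between - within_mean)`, the
#' squared Mahalanobis distance of the between-image difference from the
#' mean of the within differences, weighted by the combined covariance.
#'
#' @param between Between-difference vector (length `p`).
#' @param within_mean Mean of the within-difference vectors.
#' @param cov `p x p` covariance matrix.
#' @param singular `"error"` or `"pseudoinverse"` (Moore-Penrose, with a
#'   warning) for singular `cov`.
#' @return The nonnegative scalar `D^2`.
#' @export
d2_statistic <- function(between, within_mean, cov,
                         singular = c("error", "pseudoinverse")) {
  singular <- match.arg(singular)
  d <- as.numeric(between) - as.numeric(within_mean)
  cov <- as.matrix(cov)
  sol <- tryCatch(solve(cov, d), error = function(e) NULL)
  if (is.null(sol)) {
    if (singular == "error") {
      stop("combined covariance is singular; raise n_resamples or use ",
           "singular = \"pseudoinverse\"")
    }
    warning("singular covariance: using Moore-Penrose pseudoinverse")
    sol <- MASS::ginv(cov) %*% d
  }
  as.numeric(crossprod(d, sol))
}

#' Upper-tail chi-squared p-value for D^2
#'
#' Under multivariate normality the statistic is referred to a chi-squared
#' distribution with `p` degrees of freedom, `p` being the number of
#' attributes; the p-value is the upper-tail probability
#' `Pr(chi^2_p >= d2)`.
#'
#' @param d2 Nonnegative statistic value.
#' @param df Degrees of freedom (number of attributes, >= 1).
#' @return The p-value in `[0, 1]`.
#' @export
chisq_pvalue <- function(d2, df) {
  if (any(d2 < 0)) stop("d2 must be nonnegative")
  if (any(df < 1)) stop("df must be >= 1")
  stats::pchisq(d2, df = df, lower.tail = FALSE)
}

# core of the protocol, operating on precomputed pixel pools
.d2_from_pools <- function(pool_a, pool_b, cfg) {
  n <- .resolve_n_pixels(cfg, nrow(pool_a), nrow(pool_b))
  P <- cfg$n_resamples
  ma <- .resample_means(pool_a, n, P)
  mb <- .resample_means(pool_b, n, P)
  w <- .within_from_means(ma, mb, cfg$pairing)
  between <- colMeans(pool_a) - colMeans(pool_b)
  S <- combined_covariance(w, between, cfg$cov_mode)
  wm <- colMeans(w)
  d2 <- d2_statistic(between, wm, S, cfg$singular)
  p <- length(between)
  list(d2 = d2, df = p, p_value = chisq_pvalue(d2, p),
       between_diff = between, within_mean = wm, within_cov = S,
       n_within = nrow(w), n_pixels = n)
}

#' Pixel-resampling Mahalanobis test for two leaf images
#'
#' Runs the full nine-step protocol on a pair of leaf images: draw `P`
#' pixel-resampling images from each, form the within-image attribute
#' differences and their combined covariance, take the between-image
#' difference of the full-mask band means, and refer the Mahalanobis
#' statistic D^2 to a chi-squared distribution with one degree of freedom
#' per attribute. A LARGE p-value indicates the two images are consistent
#' with leaves of the same individual; a small p-value indicates distinct
#' individuals.
#'
#' @param img_a,img_b RGB arrays (see [read_rgb()]).
#' @param mask_a,mask_b Optional logical masks; segmented with
#'   [segment_leaf()] defaults when omitted.
#' @param config A [protocol_config()].
#' @return Object of class `c("d2_test", "htest")` with `statistic`
#'   (`D2`), `parameter` (`df`), `p.value`, plus the protocol internals:
#'   `between_diff`, `within_mean`, `within_cov`, `n_within`, `n_pixels`
#'   and the `config` used.
#' @examples
#' b <- generate_bundle(synthetic_config(design = ss_design(1, 0, 0),
#'                                       image_size = c(60, 60)), seed = 1)
#' d2_test(b$images[[1]], b$images[[2]],
#'         config = protocol_config(seed = 1))
#' @export
d2_test <- function(img_a, img_b, mask_a = NULL, mask_b = NULL,
                    config = protocol_config()) {
  stopifnot(inherits(config, "protocol_config"))
  if (is.null(mask_a)) mask_a <- segment_leaf(img_a)
  if (is.null(mask_b)) mask_b <- segment_leaf(img_b)
  pool_a <- .pixel_pool(img_a, mask_a, config$attrs)
  pool_b <- .pixel_pool(img_b, mask_b, config$attrs)
  run <- function() .d2_from_pools(pool_a, pool_b, config)
  res <- if (is.null(config$seed)) run() else with_seed(config$seed, run())
  dn <- paste(deparse(substitute(img_a)), "vs", deparse(substitute(img_b)))
  structure(
    list(statistic = c(D2 = res$d2), parameter = c(df = res$df),
         p.value = res$p_value,
         estimate = stats::setNames(res$between_diff,
                                    paste0("between diff ", config$attrs)),
         method = "Pixel-resampling Mahalanobis test (chi-squared reference)",
         data.name = dn,
         between_diff = res$between_diff, within_mean = res$within_mean,
         within_cov = res$within_cov, n_within = res$n_within,
         n_pixels = res$n_pixels, config = config),
    class = c("d2_test", "htest")
  )
}

#' Run the protocol over many sample pairs
#'
#' Batch form of [d2_test()]: pixel pools and full-mask means are computed
#' once per image, then each pair is tested with fresh resampling draws.
#'
#' @param images Named list of RGB arrays, names = sample ids.
#' @param pairs Data frame from [enumerate_pairs()] (columns `sample_a`,
#'   `sample_b`, optionally `pair_class`).
#' @param config A [protocol_config()]; its `seed` (default the global RNG
#'   stream) seeds the whole batch.
#' @param masks Optional named list of logical masks; segmented on the fly
#'   when omitted.
#' @return Data frame: `sample_a`, `sample_b`, `pair_class` (if supplied),
#'   `d2`, `df`, `p_value`.
#' @export
d2_test_pairs <- function(images, pairs, config = protocol_config(),
                          masks = NULL) {
  stopifnot(inherits(config, "protocol_config"))
  ids <- unique(c(pairs$sample_a, pairs$sample_b))
  miss <- setdiff(ids, names(images))
  if (length(miss) > 0) {
    stop("image(s) missing: ", paste(utils::head(miss, 5), collapse = ", "))
  }
  pools <- lapply(ids, function(id) {
    m <- if (!is.null(masks)) masks[[id]] else segment_leaf(images[[id]])
    .pixel_pool(images[[id]], m, config$attrs)
  })
  names(pools) <- ids
  run <- function() {
    t(vapply(seq_len(nrow(pairs)), function(k) {
      r <- .d2_from_pools(pools[[pairs$sample_a[k]]],
                          pools[[pairs$sample_b[k]]], config)
      c(r$d2, r$df, r$p_value)
    }, numeric(3)))
  }
  res <- if (is.null(config$seed)) run() else with_seed(config$seed, run())
  out <- pairs[, intersect(c("sample_a", "sample_b", "pair_class"),
                           names(pairs)), drop = FALSE]
  out$d2 <- res[, 1]
  out$df <- as.integer(res[, 2])
  out$p_value <- res[, 3]
  out
}

#' Quantile-quantile table against a chi-squared reference
#'
#' Pairs the sorted observed D^2 values with chi-squared quantiles at
#' plotting positions `(i - 0.5) / n`; used to check that the statistic
#' follows its nominal chi-squared distribution.
#'
#' @param d2_values Numeric vector of observed statistics (>= 10 values).
#' @param df Chi-squared degrees of freedom.
#' @return Data frame with columns `theoretical` and `empirical`.
#' @export
qq_chisq <- function(d2_values, df) {
  d2_values <- as.numeric(d2_values)
  if (length(d2_values) < 10) stop("need at least 10 values for a QQ table")
  n <- length(d2_values)
  pp <- (seq_len(n) - 0.5) / n
  data.frame(theoretical = stats::qchisq(pp, df = df),
             empirical = sort(d2_values))
}
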