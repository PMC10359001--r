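#' Standardize feature columns
#'
#' Centers every column to mean 0 and scales it to standard deviation 1
#' (denominator `n - 1`). All attributes are standardized before distance
#' computation so that image bands and spectral channels contribute on a
#' common scale.
#'
#' @param x Numeric matrix, samples in rows (rownames = sample ids).
#' @return The standardized matrix, with attribute `standardized = TRUE`.
#' @export
standardize_columns <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("standardization needs at least 2 samples")
  sds <- apply(x, 2, stats::sd)
  bad <- which(sds < .Machine$double.eps)
  if (length(bad) > 0) {
    nm <- colnames(x)[bad]
    stop("zero-variance column(s): ",
         paste(if (is.null(nm)) bad else nm, collapse = ", "))
  }
  out <- scale(x, center = TRUE, scale = sds)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "standardized") <- TRUE
  out
}

#' Euclidean distance between two attribute vectors
#'
#' @param x,y Numeric vectors of equal length (and equal names, if named).
#' @return The Euclidean distance `sqrt(sum((x - y)^2))`.
#' @export
euclidean_distance <- function(x, y) {
  if (length(x) != length(y)) stop("attribute vectors differ in length")
  if (!is.null(names(x)) && !is.null(names(y)) &&
      !identical(names(x), names(y))) {
    stop("attribute names differ")
  }
  sqrt(sum((x - y)^2))
}

.scenarios <- c("RGB", "R", "NIR", "RGB+NIR", "R+NIR")

#' Assemble the feature table for a comparison scenario
#'
#' Builds the standardized samples-by-features table for one of the five
#' scenarios: `RGB` (three band means), `R` (red band mean only), `NIR`
#' (pretreated spectrum), and the concatenations `RGB+NIR` and `R+NIR`.
#'
#' @param rgb Numeric matrix of band means, columns `R`, `G`, `B`, rownames
#'   = sample ids.
#' @param nir Optional [spectra_matrix()] with matching sample ids;
#'   required for NIR-containing scenarios.
#' @param scenario One of `"RGB"`, `"R"`, `"NIR"`, `"RGB+NIR"`, `"R+NIR"`.
#' @param pipeline Pretreatment applied to `nir` first: an [nir_pipeline()]
#'   or signature string (default `"SG(5,2)+D1+MSC+MC"`); `""` for raw
#'   spectra.
#' @return Standardized feature matrix with attributes `scenario` and
#'   `pipeline`.
#' @export
scenario_features <- function(rgb, nir = NULL, scenario = .scenarios,
                              pipeline = "SG(5,2)+D1+MSC+MC") {
  scenario <- match.arg(scenario)
  rgb <- as.matrix(rgb)
  if (!all(c("R", "G", "B") %in% colnames(rgb))) {
    stop("rgb must have columns R, G, B")
  }
  need_nir <- grepl("NIR", scenario)
  sig <- ""
  nmat <- NULL
  if (need_nir) {
    if (is.null(nir)) stop("scenario ", scenario, " needs NIR spectra")
    nir <- .as_spectra(nir)
    if (!identical(sort(rownames(rgb)), sort(rownames(nir)))) {
      stop("rgb and nir sample ids do not match")
    }
    if (is.character(pipeline)) pipeline <- nir_pipeline(pipeline)
    nir <- apply_pipeline(nir, pipeline)
    sig <- pipeline_signature(pipeline)
    nmat <- unclass(nir)[rownames(rgb), , drop = FALSE]
    colnames(nmat) <- paste0("nm", colnames(nmat))
  }
  feats <- switch(scenario,
    "RGB" = rgb[, c("R", "G", "B"), drop = FALSE],
    "R" = rgb[, "R", drop = FALSE],
    "NIR" = nmat,
    "RGB+NIR" = cbind(rgb[, c("R", "G", "B"), drop = FALSE], nmat),
    "R+NIR" = cbind(rgb[, "R", drop = FALSE], nmat)
  )
  out <- standardize_columns(feats)
  attr(out, "scenario") <- scenario
  attr(out, "pipeline") <- sig
  out
}

#' Euclidean distance for every sample pair
#'
#' @param features Standardized feature matrix ([scenario_features()] or
#'   [standardize_columns()] output), rownames = sample ids.
#' @param pairs Data frame from [enumerate_pairs()].
#' @return `pairs` with columns `scenario` and `distance` appended.
#' @export
pair_distances <- function(features, pairs) {
  if (!isTRUE(attr(features, "standardized"))) {
    stop("features must be standardized (see standardize_columns)")
  }
  miss <- setdiff(unique(c(pairs$sample_a, pairs$sample_b)), rownames(features))
  if (length(miss) > 0) {
    stop("sample id(s) missing from feature table: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  xa <- features[pairs$sample_a, , drop = FALSE]
  xb <- features[pairs$sample_b, , drop = FALSE]
  out <- pairs
  out$scenario <- attr(features, "scenario") %||% "custom"
  out$distance <- sqrt(rowSums((xa - xb)^2))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' ROC analysis of pairwise distances
#'
#' Evaluates how well a distance separates same-individual pairs (class
#' `C1`, the positives) from the rest. Orientation: a SMALLER distance
#' indicates the positive class. The AUC is the midrank Mann-Whitney
#' probability `P(D_pos < D_neg) + 0.5 P(tie)`; the curve is traced by
#' sweeping the decision threshold over the observed distances.
#'
#' @param distances Data frame from [pair_distances()] (columns
#'   `pair_class`, `distance`).
#' @param positive Pair classes forming the positive group (default `C1`).
#' @param negative Pair classes forming the negative group (default
#'   `C2` and `C3`); pairs in neither group are dropped.
#' @return Object of class `pair_roc`: list with elements `auc`,
#'   `thresholds`, `fpr`, `tpr`, `n_pos`, `n_neg`, `positive`, `scenario`.
#' @export
pair_roc <- function(distances, positive = "C1", negative = c("C2", "C3")) {
  dpos <- distances$distance[distances$pair_class %in% positive]
  dneg <- distances$distance[distances$pair_class %in% negative]
  if (length(dpos) == 0 || length(dneg) == 0) {
    stop("both positive and negative pairs are required")
  }
  r <- rank(c(dpos, dneg))
  n_pos <- length(dpos); n_neg <- length(dneg)
  # midranks of negatives give P(D_neg > D_pos) + 0.5 P(tie)
  auc <- (sum(r[(n_pos + 1):(n_pos + n_neg)]) - n_neg * (n_neg + 1) / 2) /
    (n_pos * n_neg)
  th <- c(-Inf, sort(unique(c(dpos, dneg))))
  tpr <- vapply(th, function(t) mean(dpos <= t), numeric(1))
  fpr <- vapply(th, function(t) mean(dneg <= t), numeric(1))
  structure(
    list(auc = auc, thresholds = th, fpr = fpr, tpr = tpr,
         n_pos = n_pos, n_neg = n_neg, positive = positive,
         scenario = distances$scenario[1] %||% "custom"),
    class = "pair_roc"
  )
}

#' @export
print.pair_roc <- function(x, ...) {
  cat("ROC for pairwise distances (scenario ", x$scenario, ")\n", sep = "")
  cat("  positives: ", paste(x$positive, collapse = "+"),
      " (n = ", x$n_pos, "), negatives n = ", x$n_neg, "\n", sep = "")
  cat("  AUC =", format(x$auc, digits = 4),
      "(smaller distance => positive)\n")
  invisible(x)
}

#' @export
plot.pair_roc <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("Scenario %s (AUC = %.4f)", x$scenario, x$auc),
                 ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Write distance records or an ROC curve to CSV
#'
#' @param distances Data frame from [pair_distances()].
#' @param path Output path.
#' @export
write_distances <- function(distances, path) {
  utils::write.csv(distances, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distances
#' @param roc A [pair_roc()] object.
#' @export
write_roc <- function(roc, path) {
  stopifnot(inherits(roc, "pair_roc"))
  utils::write.csv(
    data.frame(threshold = roc$thresholds, fpr = roc$fpr, tpr = roc$tpr),
    path, row.names = FALSE
  )
  invisible(path)
}
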