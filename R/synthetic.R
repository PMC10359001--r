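#' Configuration of the synthetic study generator
#'
#' Defines a study-like dataset with known ground truth: a hierarchical
#' variance-component model for leaf images (family, clone, leaf and pixel
#' effects, in 8-bit intensity units) and a peak-plus-scatter model for
#' NIR spectra. Defaults emulate the second-stage study subset: 7 families
#' present in both of 2 blocks, 3 `+1` leaves per plot.
#'
#' Image model: the mean intensity of channel c in the leaf of clone
#' (family f, block h) is `base_rgb[c] + family_f[c] + clone_fh[c]`; each
#' leaf adds a leaf effect, and each pixel adds independent noise, clipped
#' to `[0, 255]` and rounded. Clones of the same family in different
#' blocks share the family effect but draw independent clone effects, so
#' same-plot (C1) pairs differ only by leaf and pixel variation.
#'
#' NIR model: a clone signature (smooth baseline plus Gaussian absorbance
#' peaks whose amplitudes carry relative family/clone/leaf perturbations)
#' observed through per-leaf multiplicative scatter `a * s + b` plus
#' additive channel noise -- so scatter correction and smoothing have real
#' work to do.
#'
#' @param design A [leaf_design()] (default `ss_design(7, 0, 0)`).
#' @param sd_family,sd_clone,sd_leaf,sd_pixel Standard deviations of the
#'   image-intensity effects (0--255 units). Defaults 3 / 2 / 2 / 12 put
#'   the red band in a moderately informative regime (pairwise AUC well
#'   below 1) and keep clipping below 1% of pixels.
#' @param base_rgb Baseline channel means of a leaf (green-dominated).
#' @param image_size `c(height, width)` of the generated images; the leaf
#'   is an axis-aligned ellipse covering roughly a third of the frame.
#' @param bg_range Background intensities drawn uniformly from this range
#'   (bright plane).
#' @param nir_channels Number of spectral channels over 900--1700 nm
#'   (default 605, the study-like attribute count).
#' @param nir_sd_family,nir_sd_clone,nir_sd_leaf Relative (dimensionless)
#'   perturbations of the peak amplitudes.
#' @param scatter_slope_sd,scatter_offset_sd Per-leaf multiplicative and
#'   additive scatter.
#' @param nir_noise_sd Additive channel noise (absorbance units).
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(design = ss_design(7L, 0L, 0L),
                             sd_family = 3, sd_clone = 2, sd_leaf = 2,
                             sd_pixel = 12,
                             base_rgb = c(R = 110, G = 150, B = 60),
                             image_size = c(200L, 200L),
                             bg_range = c(245, 255),
                             nir_channels = 605L,
                             nir_sd_family = 0.10, nir_sd_clone = 0.08,
                             nir_sd_leaf = 0.01,
                             scatter_slope_sd = 0.05,
                             scatter_offset_sd = 0.02,
                             nir_noise_sd = 0.001) {
  stopifnot(inherits(design, "leaf_design"))
  sds <- c(sd_family, sd_clone, sd_leaf, sd_pixel,
           nir_sd_family, nir_sd_clone, nir_sd_leaf,
           scatter_slope_sd, scatter_offset_sd, nir_noise_sd)
  if (any(sds < 0)) stop("all standard deviations must be >= 0")
  image_size <- as.integer(image_size)
  if (length(image_size) != 2 || any(image_size < 20)) {
    stop("image_size must be c(height, width) with both >= 20")
  }
  nir_channels <- as.integer(nir_channels)
  if (nir_channels < 3) stop("nir_channels must be >= 3")
  structure(
    list(design = design, sd_family = sd_family, sd_clone = sd_clone,
         sd_leaf = sd_leaf, sd_pixel = sd_pixel, base_rgb = base_rgb,
         image_size = image_size, bg_range = bg_range,
         nir_channels = nir_channels, nir_sd_family = nir_sd_family,
         nir_sd_clone = nir_sd_clone, nir_sd_leaf = nir_sd_leaf,
         scatter_slope_sd = scatter_slope_sd,
         scatter_offset_sd = scatter_offset_sd,
         nir_noise_sd = nir_noise_sd),
    class = "synthetic_config"
  )
}

# absorbance peak layout shared by all synthetic spectra (water ~970/1450,
# starch/cellulose overtones in between)
.nir_peaks <- function() {
  list(center = c(970, 1150, 1300, 1450, 1650),
       amplitude = c(0.15, 0.10, 0.08, 0.25, 0.12),
       width = 30)
}

# deterministic per-leaf substream: plot index and leaf index map to a
# unique seed, so adding leaves or regenerating a single leaf never
# reshuffles the others
.leaf_seed <- function(seed, plot_idx, leaf_idx, offset = 0L) {
  (as.integer(seed) %% 1000003L) * 1000L + 97L * plot_idx + 13L * leaf_idx +
    offset + 1L
}

#' Generate a synthetic study bundle
#'
#' Draws the hierarchical effects, renders one leaf image and one NIR
#' spectrum per sample, and records every effect drawn in a truth table.
#' Fully reproducible: the same `config` and `seed` give byte-identical
#' bundles. Family and clone effects are drawn from the bundle stream in
#' design order; each leaf then uses its own derived substream.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return Object of class `ss_bundle`: list with elements `design`,
#'   `samples`, `images` (named list of RGB arrays), `spectra`
#'   (a [spectra_matrix()]), `truth` (data frame of drawn effects),
#'   `config`, `seed`.
#' @export
generate_bundle <- function(config = synthetic_config(), seed = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  design <- config$design
  samples <- enumerate_samples(design)
  pres <- unique(samples[, c("family", "block")])
  pres$plot_idx <- seq_len(nrow(pres))
  pk <- .nir_peaks()
  n_pk <- length(pk$center)

  # family- and clone-level effects from the bundle stream, design order
  eff <- with_seed(seed, {
    fam_rgb <- matrix(stats::rnorm(3 * length(design$families), 0,
                                   config$sd_family),
                      ncol = 3, dimnames = list(design$families,
                                                c("R", "G", "B")))
    fam_nir <- matrix(stats::rnorm(n_pk * length(design$families), 0,
                                   config$nir_sd_family),
                      ncol = n_pk, dimnames = list(design$families, NULL))
    clone_rgb <- matrix(stats::rnorm(3 * nrow(pres), 0, config$sd_clone),
                        ncol = 3, dimnames = list(NULL, c("R", "G", "B")))
    clone_nir <- matrix(stats::rnorm(n_pk * nrow(pres), 0,
                                     config$nir_sd_clone), ncol = n_pk)
    list(fam_rgb = fam_rgb, fam_nir = fam_nir,
         clone_rgb = clone_rgb, clone_nir = clone_nir)
  })

  h <- config$image_size[1]; w <- config$image_size[2]
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  leaf_mask <- ((xx - (w + 1) / 2) / (0.40 * w))^2 +
    ((yy - (h + 1) / 2) / (0.28 * h))^2 <= 1
  n_fg <- sum(leaf_mask)

  wl <- seq(900, 1700, length.out = config$nir_channels)
  peak_shapes <- vapply(seq_len(n_pk), function(k) {
    exp(-(wl - pk$center[k])^2 / (2 * pk$width^2))
  }, numeric(length(wl)))
  baseline <- 0.35 + 0.25 * (wl - 900) / 800

  images <- vector("list", nrow(samples))
  spectra <- matrix(NA_real_, nrow(samples), length(wl))
  truth <- vector("list", nrow(samples))

  for (i in seq_len(nrow(samples))) {
    s <- samples[i, ]
    pidx <- pres$plot_idx[pres$family == s$family & pres$block == s$block]
    fam_rgb <- eff$fam_rgb[s$family, ]
    clone_rgb <- eff$clone_rgb[pidx, ]
    clone_mean <- config$base_rgb + fam_rgb + clone_rgb

    img <- with_seed(.leaf_seed(seed, pidx, s$leaf_index), {
      leaf_eff <- stats::rnorm(3, 0, config$sd_leaf)
      arr <- array(0, c(h, w, 3))
      for (c in 1:3) {
        plane <- matrix(stats::runif(h * w, config$bg_range[1],
                                     config$bg_range[2]), h, w)
        px <- clone_mean[c] + leaf_eff[c] +
          stats::rnorm(n_fg, 0, config$sd_pixel)
        plane[leaf_mask] <- px
        arr[, , c] <- plane
      }
      list(arr = round(pmin(pmax(arr, 0), 255)), leaf_eff = leaf_eff)
    })

    nir <- with_seed(.leaf_seed(seed, pidx, s$leaf_index, offset = 500000L), {
      leaf_pk <- stats::rnorm(n_pk, 0, config$nir_sd_leaf)
      amp <- pk$amplitude *
        (1 + eff$fam_nir[s$family, ] + eff$clone_nir[pidx, ] + leaf_pk)
      signature <- baseline + as.numeric(peak_shapes %*% amp)
      a <- stats::rnorm(1, 1, config$scatter_slope_sd)
      b <- stats::rnorm(1, 0, config$scatter_offset_sd)
      obs <- a * signature + b +
        stats::rnorm(length(wl), 0, config$nir_noise_sd)
      list(obs = obs, leaf_pk = leaf_pk, a = a, b = b)
    })

    images[[i]] <- img$arr
    spectra[i, ] <- nir$obs
    truth[[i]] <- data.frame(
      sample_id = s$sample_id, family = s$family, block = s$block,
      leaf_index = s$leaf_index,
      clone_id = paste(s$family, s$block, sep = "_"),
      fam_R = fam_rgb["R"], fam_G = fam_rgb["G"], fam_B = fam_rgb["B"],
      clone_R = clone_rgb["R"], clone_G = clone_rgb["G"],
      clone_B = clone_rgb["B"],
      leaf_R = img$leaf_eff[1], leaf_G = img$leaf_eff[2],
      leaf_B = img$leaf_eff[3],
      nir_scatter_a = nir$a, nir_scatter_b = nir$b,
      stringsAsFactors = FALSE
    )
  }

  names(images) <- samples$sample_id
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  structure(
    list(design = design, samples = samples, images = images,
         spectra = spectra_matrix(spectra, wl, samples$sample_id),
         truth = truth, config = config, seed = as.integer(seed)),
    class = "ss_bundle"
  )
}

#' @export
print.ss_bundle <- function(x, ...) {
  cat("Synthetic study bundle:", nrow(x$samples), "leaf samples (",
      length(x$design$families), "families ), seed", x$seed, "\n")
  cat("  images:", paste(dim(x$images[[1]])[1:2], collapse = "x"),
      " spectra:", ncol(x$spectra), "channels\n")
  invisible(x)
}

#' Label pairs from the ground truth and cross-check the design classes
#'
#' Labels every pair from the truth table (`same-individual` when the two
#' samples share a `clone_id`, `same-family` when they share only the
#' family, else `different-family`) and verifies that the labels agree
#' with the design-derived `C1`/`C2`/`C3` classes.
#'
#' @param pairs Data frame from [enumerate_pairs()].
#' @param truth Truth table of a bundle (`bundle$truth`).
#' @return `pairs` with a `truth_label` column appended.
#' @export
truth_join <- function(pairs, truth) {
  miss <- setdiff(unique(c(pairs$sample_a, pairs$sample_b)),
                  truth$sample_id)
  if (length(miss) > 0) {
    stop("sample id(s) absent from truth table: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  ia <- match(pairs$sample_a, truth$sample_id)
  ib <- match(pairs$sample_b, truth$sample_id)
  lab <- ifelse(truth$clone_id[ia] == truth$clone_id[ib], "same-individual",
                ifelse(truth$family[ia] == truth$family[ib], "same-family",
                       "different-family"))
  expected <- c(C1 = "same-individual", C2 = "same-family",
                C3 = "different-family")[pairs$pair_class]
  if (!all(lab == expected)) {
    stop("truth labels disagree with design-derived pair classes")
  }
  out <- pairs
  out$truth_label <- lab
  out
}

#' Per-sample attribute tables of a bundle
#'
#' Segments every image and computes its band means, returning the inputs
#' of the first-stage scenario analysis.
#'
#' @param bundle An [generate_bundle()] result.
#' @return List with `rgb` (samples x 3 matrix of band means) and `nir`
#'   (the bundle's [spectra_matrix()]).
#' @export
bundle_attributes <- function(bundle) {
  stopifnot(inherits(bundle, "ss_bundle"))
  rgb <- t(vapply(bundle$images, function(img) {
    band_means(img, segment_leaf(img))
  }, numeric(3)))
  colnames(rgb) <- c("R", "G", "B")
  list(rgb = rgb, nir = bundle$spectra)
}

#' Write a bundle to disk
#'
#' Writes `{family}_{block}_leaf{N}.png` images, `spectra.csv`,
#' `design.yaml`, `samples.csv` and `truth.csv` into a directory.
#'
#' @param bundle An `ss_bundle`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "ss_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(bundle$images)) {
    write_rgb(bundle$images[[id]], file.path(dir, paste0(id, ".png")))
  }
  write_spectra(bundle$spectra, file.path(dir, "spectra.csv"))
  write_design(bundle$design, file.path(dir, "design.yaml"))
  utils::write.csv(bundle$samples, file.path(dir, "samples.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
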