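#' Experimental design for a Simplified System leaf sampling study
#'
#' Describes which family is planted in which block (a plot is a
#' family-by-block combination holding a single clone) and how many
#' `+1` leaves are sampled per plot.
#'
#' @param families Character vector of family identifiers (unique).
#' @param blocks Character vector of block identifiers (unique).
#' @param presence Data frame with columns `family` and `block`, one row per
#'   plot that is actually planted. Keys must be unique and refer to known
#'   families/blocks; every family must appear in at least one block.
#' @param leaves_per_plot Number of `+1` leaves sampled per plot (>= 1).
#'
#' @return An object of class `leaf_design`.
#' @seealso [ss_design()] for the standard two-block layout,
#'   [enumerate_samples()], [enumerate_pairs()].
#' @export
leaf_design <- function(families, blocks, presence, leaves_per_plot = 3L) {
  families <- as.character(families)
  blocks <- as.character(blocks)
  if (anyDuplicated(families)) stop("duplicate family identifiers")
  if (anyDuplicated(blocks)) stop("duplicate block identifiers")
  if (!is.data.frame(presence) ||
      !all(c("family", "block") %in% names(presence))) {
    stop("`presence` must be a data frame with columns family, block")
  }
  presence <- data.frame(family = as.character(presence$family),
                         block = as.character(presence$block),
                         stringsAsFactors = FALSE)
  if (anyDuplicated(presence)) stop("duplicate (family, block) plot keys")
  if (!all(presence$family %in% families)) stop("presence refers to unknown family")
  if (!all(presence$block %in% blocks)) stop("presence refers to unknown block")
  missing_fam <- setdiff(families, presence$family)
  if (length(missing_fam) > 0) {
    stop("family absent from every block: ", paste(missing_fam, collapse = ", "))
  }
  leaves_per_plot <- as.integer(leaves_per_plot)
  if (is.na(leaves_per_plot) || leaves_per_plot < 1L) {
    stop("leaves_per_plot must be a positive integer")
  }
  structure(
    list(families = families, blocks = blocks, presence = presence,
         leaves_per_plot = leaves_per_plot),
    class = "leaf_design"
  )
}

#' Standard two-block Simplified System design
#'
#' The full study layout has 31 families over two blocks: `n_dual` families
#' planted in both blocks, `n_block1_only` only in block 1 and
#' `n_block2_only` only in block 2 (defaults give 14 plots in block 1 and
#' 24 in block 2). The second-stage analysis subset is the dual-block
#' families alone: `ss_design(7, 0, 0)`.
#'
#' @param n_dual Families present in both blocks.
#' @param n_block1_only,n_block2_only Families present in one block only.
#' @param leaves_per_plot Leaves sampled per plot.
#' @return A [leaf_design()] object.
#' @examples
#' d <- ss_design(7, 0, 0)             # dual-block subset: 42 samples
#' nrow(enumerate_samples(d))
#' @export
ss_design <- function(n_dual = 7L, n_block1_only = 7L, n_block2_only = 17L,
                      leaves_per_plot = 3L) {
  n_total <- n_dual + n_block1_only + n_block2_only
  if (n_total < 1) stop("design has no families")
  families <- sprintf("F%02d", seq_len(n_total))
  blocks <- c("B1", "B2")
  fam_dual <- families[seq_len(n_dual)]
  fam_b1 <- families[n_dual + seq_len(n_block1_only)]
  fam_b2 <- families[n_dual + n_block1_only + seq_len(n_block2_only)]
  presence <- rbind(
    data.frame(family = rep(fam_dual, each = 2), block = rep(blocks, n_dual)),
    if (n_block1_only > 0) data.frame(family = fam_b1, block = "B1"),
    if (n_block2_only > 0) data.frame(family = fam_b2, block = "B2")
  )
  leaf_design(families, blocks, presence, leaves_per_plot)
}

#' @export
print.leaf_design <- function(x, ...) {
  cat("Leaf sampling design:", length(x$families), "families,",
      length(x$blocks), "blocks,", nrow(x$presence), "plots,",
      x$leaves_per_plot, "leaves per plot\n")
  tab <- table(x$presence$block)
  cat("  plots per block:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Restrict a design to a subset of families
#'
#' @param design A [leaf_design()].
#' @param families Families to keep.
#' @return A [leaf_design()] containing only those families.
#' @export
subset_design <- function(design, families) {
  stopifnot(inherits(design, "leaf_design"))
  if (!all(families %in% design$families)) stop("unknown family in subset")
  keep <- design$presence$family %in% families
  leaf_design(families,
              intersect(design$blocks, design$presence$block[keep]),
              design$presence[keep, , drop = FALSE],
              design$leaves_per_plot)
}

#' Families present in more than one block
#'
#' @param design A [leaf_design()].
#' @return Character vector of family identifiers.
#' @export
dual_block_families <- function(design) {
  stopifnot(inherits(design, "leaf_design"))
  tab <- table(design$presence$family)
  names(tab)[tab > 1]
}

#' Enumerate all leaf samples of a design
#'
#' One sample per leaf of every present plot, in deterministic
#' (family, block, leaf index) order. Sample identifiers are
#' `family_block_leafN`.
#'
#' @param design A [leaf_design()].
#' @return Data frame with columns `sample_id`, `family`, `block`,
#'   `leaf_index`.
#' @export
enumerate_samples <- function(design) {
  stopifnot(inherits(design, "leaf_design"))
  pres <- design$presence
  ord <- order(match(pres$family, design$families),
               match(pres$block, design$blocks))
  pres <- pres[ord, , drop = FALSE]
  L <- design$leaves_per_plot
  out <- data.frame(
    family = rep(pres$family, each = L),
    block = rep(pres$block, each = L),
    leaf_index = rep(seq_len(L), nrow(pres)),
    stringsAsFactors = FALSE
  )
  out$sample_id <- sprintf("%s_%s_leaf%d", out$family, out$block, out$leaf_index)
  out[, c("sample_id", "family", "block", "leaf_index")]
}

# vectorised class rule shared by classify_pair / enumerate_pairs
.pair_class <- function(fam_a, blk_a, fam_b, blk_b) {
  ifelse(fam_a != fam_b, "C3", ifelse(blk_a == blk_b, "C1", "C2"))
}

#' Classify a pair of leaf samples
#'
#' Pairs of leaves fall into three classes: `C1` (same family and block,
#' hence leaves of the same individual, since each plot holds one clone),
#' `C2` (same family, different block: distinct individuals of the same
#' family) and `C3` (different families). The classification is symmetric
#' in its arguments.
#'
#' @param a,b Leaf samples: lists or one-row data frames with elements
#'   `sample_id`, `family`, `block`.
#' @return `"C1"`, `"C2"` or `"C3"`.
#' @export
classify_pair <- function(a, b) {
  if (identical(as.character(a$sample_id), as.character(b$sample_id))) {
    stop("cannot classify a sample against itself")
  }
  .pair_class(as.character(a$family), as.character(a$block),
              as.character(b$family), as.character(b$block))
}

#' Enumerate and classify all unordered sample pairs
#'
#' Returns all `choose(n, 2)` unordered pairs, each canonicalised so that
#' `sample_a < sample_b` lexicographically, with its pair class.
#'
#' @param samples Data frame as returned by [enumerate_samples()].
#' @return Data frame with columns `sample_a`, `sample_b`, `pair_class`.
#' @examples
#' p <- enumerate_pairs(enumerate_samples(ss_design(7, 0, 0)))
#' table(p$pair_class)  # 42 C1, 63 C2, 756 C3 of 861
#' @export
enumerate_pairs <- function(samples) {
  if (nrow(samples) < 2) stop("need at least two samples")
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id")
  n <- nrow(samples)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  a <- samples$sample_id[i]; b <- samples$sample_id[j]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  out <- data.frame(
    sample_a = a, sample_b = b,
    pair_class = .pair_class(samples$family[i], samples$block[i],
                             samples$family[j], samples$block[j]),
    stringsAsFactors = FALSE
  )
  out[order(out$sample_a, out$sample_b), , drop = FALSE]
}

#' Read or write a design file
#'
#' Designs are stored as YAML with fields `families`, `blocks`, `presence`
#' (a mapping family -> list of blocks) and `leaves_per_plot`.
#'
#' @param path File path.
#' @return `read_design()` returns a [leaf_design()].
#' @export
read_design <- function(path) {
  y <- yaml::read_yaml(path)
  pres <- do.call(rbind, lapply(names(y$presence), function(f) {
    data.frame(family = f, block = as.character(y$presence[[f]]),
               stringsAsFactors = FALSE)
  }))
  leaf_design(y$families, y$blocks, pres, y$leaves_per_plot)
}

#' @rdname read_design
#' @param design A [leaf_design()] to serialise.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "leaf_design"))
  pres <- split(design$presence$block, design$presence$family)
  pres <- pres[intersect(design$families, names(pres))]
  yaml::write_yaml(
    list(families = design$families, blocks = design$blocks,
         presence = pres, leaves_per_plot = design$leaves_per_plot),
    path
  )
  invisible(path)
}

#' Write classified pairs to CSV
#'
#' @param pairs Data frame from [enumerate_pairs()].
#' @param path Output CSV path.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.csv(pairs, path, row.names = FALSE)
  invisible(path)
}
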