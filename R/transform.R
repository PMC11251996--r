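#' Offset log2 transform
#'
#' \code{log2(x + offset)} with a small positive offset so zero abundances
#' stay finite.  The conventional offset for FPKM-like values is 0.01.
#'
#' @param x an \code{expression_study} (its values layer is used) or a
#'   non-negative numeric matrix.
#' @param offset positive pseudo-value added before taking log2.
#' @return matrix of log2 values with the offset recorded as attribute
#'   \code{"offset"}.
#' @export
log_transform <- function(x, offset = 0.01) {
  if (!is.numeric(offset) || length(offset) != 1L || offset <= 0) {
    stop("offset must be a positive number")
  }
  m <- if (inherits(x, "expression_study")) x$values else x
  if (any(m < 0)) stop("values must be non-negative")
  out <- log2(m + offset)
  attr(out, "offset") <- offset
  out
}

#' Detectability mask from read counts
#'
#' A gene is detected in a (group, batch) cell when at least
#' \code{min_replicates} of its replicates carry \code{min_reads} or more
#' mapped reads (default: >= 3 reads in at least 2 replicates).
#'
#' @param study an \code{expression_study} with a counts layer.
#' @param min_reads minimum read count per replicate.
#' @param min_replicates minimum number of replicates reaching
#'   \code{min_reads}.
#' @return a logical gene x (group, batch) matrix of class
#'   \code{detectability_mask}, with per-column \code{group}/\code{batch}
#'   attributes and the thresholds stored for provenance.
#' @export
detectability_mask <- function(study, min_reads = 3, min_replicates = 2) {
  if (!inherits(study, "expression_study")) {
    stop("study must be an expression_study")
  }
  if (is.null(study$counts)) {
    stop("detectability requires a counts layer; supply counts when ",
         "building the study, or apply a values-threshold fallback ",
         "upstream")
  }
  d <- study$design
  cells <- unique(d[, c("group", "batch")])
  rownames(cells) <- NULL
  mask <- matrix(NA, nrow = nrow(study$counts), ncol = nrow(cells),
                 dimnames = list(rownames(study$counts),
                                 paste(cells$group, cells$batch, sep = ":")))
  for (i in seq_len(nrow(cells))) {
    idx <- d$sample[d$group == cells$group[i] & d$batch == cells$batch[i]]
    if (length(idx) < min_replicates) {
      stop("(group=", cells$group[i], ", batch=", cells$batch[i],
           ") has fewer than min_replicates = ", min_replicates,
           " replicates")
    }
    hits <- rowSums(study$counts[, idx, drop = FALSE] >= min_reads)
    mask[, i] <- hits >= min_replicates
  }
  structure(mask,
            group = cells$group, batch = cells$batch,
            min_reads = min_reads, min_replicates = min_replicates,
            class = c("detectability_mask", class(mask)))
}

#' Consensus-detectable genes for a group across batches
#'
#' @param masks a list of \code{\link{detectability_mask}} objects, one per
#'   batch (a single mask spanning several batches also works).
#' @param group group label to evaluate.
#' @param require_all if TRUE (default) a gene must be detected in the group
#'   in every batch where the group appears; otherwise \code{min_batches}
#'   applies.
#' @param min_batches minimum number of batches when \code{require_all} is
#'   FALSE.
#' @return character vector of gene identifiers.
#' @export
consensus_detectable <- function(masks, group, require_all = TRUE,
                                 min_batches = NULL) {
  if (inherits(masks, "detectability_mask")) masks <- list(masks)
  if (length(masks) == 0L) stop("empty batch mask list")
  det <- NULL
  n_used <- 0L
  for (m in masks) {
    cols <- which(attr(m, "group") == group)
    if (length(cols) == 0L) {
      warning("group '", group, "' absent from a batch mask; batch skipped")
      next
    }
    for (ci in cols) {
      v <- m[, ci]
      det <- if (is.null(det)) cbind(v) else cbind(det, v)
      n_used <- n_used + 1L
    }
  }
  if (n_used == 0L) stop("group '", group, "' absent from every batch mask")
  hits <- rowSums(det)
  if (require_all) {
    keep <- hits == n_used
  } else {
    if (is.null(min_batches)) {
      stop("min_batches required when require_all = FALSE")
    }
    keep <- hits >= min_batches
  }
  rownames(det)[keep]
}

#' Ratio-based (relative-scale) expression
#'
#' Converts absolute log2 profiles to relative-scale profiles within each
#' batch: for every gene, the mean log2 value of the designated denominator
#' replicates in the same batch is subtracted.  Gene-wise additive batch
#' shifts cancel exactly under this transform, which is what makes
#' ratio-based profiles comparable across batches.
#'
#' @param log_matrix gene x sample matrix of log2 values (see
#'   \code{\link{log_transform}}).
#' @param design the matching \code{study_design}.
#' @param denominator_group group label whose replicates serve as in-batch
#'   denominator.
#' @param denominator_replicates optional integer subset of replicate
#'   indices to use (default: all replicates of the denominator group in
#'   each batch; single-replicate denominators are allowed but carry more
#'   noise).
#' @return gene x sample matrix of log2 ratios, class \code{ratio_matrix},
#'   with the denominator specification stored in attributes.
#' @export
ratio_transform <- function(log_matrix, design, denominator_group,
                            denominator_replicates = NULL) {
  if (!inherits(design, "study_design")) design <- study_design(design)
  if (!all(design$sample %in% colnames(log_matrix))) {
    stop("log_matrix must contain every design sample")
  }
  log_matrix <- log_matrix[, design$sample, drop = FALSE]
  out <- log_matrix
  for (b in unique(design$batch)) {
    in_batch <- design$batch == b
    den <- in_batch & design$group == denominator_group
    if (!is.null(denominator_replicates)) {
      den <- den & design$replicate %in% denominator_replicates
    }
    if (!any(den)) {
      stop("denominator group '", denominator_group,
           "' (replicates ",
           if (is.null(denominator_replicates)) "all"
           else paste(denominator_replicates, collapse = ","),
           ") missing in batch '", b, "'")
    }
    den_mean <- rowMeans(log_matrix[, design$sample[den], drop = FALSE])
    out[, design$sample[in_batch]] <-
      log_matrix[, design$sample[in_batch], drop = FALSE] - den_mean
  }
  structure(out,
            denominator = list(group = denominator_group,
                               replicates = denominator_replicates),
            offset = attr(log_matrix, "offset"),
            class = c("ratio_matrix", class(out)))
}
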