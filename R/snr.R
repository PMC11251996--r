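## Internal: align a design to the matrix columns and return group labels.
.aligned_groups <- function(m, design) {
  if (!inherits(design, "study_design")) design <- study_design(design)
  if (is.null(colnames(m))) stop("matrix must carry sample colnames")
  missing <- setdiff(colnames(m), design$sample)
  if (length(missing) > 0L) {
    stop("sample(s) absent from design: ", paste(missing, collapse = ", "))
  }
  design$group[match(colnames(m), design$sample)]
}

## Internal: mean distance between and within groups given a full distance
## matrix (samples x samples) and group labels.
.signal_noise <- function(D, groups) {
  n <- length(groups)
  same <- outer(groups, groups, "==")
  ut <- upper.tri(D)
  list(signal = mean(D[ut & !same]), noise = mean(D[ut & same]))
}

.snr_methods <- c("OriAll_EucDist", "OriSingle_MedianEucDist",
                  "OriAll_1-Cor", "ReducedDim_tSNE", "ReducedDim_PCA")

#' PCA-weighted signal-to-noise ratio
#'
#' Measures a dataset's power to separate biological groups from replicate
#' noise.  Features are centered and (by default) scaled to unit variance,
#' a PCA is computed, and the SNR in decibels is
#' \deqn{10 \log_{10} \frac{\mathrm{mean}_{x \ne y, i, j} \sum_p W_p (PC_{p,i,x}-PC_{p,j,y})^2}
#'                          {\mathrm{mean}_{x, i<j} \sum_p W_p (PC_{p,i,x}-PC_{p,j,x})^2}}
#' where \eqn{p} runs over the first \code{n_pcs} components and \eqn{W_p}
#' is the fraction of total variance explained by component \eqn{p}.  For a
#' balanced design of m groups with n replicates the ratio of means equals
#' the textbook prefactor \eqn{m\binom{n}{2} / (\binom{m}{2} n^2)} times the
#' ratio of pair sums; unequal group sizes generalize the prefactor to
#' (number of within pairs)/(number of between pairs).
#'
#' @param m gene x sample matrix of log2 (or ratio-based) values.
#' @param design the matching \code{study_design}.
#' @param n_pcs number of leading principal components (default 2,
#'   matching the visual PCA plane).
#' @param scale divide each feature by its standard deviation before PCA
#'   (univariance scaling); zero-variance features are dropped first, with
#'   the count reported in the result.
#' @return an object of class \code{snr_result}: \code{snr_db}, the method
#'   name, per-PC weights, sample scores (for plotting), group sizes, the
#'   raw signal/noise means and an \code{infinite} flag (zero within-group
#'   dispersion is reported as a capped display value, default 60 dB).
#' @export
snr_pca <- function(m, design, n_pcs = 2, scale = TRUE) {
  groups <- .aligned_groups(m, design)
  tab <- table(groups)
  if (length(tab) < 2L) stop("SNR undefined: need at least 2 groups")
  if (any(tab < 2L)) {
    stop("noise undefined: group(s) with a single replicate: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  }
  X <- t(m)                              # samples x features
  v <- apply(X, 2L, stats::var)
  n_dropped <- 0L
  if (scale) {
    keep <- v > 0
    n_dropped <- sum(!keep)
    X <- X[, keep, drop = FALSE]
  }
  if (ncol(X) < 2L) stop("need at least 2 features with nonzero variance")
  pca <- stats::prcomp(X, center = TRUE, scale. = scale)
  w_all <- pca$sdev^2 / sum(pca$sdev^2)
  k <- min(n_pcs, ncol(pca$x))
  scores <- pca$x[, seq_len(k), drop = FALSE]
  w <- w_all[seq_len(k)]
  D2 <- as.matrix(stats::dist(sweep(scores, 2L, sqrt(w), "*")))^2
  sn <- .signal_noise(D2, groups)
  infinite <- sn$noise == 0
  snr_db <- if (infinite) 60 else 10 * log10(sn$signal / sn$noise)
  structure(list(snr_db = snr_db, method = "ReducedDim_PCA",
                 n_pcs = k, weights = w, weights_all = w_all,
                 scores = scores, groups = groups,
                 m = length(tab), n_per_group = as.integer(tab),
                 signal = sn$signal, noise = sn$noise,
                 infinite = infinite, n_dropped_features = n_dropped),
            class = "snr_result")
}

#' @export
print.snr_result <- function(x, ...) {
  cat(sprintf("SNR (%s): %.3f dB%s\n", x$method, x$snr_db,
              if (isTRUE(x$infinite)) " [infinite: zero within-group dispersion, capped]"
              else if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  cat("  m =", x$m, "groups; replicates:",
      paste(x$n_per_group, collapse = ", "), "\n")
  if (!is.null(x$weights)) {
    cat("  PC weights:",
        paste(sprintf("%.3f", x$weights), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.snr_result <- function(x, ...) {
  if (is.null(x$scores) || ncol(x$scores) < 2L) {
    stop("no 2-D embedding stored in this result")
  }
  grp <- factor(x$groups)
  graphics::plot(x$scores[, 1L], x$scores[, 2L],
                 col = as.integer(grp), pch = 19,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$weights[1L]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$weights[2L]),
                 main = sprintf("SNR = %.1f dB", x$snr_db), ...)
  graphics::legend("topright", legend = levels(grp),
                   col = seq_along(levels(grp)), pch = 19, bty = "n")
  invisible(x)
}

#' SNR variants on original or reduced feature space
#'
#' Five ways to measure the between/within group distance ratio:
#' \describe{
#'   \item{OriAll_EucDist}{Euclidean distance between full sample vectors.}
#'   \item{OriSingle_MedianEucDist}{per-feature absolute difference,
#'     summarized as the median across features.}
#'   \item{OriAll_1-Cor}{one minus the Pearson correlation of sample
#'     vectors.}
#'   \item{ReducedDim_tSNE}{Euclidean distance in a seeded 2-D tSNE
#'     embedding (requires the \pkg{Rtsne} package or a user-supplied
#'     \code{embed_fun}).}
#'   \item{ReducedDim_PCA}{delegates to \code{\link{snr_pca}}.}
#' }
#' For the original-space and tSNE variants the SNR is
#' \code{10*log10(mean between-group distance / mean within-group
#' distance)}.
#'
#' @inheritParams snr_pca
#' @param method one of the five variant names.
#' @param seed integer seed, mandatory for \code{ReducedDim_tSNE} (the
#'   embedding is stochastic).
#' @param embed_fun optional function \code{(samples x features matrix) ->
#'   (samples x 2 matrix)} supplying the low-dimensional embedding for
#'   \code{ReducedDim_tSNE}; overrides the Rtsne backend.
#' @param perplexity tSNE perplexity; default \code{min(10, (N-1)/3)}.
#' @param ... passed to \code{\link{snr_pca}} for
#'   \code{method = "ReducedDim_PCA"}.
#' @return an \code{snr_result}.  A configuration where both signal and
#'   noise vanish (e.g. perfectly correlated samples under
#'   \code{OriAll_1-Cor}) is flagged \code{degenerate} with \code{snr_db =
#'   NA}.
#' @export
snr_variant <- function(m, design, method, seed = NULL, embed_fun = NULL,
                        perplexity = NULL, ...) {
  if (!method %in% .snr_methods) {
    stop("unknown method '", method, "'; must be one of: ",
         paste(.snr_methods, collapse = ", "))
  }
  if (method == "ReducedDim_PCA") return(snr_pca(m, design, ...))
  groups <- .aligned_groups(m, design)
  tab <- table(groups)
  if (length(tab) < 2L) stop("SNR undefined: need at least 2 groups")
  if (any(tab < 2L)) {
    stop("noise undefined: group(s) with a single replicate: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  }
  X <- t(m)
  D <- switch(method,
    "OriAll_EucDist" = as.matrix(stats::dist(X)),
    "OriSingle_MedianEucDist" = {
      n <- nrow(X)
      D <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
      for (i in seq_len(n - 1L)) {
        for (j in seq.int(i + 1L, n)) {
          D[i, j] <- D[j, i] <- stats::median(abs(X[i, ] - X[j, ]))
        }
      }
      D
    },
    "OriAll_1-Cor" = 1 - stats::cor(m),
    "ReducedDim_tSNE" = {
      if (is.null(embed_fun)) {
        if (is.null(seed)) stop("ReducedDim_tSNE requires a seed")
        if (!requireNamespace("Rtsne", quietly = TRUE)) {
          stop("ReducedDim_tSNE needs the Rtsne package or an explicit ",
               "embed_fun supplying the 2-D embedding")
        }
        if (is.null(perplexity)) {
          perplexity <- min(10, (nrow(X) - 1) / 3)
        }
        set.seed(seed)
        emb <- Rtsne::Rtsne(X, dims = 2, perplexity = perplexity,
                            check_duplicates = FALSE)$Y
      } else {
        if (!is.null(seed)) set.seed(seed)
        emb <- embed_fun(X)
      }
      as.matrix(stats::dist(emb))
    })
  sn <- .signal_noise(D, groups)
  eps <- 1e-12
  degenerate <- sn$signal < eps && sn$noise < eps
  infinite <- !degenerate && sn$noise < eps
  snr_db <- if (degenerate) NA_real_
            else if (infinite) 60
            else 10 * log10(sn$signal / sn$noise)
  structure(list(snr_db = snr_db, method = method,
                 n_pcs = NULL, weights = NULL, scores = NULL,
                 groups = groups, m = length(tab),
                 n_per_group = as.integer(tab),
                 signal = sn$signal, noise = sn$noise,
                 infinite = infinite, degenerate = degenerate),
            class = "snr_result")
}

#' Leave-one-out SNR diagnosis
#'
#' Recomputes the PCA SNR with each sample excluded in turn (the
#' "11-of-12" diagnostic for the canonical batch).  If excluding one sample
#' raises the SNR by more than \code{delta_db} (default 6 dB) the batch is
#' diagnosed as a random failure of that replicate; if the full-batch SNR is
#' below \code{cutoff} and no exclusion helps, the failure is systematic;
#' otherwise the batch passes.
#'
#' @inheritParams snr_pca
#' @param delta_db gain (dB) above which an exclusion flags a random
#'   failure.
#' @param cutoff SNR acceptance cutoff in dB (default 12, the published
#'   multi-batch operating point).
#' @return class \code{snr_loo}: the full-data \code{snr_result}, a
#'   per-sample table (\code{sample}, \code{snr11}, \code{delta_db}) and a
#'   \code{diagnosis} of \code{"pass"}, \code{"random-failure"} (with the
#'   implicated sample) or \code{"systematic-failure"}.
#' @export
snr_leave_one_out <- function(m, design, delta_db = 6, cutoff = 12,
                              n_pcs = 2, scale = TRUE) {
  groups <- .aligned_groups(m, design)
  tab <- table(groups)
  if (any(tab < 3L)) {
    stop("leave-one-out needs >= 3 replicates per group so every ",
         "exclusion leaves >= 2; offending group(s): ",
         paste(names(tab)[tab < 3L], collapse = ", "))
  }
  if (!inherits(design, "study_design")) design <- study_design(design)
  full <- snr_pca(m, design, n_pcs = n_pcs, scale = scale)
  samples <- colnames(m)
  snr11 <- vapply(samples, function(s) {
    keep <- setdiff(samples, s)
    d_sub <- design[design$sample %in% keep, , drop = FALSE]
    class(d_sub) <- class(design)
    snr_pca(m[, keep, drop = FALSE], d_sub,
            n_pcs = n_pcs, scale = scale)$snr_db
  }, numeric(1L))
  gain <- snr11 - full$snr_db
  table_ <- data.frame(sample = samples, snr11 = snr11, delta_db = gain,
                       row.names = NULL, stringsAsFactors = FALSE)
  if (max(gain) > delta_db) {
    diagnosis <- "random-failure"
    implicated <- samples[which.max(gain)]
  } else if (full$snr_db < cutoff) {
    diagnosis <- "systematic-failure"
    implicated <- NA_character_
  } else {
    diagnosis <- "pass"
    implicated <- NA_character_
  }
  structure(list(full = full, table = table_, diagnosis = diagnosis,
                 implicated_sample = implicated,
                 delta_db = delta_db, cutoff = cutoff),
            class = "snr_loo")
}

#' @export
print.snr_loo <- function(x, ...) {
  cat(sprintf("Full-batch SNR: %.3f dB; diagnosis: %s%s\n",
              x$full$snr_db, x$diagnosis,
              if (!is.na(x$implicated_sample))
                paste0(" (sample ", x$implicated_sample, ")") else ""))
  best <- x$table[which.max(x$table$delta_db), ]
  cat(sprintf("  best exclusion: %s (gain %.2f dB, threshold %g dB)\n",
              best$sample, best$delta_db, x$delta_db))
  invisible(x)
}
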