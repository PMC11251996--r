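#' Two-group differential expression on log2 values
#'
#' Per-gene two-sample t-test on log2 expression with a fold-change gate: a
#' gene is called up (down) when the two-sided P value is below
#' \code{p_threshold} and the log2 fold change group A minus group B is at
#' least \code{log2(fc_threshold)} (at most \code{-log2(fc_threshold)}).
#'
#' @param log_matrix gene x sample matrix of log2 values.
#' @param design the matching \code{study_design}.
#' @param group_a,group_b group labels; the fold change is A over B.
#' @param p_threshold two-sided P-value gate (default 0.05, uncorrected; set
#'   \code{adjust = "BH"} to gate on Benjamini-Hochberg adjusted values).
#' @param fc_threshold linear fold-change gate (default 2, i.e. |log2FC| >=
#'   1).
#' @param test \code{"student"} (pooled variance, default), \code{"welch"},
#'   or \code{"moderated"} (empirical-Bayes variance shrinkage towards the
#'   mean per-gene variance with \code{prior_df} prior degrees of freedom).
#' @param prior_df prior degrees of freedom for the moderated test.
#' @param adjust \code{"none"} (default) or \code{"BH"}.
#' @return class \code{deg_table} data.frame: \code{gene}, \code{log2fc},
#'   \code{t}, \code{df}, \code{p}, \code{call} in \{up, down, non-DE\},
#'   \code{degenerate} (constant gene under student/welch: P reported as 1).
#'   The group pair and test are stored as attributes.
#' @export
call_degs <- function(log_matrix, design, group_a, group_b,
                      p_threshold = 0.05, fc_threshold = 2,
                      test = c("student", "welch", "moderated"),
                      prior_df = 4, adjust = c("none", "BH")) {
  test <- match.arg(test)
  adjust <- match.arg(adjust)
  if (!inherits(design, "study_design")) design <- study_design(design)
  a_samp <- design$sample[design$group == group_a]
  b_samp <- design$sample[design$group == group_b]
  a_samp <- intersect(a_samp, colnames(log_matrix))
  b_samp <- intersect(b_samp, colnames(log_matrix))
  if (length(a_samp) < 2L || length(b_samp) < 2L) {
    stop("both groups need >= 2 replicates present in the matrix (",
         group_a, ": ", length(a_samp), ", ",
         group_b, ": ", length(b_samp), ")")
  }
  A <- log_matrix[, a_samp, drop = FALSE]
  B <- log_matrix[, b_samp, drop = FALSE]
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- apply(A, 1L, stats::var)
  vb <- apply(B, 1L, stats::var)
  lfc <- ma - mb

  if (test == "welch") {
    se2 <- va / na + vb / nb
    tt <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    degenerate <- va == 0 & vb == 0
  } else {
    df0 <- na + nb - 2
    s2 <- ((na - 1) * va + (nb - 1) * vb) / df0
    if (test == "moderated") {
      s2_prior <- mean(s2)
      s2_post <- (prior_df * s2_prior + df0 * s2) / (prior_df + df0)
      tt <- (ma - mb) / sqrt(s2_post * (1 / na + 1 / nb))
      df <- rep(df0 + prior_df, length(tt))
      degenerate <- rep(FALSE, length(tt))
    } else {
      tt <- (ma - mb) / sqrt(s2 * (1 / na + 1 / nb))
      df <- rep(df0, length(tt))
      degenerate <- s2 == 0
    }
  }
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  p[degenerate] <- 1
  tt[degenerate] <- NA_real_
  p_gate <- if (adjust == "BH") stats::p.adjust(p, method = "BH") else p
  lfc_gate <- log2(fc_threshold)
  call <- rep("non-DE", length(lfc))
  call[p_gate < p_threshold & lfc >= lfc_gate]  <- "up"
  call[p_gate < p_threshold & lfc <= -lfc_gate] <- "down"
  out <- data.frame(gene = rownames(log_matrix), log2fc = lfc, t = tt,
                    df = df, p = p, call = call, degenerate = degenerate,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (adjust == "BH") out$p_adj <- p_gate
  structure(out, pair = c(group_a, group_b), test = test,
            p_threshold = p_threshold, fc_threshold = fc_threshold,
            class = c("deg_table", "data.frame"))
}

#' Cross-batch consensus differential-expression voting
#'
#' Counts, per gene, the batches calling it up and down.  A gene becomes a
#' consensus (reference) DEG when its vote count strictly exceeds
#' \code{min_batches} in one direction; genes exceeding the threshold in
#' both directions are excluded as discordant.  All remaining genes are
#' labeled non-DEG candidates.
#'
#' @param tables list of \code{\link{call_degs}} tables over the same group
#'   pair, one per batch.
#' @param min_batches vote threshold; a gene needs strictly more than this
#'   many concordant batch-level calls (default 6, matching a 13-batch
#'   corpus).
#' @return data.frame: \code{gene}, \code{n_up}, \code{n_down},
#'   \code{n_batches}, \code{label} in \{up, down, non-DEG\}; discordant
#'   genes are recorded in attribute \code{"discordant"}.
#' @export
consensus_degs <- function(tables, min_batches = 6) {
  if (length(tables) == 0L) stop("empty DEG table list")
  pairs <- lapply(tables, attr, "pair")
  if (!all(vapply(pairs, identical, logical(1L), pairs[[1L]]))) {
    stop("all DEG tables must cover the same ordered group pair")
  }
  genes <- sort(unique(unlist(lapply(tables, `[[`, "gene"))))
  n_up <- n_down <- stats::setNames(integer(length(genes)), genes)
  for (tb in tables) {
    n_up[tb$gene[tb$call == "up"]] <- n_up[tb$gene[tb$call == "up"]] + 1L
    n_down[tb$gene[tb$call == "down"]] <-
      n_down[tb$gene[tb$call == "down"]] + 1L
  }
  label <- rep("non-DEG", length(genes))
  label[n_up > min_batches] <- "up"
  label[n_down > min_batches] <- "down"
  discordant <- n_up > min_batches & n_down > min_batches
  out <- data.frame(gene = genes, n_up = as.integer(n_up),
                    n_down = as.integer(n_down),
                    n_batches = length(tables), label = label,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[!discordant, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, pair = pairs[[1L]], min_batches = min_batches,
            discordant = genes[discordant],
            class = c("consensus_degs", "data.frame"))
}
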