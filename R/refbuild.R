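## Internal: parse a pair specification ("D5/D6" or c("D5","D6")).
.parse_pair <- function(pair) {
  if (length(pair) == 1L && grepl("/", pair)) {
    pair <- strsplit(pair, "/", fixed = TRUE)[[1L]]
  }
  if (length(pair) != 2L) stop("a pair must be two group labels")
  as.character(pair)
}

#' Build ratio-based reference fold changes from high-quality batches
#'
#' The characterization step of the reference-dataset workflow.  For each
#' requested ordered group pair, per-batch log2 fold changes (difference of
#' replicate-mean log2 values) are computed in every batch and genes are
#' gated on: (a) consensus detectability in both groups across all batches
#' (requires count layers; disabled with \code{detect = FALSE}); (b) a
#' batch-level differential-expression P value below \code{p_gate} in at
#' least \code{p_in_batches} batches; (c) optionally, no significant
#' difference between library-preparation protocols (two-sided P > 0.05
#' \emph{or} a between-protocol fold change strictly between 1/2 and 2).
#' The reference value is the arithmetic mean of per-batch log2 ratios
#' (i.e. the log of the geometric-mean linear ratio), and
#' consensus vote counts yield the reference DEG label.
#'
#' @param batches list of \code{expression_study} objects, one per
#'   high-quality batch (single-batch studies).
#' @param pairs list of ordered group pairs (each \code{c(num, den)} or
#'   \code{"num/den"}).
#' @param p_in_batches minimum number of batches with P < \code{p_gate}
#'   (gate b; default 4, matching a 13-batch corpus).
#' @param p_gate batch-level P threshold for gate (b).
#' @param min_batches_deg consensus vote threshold for the reference DEG
#'   label (strictly-greater rule; default 6).
#' @param detect apply the consensus-detectability gate (a); requires every
#'   batch to carry counts.
#' @param protocol_gate apply gate (c) when the designs carry a
#'   \code{protocol} column with more than one level.
#' @param test,fc_threshold,offset passed to the per-batch DEG test and log
#'   transform.
#' @param min_reads,min_replicates detectability thresholds.
#' @return a \code{\link{reference_dataset}} with \code{log2fc_ref},
#'   \code{n_batches}, vote counts and \code{deg_label}; uncertainty fields
#'   are NA until \code{\link{uncertainty_bundle}} fills them.  The
#'   per-batch fold-change matrices are attached as attribute
#'   \code{"batch_fc"} (a list, one genes x batches matrix per pair) for
#'   the uncertainty step.
#' @export
build_reference_ratios <- function(batches, pairs,
                                   p_in_batches = 4, p_gate = 0.05,
                                   min_batches_deg = 6,
                                   detect = TRUE, protocol_gate = TRUE,
                                   test = "student", fc_threshold = 2,
                                   offset = 0.01,
                                   min_reads = 3, min_replicates = 2) {
  if (length(batches) < 2L) stop("need >= 2 high-quality batches")
  if (!is.list(pairs) || length(pairs) == 0L) {
    if (is.character(pairs)) pairs <- as.list(pairs)
    else stop("pairs must be a non-empty list")
  }
  pairs <- lapply(pairs, .parse_pair)
  logm <- lapply(batches, log_transform, offset = offset)
  masks <- if (detect) {
    lapply(batches, detectability_mask,
           min_reads = min_reads, min_replicates = min_replicates)
  } else NULL
  protocols <- vapply(batches, function(b) {
    if ("protocol" %in% names(b$design)) b$design$protocol[1L]
    else NA_character_
  }, character(1L))
  use_protocol <- protocol_gate && !anyNA(protocols) &&
    length(unique(protocols)) > 1L

  records <- list()
  batch_fc <- list()
  for (pr in pairs) {
    pair_id <- paste(pr, collapse = "/")
    for (b in batches) {
      if (!all(pr %in% b$design$group)) {
        stop("pair group(s) ", paste(setdiff(pr, b$design$group),
                                     collapse = ", "),
             " absent in a batch")
      }
    }
    genes <- Reduce(intersect, lapply(batches,
                                      function(b) rownames(b$values)))
    if (detect) {
      det_a <- consensus_detectable(masks, pr[1L], require_all = TRUE)
      det_b <- consensus_detectable(masks, pr[2L], require_all = TRUE)
      genes <- intersect(genes, intersect(det_a, det_b))
    }
    if (length(genes) == 0L) {
      warning("no genes pass the gates for pair ", pair_id)
      next
    }
    tabs <- vector("list", length(batches))
    fc <- matrix(NA_real_, nrow = length(genes), ncol = length(batches),
                 dimnames = list(genes, paste0("b", seq_along(batches))))
    pvals <- fc
    for (i in seq_along(batches)) {
      tb <- call_degs(logm[[i]][genes, , drop = FALSE], batches[[i]]$design,
                      pr[1L], pr[2L], test = test,
                      fc_threshold = fc_threshold)
      tabs[[i]] <- tb
      fc[tb$gene, i] <- tb$log2fc
      pvals[tb$gene, i] <- tb$p
    }
    keep <- rowSums(pvals < p_gate, na.rm = TRUE) >= p_in_batches
    if (use_protocol) {
      pro <- factor(protocols)
      keep_pro <- vapply(seq_len(nrow(fc)), function(g) {
        x <- split(fc[g, ], pro)
        if (any(vapply(x, length, integer(1L)) < 2L)) return(TRUE)
        pv <- tryCatch(stats::t.test(x[[1L]], x[[2L]])$p.value,
                       error = function(e) 1)
        dfc <- abs(mean(x[[1L]]) - mean(x[[2L]]))
        pv > 0.05 || dfc < log2(fc_threshold)
      }, logical(1L))
      keep <- keep & keep_pro
    }
    genes_kept <- genes[keep]
    if (length(genes_kept) == 0L) {
      warning("no genes pass the gates for pair ", pair_id)
      next
    }
    votes <- consensus_degs(tabs, min_batches = min_batches_deg)
    votes <- votes[match(genes_kept, votes$gene), , drop = FALSE]
    records[[pair_id]] <- data.frame(
      gene = genes_kept, pair = pair_id,
      log2fc_ref = rowMeans(fc[genes_kept, , drop = FALSE]),
      n_batches = length(batches),
      n_up = votes$n_up, n_down = votes$n_down,
      u_char = NA_real_, u_bb = NA_real_, u_s = NA_real_,
      u_c = NA_real_, k = NA_real_, U = NA_real_,
      deg_label = votes$label,
      row.names = NULL, stringsAsFactors = FALSE)
    batch_fc[[pair_id]] <- fc[genes_kept, , drop = FALSE]
  }
  if (length(records) == 0L) {
    warning("no batches/genes passed; returning empty reference")
    empty <- stats::setNames(
      as.data.frame(matrix(nrow = 0L, ncol = length(.ref_columns))),
      .ref_columns)
    return(reference_dataset(empty, validate = FALSE))
  }
  ref <- reference_dataset(do.call(rbind, records), validate = FALSE)
  attr(ref, "batch_fc") <- batch_fc
  ref
}

#' Homogeneity assessment (one replicated unit vs many single units)
#'
#' Per-gene ANOVA-style comparison of between-unit and within-unit
#' variance on ratio-based values, for the unbalanced design in which one
#' packaging unit is measured r times (within-unit arm) and u further units
#' once each (between-unit arm).  The F statistic is the between-arm
#' variance over the within-unit variance with (u-1, r-1) degrees of
#' freedom; the two-sided P is Benjamini-Hochberg adjusted across genes and
#' a gene passes when the adjusted P exceeds 0.05.  The between-unit
#' variance component is \code{s1_sq = max(v_between - s2_sq, 0)}.
#'
#' @param values gene x measurement matrix (ratio-based expression).
#' @param units character/factor of unit labels, one per column.
#' @param alpha significance level for the pass rule.
#' @return class \code{homogeneity_result} data.frame: \code{gene},
#'   \code{s1_sq}, \code{s2_sq}, \code{v_between}, \code{f}, \code{p},
#'   \code{p_adj}, \code{pass}, \code{degenerate} (zero within-unit
#'   variance; excluded from the FDR set).  Degrees of freedom and the
#'   between-measurement count are attributes.
#' @export
homogeneity_test <- function(values, units, alpha = 0.05) {
  units <- as.character(units)
  if (length(units) != ncol(values)) {
    stop("units must have one label per column of values")
  }
  tab <- table(units)
  rep_units <- names(tab)[tab >= 2L]
  single_units <- names(tab)[tab == 1L]
  if (length(rep_units) != 1L) {
    stop("need exactly one replicated unit (got ", length(rep_units), ")")
  }
  if (length(single_units) < 2L) {
    stop("need >= 2 single-measurement units")
  }
  within_idx <- which(units == rep_units)
  between_idx <- which(units %in% single_units)
  r <- length(within_idx)
  u <- length(between_idx)
  s2_sq <- apply(values[, within_idx, drop = FALSE], 1L, stats::var)
  v_b <- apply(values[, between_idx, drop = FALSE], 1L, stats::var)
  degenerate <- s2_sq == 0
  f <- v_b / s2_sq
  f[degenerate] <- NA_real_
  pf_up <- stats::pf(f, u - 1L, r - 1L, lower.tail = FALSE)
  p <- 2 * pmin(pf_up, 1 - pf_up)
  p <- pmin(p, 1)
  p_adj <- rep(NA_real_, length(p))
  p_adj[!degenerate] <- stats::p.adjust(p[!degenerate], method = "BH")
  out <- data.frame(gene = rownames(values),
                    s1_sq = pmax(v_b - s2_sq, 0), s2_sq = s2_sq,
                    v_between = v_b, f = f, p = p, p_adj = p_adj,
                    pass = !degenerate & p_adj > alpha,
                    degenerate = degenerate,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, df_within = r - 1L, df_between = u - 1L, n_between = u,
            class = c("homogeneity_result", "data.frame"))
}

#' Long-term stability assessment by per-gene regression
#'
#' Ordinary least squares of each gene's ratio-based expression on time
#' (months).  A gene is stable when the absolute slope is smaller than its
#' standard error times the two-sided 95\% critical t value with n-2
#' degrees of freedom.
#'
#' @param values gene x measurement matrix.
#' @param timepoints numeric vector of months, one per column (>= 3
#'   distinct values).
#' @param confidence confidence level of the slope test (default 0.95).
#' @return class \code{stability_result} data.frame: \code{gene},
#'   \code{b0}, \code{b1}, \code{se_b1}, \code{t_crit}, \code{pass}.  The
#'   number of measurements and the maximum timepoint (default shelf-life
#'   horizon for the instability uncertainty) are attributes.
#' @export
stability_test <- function(values, timepoints, confidence = 0.95) {
  timepoints <- as.numeric(timepoints)
  if (length(timepoints) != ncol(values)) {
    stop("timepoints must have one value per column of values")
  }
  if (length(unique(timepoints)) < 3L) {
    stop("need >= 3 distinct timepoints")
  }
  n <- length(timepoints)
  xbar <- mean(timepoints)
  sxx <- sum((timepoints - xbar)^2)
  if (sxx == 0) stop("zero variance in timepoints")
  xc <- timepoints - xbar
  b1 <- as.numeric(values %*% xc) / sxx
  b0 <- rowMeans(values) - b1 * xbar
  fitted <- outer(b1, timepoints) + b0
  rss <- rowSums((values - fitted)^2)
  se_b1 <- sqrt(rss / (n - 2) / sxx)
  t_crit <- stats::qt(1 - (1 - confidence) / 2, df = n - 2)
  # non-strict comparison so an exactly constant series (b1 = 0, se = 0)
  # passes while exact nonzero drift (se = 0, |b1| > 0) fails
  out <- data.frame(gene = rownames(values), b0 = b0, b1 = b1,
                    se_b1 = se_b1, t_crit = t_crit,
                    pass = abs(b1) <= se_b1 * t_crit,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, n = n, t_max = max(timepoints), confidence = confidence,
            class = c("stability_result", "data.frame"))
}

#' Between-unit uncertainty from variance components
#'
#' Absolute between-bottle uncertainty: when the between-unit component
#' exceeds the within-unit variance, \code{sqrt((s1_sq - s2_sq) / n)};
#' otherwise (including ties) the detectability-limited form
#' \code{sqrt(s2_sq / n) * (2 / df_s2)^(1/4)}.
#'
#' @param s1_sq between-unit variance component (here the between-arm
#'   variance, so s1_sq - s2_sq is the excess over within-unit noise).
#'   Vectorized.
#' @param s2_sq within-unit variance.
#' @param df_s2 degrees of freedom of \code{s2_sq}.
#' @param n number of between-unit measurements.
#' @return list with \code{u_bb} (absolute scale) and \code{branch}
#'   (\code{"excess"} or \code{"floor"}).
#' @export
u_bb_from_variances <- function(s1_sq, s2_sq, df_s2, n) {
  excess <- s1_sq > s2_sq
  u <- sqrt(s2_sq / n) * (2 / df_s2)^(1 / 4)
  u[excess] <- sqrt((s1_sq[excess] - s2_sq[excess]) / n)
  list(u_bb = u, branch = ifelse(excess, "excess", "floor"))
}

#' Uncertainty budget of reference fold changes
#'
#' Combines, per (gene, pair) record, the three uncertainty sources of a
#' reference value: characterization (relative standard error of the mean
#' of the per-batch log2 ratios), between-unit inhomogeneity
#' (\code{\link{u_bb_from_variances}}) and long-term instability
#' (\code{t_horizon} times the slope standard error).  The between-unit and
#' instability terms are converted to relative scale by dividing by the
#' absolute characterization mean before quadrature combination
#' (\code{u_c = sqrt(u_char^2 + u_bb^2 + u_s^2)}), and the expanded
#' uncertainty is \code{U = k * u_c}.  Records whose mean ratio is within
#' \code{epsilon} of zero cannot carry a relative uncertainty and are
#' flagged unquantifiable.
#'
#' @param char gene x batch matrix of per-batch log2 ratios for one pair
#'   (e.g. a component of \code{attr(ref, "batch_fc")}); needs >= 2
#'   columns.
#' @param hom a \code{\link{homogeneity_test}} result, or NULL to drop the
#'   inhomogeneity term.
#' @param stab a \code{\link{stability_test}} result, or NULL to drop the
#'   instability term.
#' @param t_horizon shelf-life horizon in months for the instability term
#'   (default: the maximum observed timepoint of \code{stab}).
#' @param k expansion factor (default 2, ~95\% coverage).
#' @param n_bb number of between-unit measurements (default taken from
#'   \code{hom}).
#' @param relative convert u_bb and u_s to relative scale before
#'   combination (default TRUE; FALSE combines on absolute scale).
#' @param epsilon characterization means with absolute value below this are
#'   flagged unquantifiable.
#' @return data.frame per gene: \code{xbar}, \code{n}, \code{u_char},
#'   \code{u_bb}, \code{u_s}, \code{u_c}, \code{k}, \code{U},
#'   \code{bb_branch}, \code{quantifiable}.
#' @export
uncertainty_bundle <- function(char, hom = NULL, stab = NULL,
                               t_horizon = NULL, k = 2, n_bb = NULL,
                               relative = TRUE, epsilon = 1e-6) {
  char <- as.matrix(char)
  n <- ncol(char)
  if (n < 2L) stop("characterization needs >= 2 batches")
  genes <- rownames(char)
  xbar <- rowMeans(char)
  quantifiable <- abs(xbar) > epsilon
  sem <- sqrt(apply(char, 1L, stats::var) / n)
  u_char <- sem / abs(xbar)

  u_bb_abs <- rep(0, length(genes))
  branch <- rep(NA_character_, length(genes))
  if (!is.null(hom)) {
    idx <- match(genes, hom$gene)
    if (anyNA(idx)) {
      stop("homogeneity result missing gene(s): ",
           paste(utils::head(genes[is.na(idx)], 5L), collapse = ", "))
    }
    if (is.null(n_bb)) n_bb <- attr(hom, "n_between")
    bb <- u_bb_from_variances(hom$v_between[idx], hom$s2_sq[idx],
                              attr(hom, "df_within"), n_bb)
    u_bb_abs <- bb$u_bb
    branch <- bb$branch
  }
  u_s_abs <- rep(0, length(genes))
  if (!is.null(stab)) {
    idx <- match(genes, stab$gene)
    if (anyNA(idx)) {
      stop("stability result missing gene(s): ",
           paste(utils::head(genes[is.na(idx)], 5L), collapse = ", "))
    }
    if (is.null(t_horizon)) t_horizon <- attr(stab, "t_max")
    u_s_abs <- t_horizon * stab$se_b1[idx]
  }
  scale_den <- if (relative) abs(xbar) else 1
  u_bb <- u_bb_abs / scale_den
  u_s <- u_s_abs / scale_den
  u_c <- sqrt(u_char^2 + u_bb^2 + u_s^2)
  data.frame(gene = genes, xbar = xbar, n = n,
             u_char = u_char, u_bb = u_bb, u_s = u_s, u_c = u_c,
             k = k, U = k * u_c, bb_branch = branch,
             quantifiable = quantifiable,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fill a reference dataset's uncertainty columns
#'
#' Convenience wrapper: computes \code{\link{uncertainty_bundle}} for each
#' pair of a reference built by \code{\link{build_reference_ratios}} and
#' writes the budget into the reference records.
#'
#' @param ref a \code{reference_dataset} carrying the \code{"batch_fc"}
#'   attribute.
#' @inheritParams uncertainty_bundle
#' @return the reference with \code{u_char}, \code{u_bb}, \code{u_s},
#'   \code{u_c}, \code{k}, \code{U} filled for quantifiable records.
#' @export
add_uncertainty <- function(ref, hom = NULL, stab = NULL,
                            t_horizon = NULL, k = 2, n_bb = NULL,
                            relative = TRUE, epsilon = 1e-6) {
  batch_fc <- attr(ref, "batch_fc")
  if (is.null(batch_fc)) {
    stop("reference lacks per-batch fold changes; build it with ",
         "build_reference_ratios()")
  }
  for (pair_id in names(batch_fc)) {
    ub <- uncertainty_bundle(batch_fc[[pair_id]], hom = hom, stab = stab,
                             t_horizon = t_horizon, k = k, n_bb = n_bb,
                             relative = relative, epsilon = epsilon)
    rows <- which(ref$pair == pair_id)
    idx <- match(ref$gene[rows], ub$gene)
    ok <- !is.na(idx) & ub$quantifiable[idx]
    for (col in c("u_char", "u_bb", "u_s", "u_c", "k", "U")) {
      ref[[col]][rows[ok]] <- ub[[col]][idx[ok]]
    }
  }
  ref
}
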