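#' Per-pair log2 fold changes of a test dataset
#'
#' Replicate means are taken per group first (on the log2 scale), then the
#' difference numerator-group mean minus denominator-group mean is the
#' test dataset's per-gene log2 fold change for a pair.
#'
#' @param log_matrix gene x sample matrix of log2 values.
#' @param design the matching \code{study_design}.
#' @param pair ordered group pair (\code{c(num, den)} or \code{"num/den"}).
#' @return named numeric vector of per-gene log2 fold changes.
#' @export
pair_log2fc <- function(log_matrix, design, pair) {
  pair <- .parse_pair(pair)
  if (!inherits(design, "study_design")) design <- study_design(design)
  a <- intersect(design$sample[design$group == pair[1L]],
                 colnames(log_matrix))
  b <- intersect(design$sample[design$group == pair[2L]],
                 colnames(log_matrix))
  if (length(a) == 0L || length(b) == 0L) {
    stop("pair group(s) absent from matrix: ", paste(pair, collapse = "/"))
  }
  rowMeans(log_matrix[, a, drop = FALSE]) -
    rowMeans(log_matrix[, b, drop = FALSE])
}

## Internal: intersect a test fold-change vector with reference records of
## one pair.
.ref_intersection <- function(test_fc, ref, pair) {
  pair_id <- paste(.parse_pair(pair), collapse = "/")
  rr <- ref[ref$pair == pair_id, , drop = FALSE]
  genes <- intersect(names(test_fc), rr$gene)
  if (length(genes) < 3L) {
    stop("fewer than 3 genes shared between test dataset and reference ",
         "for pair ", pair_id)
  }
  list(test = test_fc[genes],
       ref = stats::setNames(rr$log2fc_ref[match(genes, rr$gene)], genes),
       ref_records = rr)
}

#' Relative correlation with a reference dataset
#'
#' Pearson correlation between a test dataset's per-gene log2 fold changes
#' for a pair and the reference values over the shared genes.
#'
#' @param test_fc named per-gene log2 fold-change vector (see
#'   \code{\link{pair_log2fc}}).
#' @param ref a \code{reference_dataset}.
#' @param pair ordered group pair.
#' @return list: \code{rc} in [-1, 1] and \code{n_genes} used.
#' @export
relative_correlation <- function(test_fc, ref, pair) {
  z <- .ref_intersection(test_fc, ref, pair)
  if (stats::sd(z$test) == 0 || stats::sd(z$ref) == 0) {
    stop("degenerate: zero variance in test or reference fold changes")
  }
  list(rc = stats::cor(z$test, z$ref), n_genes = length(z$test))
}

#' RMSE against a reference dataset
#'
#' Root mean square difference, on the log2 scale, between test and
#' reference fold changes over the shared genes.
#'
#' @inheritParams relative_correlation
#' @return list: \code{rmse} >= 0 and \code{n_genes} used.
#' @export
rmse_vs_reference <- function(test_fc, ref, pair) {
  z <- .ref_intersection(test_fc, ref, pair)
  list(rmse = sqrt(mean((z$test - z$ref)^2)), n_genes = length(z$test))
}

#' Matthews correlation coefficient from a confusion table
#'
#' \code{(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))}; defined as
#' 0 (flagged) when any factor of the denominator vanishes.
#'
#' @param tp,tn,fp,fn non-negative counts.
#' @return list: \code{mcc} and \code{degenerate} flag.
#' @export
mcc_from_counts <- function(tp, tn, fp, fn) {
  fac <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  if (any(fac == 0)) return(list(mcc = 0, degenerate = TRUE))
  list(mcc = (tp * tn - fp * fn) / sqrt(prod(fac)), degenerate = FALSE)
}

#' MCC of differential calls against reference labels
#'
#' Evaluation is restricted to reference genes labeled up, down or non-DEG
#' for the pair (and present in the test table).  By default counting is
#' direction aware: a test DE call matching a reference DEG's direction is
#' a true positive, while a DE call with the opposite direction counts as
#' one false positive and one false negative for that gene (so the counts
#' then sum to the evaluated genes plus the mismatches).  With
#' \code{direction_aware = FALSE} any DE call on a reference DEG is a true
#' positive and the four counts always sum to the evaluated gene count.
#'
#' @param test_degs a \code{\link{call_degs}} table.
#' @param ref a \code{reference_dataset} containing both DEG and non-DEG
#'   labels for the pair.
#' @param pair ordered group pair.
#' @param direction_aware see above.
#' @return list: \code{mcc}, \code{counts} (named TP/TN/FP/FN vector),
#'   \code{n_genes} evaluated, \code{degenerate} flag.
#' @export
mcc_vs_reference <- function(test_degs, ref, pair = attr(test_degs, "pair"),
                             direction_aware = TRUE) {
  pair_id <- paste(.parse_pair(pair), collapse = "/")
  rr <- ref[ref$pair == pair_id &
              ref$deg_label %in% c("up", "down", "non-DEG"), , drop = FALSE]
  if (!any(rr$deg_label %in% c("up", "down"))) {
    stop("reference has no DEG-labeled genes for pair ", pair_id)
  }
  if (!any(rr$deg_label == "non-DEG")) {
    stop("reference has no non-DEG-labeled genes for pair ", pair_id)
  }
  genes <- intersect(test_degs$gene, rr$gene)
  if (length(genes) == 0L) stop("no shared genes with reference")
  ref_lab <- rr$deg_label[match(genes, rr$gene)]
  test_lab <- test_degs$call[match(genes, test_degs$gene)]
  ref_de <- ref_lab %in% c("up", "down")
  test_de <- test_lab %in% c("up", "down")
  if (direction_aware) {
    match_dir <- ref_de & test_de & ref_lab == test_lab
    mismatch <- ref_de & test_de & ref_lab != test_lab
    tp <- sum(match_dir)
    fn <- sum(ref_de & !test_de) + sum(mismatch)
    fp <- sum(!ref_de & test_de) + sum(mismatch)
    tn <- sum(!ref_de & !test_de)
  } else {
    tp <- sum(ref_de & test_de)
    fn <- sum(ref_de & !test_de)
    fp <- sum(!ref_de & test_de)
    tn <- sum(!ref_de & !test_de)
  }
  mc <- mcc_from_counts(tp, tn, fp, fn)
  list(mcc = mc$mcc,
       counts = c(TP = tp, TN = tn, FP = fp, FN = fn),
       n_genes = length(genes), degenerate = mc$degenerate)
}

#' Total quality score
#'
#' Geometric mean of the SNR (dB) and the relative correlation, the two
#' complementary reference-independent and reference-dependent summary
#' metrics.  Negative inputs are clipped to zero (a geometric mean of
#' negatives is undefined) and the clipping is flagged.
#'
#' @param snr_db SNR in decibels.
#' @param rc relative correlation.
#' @return list: \code{score} and \code{clipped} flag.
#' @export
total_score <- function(snr_db, rc) {
  clipped <- snr_db < 0 || rc < 0
  list(score = sqrt(max(snr_db, 0) * max(rc, 0)), clipped = clipped)
}

#' Data-driven metric cutoffs
#'
#' Mean minus one sample standard deviation for metrics where larger is
#' better (SNR, RC, MCC), mean plus one for RMSE.
#'
#' @param values numeric metric values across batches (>= 2).
#' @param direction \code{"lower-bound"} (default) or \code{"upper-bound"}.
#' @return the cutoff.
#' @export
derive_cutoffs <- function(values, direction = c("lower-bound",
                                                 "upper-bound")) {
  direction <- match.arg(direction)
  if (length(values) < 2L) stop("need >= 2 values to derive a cutoff")
  if (direction == "lower-bound") mean(values) - stats::sd(values)
  else mean(values) + stats::sd(values)
}

## Internal: reference metrics of one batch against a reference.
.batch_ref_metrics <- function(study, ref, pairs, offset = 0.01) {
  logm <- log_transform(study, offset = offset)
  vals <- lapply(pairs, function(pr) {
    fc <- pair_log2fc(logm, study$design, pr)
    rc <- relative_correlation(fc, ref, pr)
    rm <- rmse_vs_reference(fc, ref, pr)
    degs <- call_degs(logm, study$design, .parse_pair(pr)[1L],
                      .parse_pair(pr)[2L])
    mc <- tryCatch(mcc_vs_reference(degs, ref, pr)$mcc,
                   error = function(e) NA_real_)
    c(rc = rc$rc, rmse = rm$rmse, mcc = mc)
  })
  colMeans(do.call(rbind, vals), na.rm = TRUE)
}

#' Cross-validation of reference-dependent metrics
#'
#' Repeatedly splits the batches into a training set used to build the
#' reference and computes RC/RMSE/MCC for every batch against that
#' reference, labeling each value train or validation.  If the metrics
#' reflect intrinsic batch quality rather than reference membership, a
#' batch's mean train value and mean validation value agree (high
#' correlation across batches).  Batch-count-dependent gates are scaled
#' proportionally to the training size (rounded, floor of 2).
#'
#' @param batches list of \code{expression_study} objects.
#' @param pairs list of ordered group pairs for the reference.
#' @param n_rounds number of random splits (default 30).
#' @param train_size batches per training set (must be < number of
#'   batches).
#' @param seed mandatory integer seed for the splits.
#' @param detect,offset passed to \code{\link{build_reference_ratios}}.
#' @return class \code{cv_reference} list: \code{metrics} (long data.frame
#'   round/batch/role/rc/rmse/mcc), \code{train_validation_correlation}
#'   (per metric, across batches), \code{validation_cutoffs} (via
#'   \code{\link{derive_cutoffs}} on validation values).
#' @export
cross_validate_reference <- function(batches, pairs, n_rounds = 30,
                                     train_size = 13, seed,
                                     detect = TRUE, offset = 0.01) {
  if (missing(seed)) stop("seed is mandatory")
  nb <- length(batches)
  if (train_size >= nb) stop("train_size must be smaller than #batches")
  if (is.null(names(batches))) {
    names(batches) <- paste0("batch", seq_len(nb))
  }
  p_in <- max(2L, round(train_size * 4 / 13))
  min_deg <- max(2L, round(train_size * 6 / 13))
  set.seed(seed)
  rows <- list()
  for (r in seq_len(n_rounds)) {
    train <- sort(sample.int(nb, train_size))
    ref <- build_reference_ratios(batches[train], pairs,
                                  p_in_batches = p_in,
                                  min_batches_deg = min_deg,
                                  detect = detect, offset = offset)
    for (i in seq_len(nb)) {
      mets <- .batch_ref_metrics(batches[[i]], ref, pairs,
                                 offset = offset)
      rows[[length(rows) + 1L]] <- data.frame(
        round = r, batch = names(batches)[i],
        role = if (i %in% train) "train" else "validation",
        rc = mets[["rc"]], rmse = mets[["rmse"]], mcc = mets[["mcc"]],
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  metrics <- do.call(rbind, rows)
  cors <- vapply(c("rc", "rmse", "mcc"), function(mn) {
    tr <- tapply(metrics[[mn]][metrics$role == "train"],
                 metrics$batch[metrics$role == "train"], mean)
    va <- tapply(metrics[[mn]][metrics$role == "validation"],
                 metrics$batch[metrics$role == "validation"], mean)
    common <- intersect(names(tr), names(va))
    if (length(common) < 3L) return(NA_real_)
    stats::cor(tr[common], va[common])
  }, numeric(1L))
  vmask <- metrics$role == "validation"
  cutoffs <- list(
    rc = derive_cutoffs(metrics$rc[vmask], "lower-bound"),
    rmse = derive_cutoffs(metrics$rmse[vmask], "upper-bound"),
    mcc = derive_cutoffs(metrics$mcc[vmask], "lower-bound"))
  structure(list(metrics = metrics,
                 train_validation_correlation = cors,
                 validation_cutoffs = cutoffs,
                 n_rounds = n_rounds, train_size = train_size,
                 seed = seed),
            class = "cv_reference")
}

#' @export
print.cv_reference <- function(x, ...) {
  cat("Reference cross-validation:", x$n_rounds, "rounds, train size",
      x$train_size, "\n")
  cat("  train-vs-validation correlation:",
      paste(names(x$train_validation_correlation),
            sprintf("%.3f", x$train_validation_correlation),
            sep = "=", collapse = ", "), "\n")
  cat("  validation cutoffs: rc >=", sprintf("%.3f", x$validation_cutoffs$rc),
      "; rmse <=", sprintf("%.3f", x$validation_cutoffs$rmse),
      "; mcc >=", sprintf("%.3f", x$validation_cutoffs$mcc), "\n")
  invisible(x)
}

#' Metric distributions over reduced group/replicate designs
#'
#' Enumerates, within one batch, every way to keep G of the groups and R of
#' each kept group's replicates, and computes the requested metric per
#' combination ("G2R2" on a 4x3 design gives C(4,2) * C(3,2)^2 = 54
#' combinations).  Modes: \code{"snr"} (PCA SNR of the subset),
#' \code{"rc"} (mean relative correlation over the reference pairs
#' evaluable in the subset), \code{"ratio-denominator"} (PCA SNR of the
#' full batch after ratio transform with the subset's samples pooled as
#' denominator, probing cheap in-batch reference designs).
#'
#' @param study a single-batch \code{expression_study}.
#' @param groups_range,reps_range integer vectors of G and R values to
#'   evaluate.
#' @param mode see above.
#' @param ref reference dataset (required for \code{mode = "rc"}).
#' @param offset pseudo-value for the log transform.
#' @param n_pcs,scale passed to \code{\link{snr_pca}}.
#' @return data.frame: \code{G}, \code{R}, \code{combo}, \code{groups},
#'   \code{value}.
#' @export
evaluate_subset_designs <- function(study, groups_range, reps_range,
                                    mode = c("snr", "rc",
                                             "ratio-denominator"),
                                    ref = NULL, offset = 0.01,
                                    n_pcs = 2, scale = TRUE) {
  mode <- match.arg(mode)
  if (mode == "rc" && is.null(ref)) stop("mode 'rc' needs a reference")
  d <- study$design
  logm <- log_transform(study, offset = offset)
  all_groups <- unique(d$group)
  out <- list()
  for (G in groups_range) {
    if (G > length(all_groups)) {
      stop("requested G = ", G, " exceeds available groups")
    }
    if (mode == "snr" && G < 2L) stop("SNR needs G >= 2")
    gsets <- utils::combn(all_groups, G, simplify = FALSE)
    for (gs in gsets) {
      for (R in reps_range) {
        per_group <- lapply(gs, function(g) {
          reps <- sort(d$replicate[d$group == g])
          if (R > length(reps)) {
            stop("requested R = ", R, " exceeds replicates of group ", g)
          }
          utils::combn(reps, R, simplify = FALSE)
        })
        grid <- expand.grid(lapply(per_group, seq_along))
        for (row in seq_len(nrow(grid))) {
          keep <- unlist(lapply(seq_along(gs), function(i) {
            reps <- per_group[[i]][[grid[row, i]]]
            d$sample[d$group == gs[i] & d$replicate %in% reps]
          }))
          value <- switch(mode,
            "snr" = {
              d_sub <- d[d$sample %in% keep, , drop = FALSE]
              class(d_sub) <- class(d)
              snr_pca(logm[, keep, drop = FALSE], d_sub,
                      n_pcs = n_pcs, scale = scale)$snr_db
            },
            "rc" = {
              d_sub <- d[d$sample %in% keep, , drop = FALSE]
              class(d_sub) <- class(d)
              prs <- unique(ref$pair)
              vals <- vapply(prs, function(pid) {
                pr <- .parse_pair(pid)
                if (!all(pr %in% d_sub$group)) return(NA_real_)
                fc <- pair_log2fc(logm[, keep, drop = FALSE], d_sub, pr)
                tryCatch(relative_correlation(fc, ref, pr)$rc,
                         error = function(e) NA_real_)
              }, numeric(1L))
              mean(vals, na.rm = TRUE)
            },
            "ratio-denominator" = {
              den_mean <- rowMeans(logm[, keep, drop = FALSE])
              ratios <- logm - den_mean
              snr_pca(ratios, d, n_pcs = n_pcs, scale = scale)$snr_db
            })
          out[[length(out) + 1L]] <- data.frame(
            G = G, R = R, combo = length(out) + 1L,
            groups = paste(gs, collapse = "+"), value = value,
            row.names = NULL, stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Assemble a per-batch quality-control report
#'
#' Computes the SNR (with leave-one-out diagnosis when every group carries
#' at least three replicates) and, when a reference dataset is supplied,
#' the reference-dependent metrics (RC, RMSE, MCC, averaged over the
#' reference's pairs) and the total quality score, then flags each metric
#' against its cutoff.
#'
#' @param study a single-batch \code{expression_study}.
#' @param ref optional \code{reference_dataset}.
#' @param cutoffs named list with elements \code{snr}, \code{rc},
#'   \code{rmse}, \code{mcc}; the defaults (12, 0.89, 0.38, 0.54) are the
#'   published multi-batch operating points, shipped as documented
#'   defaults.
#' @param pairs group pairs to evaluate against the reference (default:
#'   the pairs present in the reference).
#' @param offset pseudo-value for the log transform.
#' @param delta_db leave-one-out gain threshold (dB).
#' @return class \code{qc_report}: metric values, pass/fail flags,
#'   leave-one-out table, diagnosis and final flag.
#' @export
qc_report <- function(study, ref = NULL,
                      cutoffs = list(snr = 12, rc = 0.89,
                                     rmse = 0.38, mcc = 0.54),
                      pairs = NULL, offset = 0.01, delta_db = 6) {
  logm <- log_transform(study, offset = offset)
  snr <- snr_pca(logm, study$design)
  loo <- tryCatch(
    snr_leave_one_out(logm, study$design, delta_db = delta_db,
                      cutoff = cutoffs$snr),
    error = function(e) NULL)
  metrics <- list(snr = snr$snr_db)
  flags <- list(snr = snr$snr_db >= cutoffs$snr)
  if (!is.null(ref)) {
    if (is.null(pairs)) pairs <- as.list(unique(ref$pair))
    mets <- .batch_ref_metrics(study, ref, pairs, offset = offset)
    ts <- total_score(snr$snr_db, mets[["rc"]])
    metrics$rc <- mets[["rc"]]
    metrics$rmse <- mets[["rmse"]]
    metrics$mcc <- mets[["mcc"]]
    metrics$total_score <- ts$score
    flags$rc <- mets[["rc"]] >= cutoffs$rc
    flags$rmse <- mets[["rmse"]] <= cutoffs$rmse
    flags$mcc <- mets[["mcc"]] >= cutoffs$mcc
  }
  final <- all(unlist(flags))
  structure(list(metrics = metrics, flags = flags,
                 final_flag = if (final) "pass" else "fail",
                 loo = loo,
                 diagnosis = if (!is.null(loo)) loo$diagnosis else NA,
                 cutoffs = cutoffs,
                 reference_used = !is.null(ref)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report (reference",
      if (x$reference_used) "supplied" else "not supplied", ")\n")
  for (mn in names(x$metrics)) {
    flag <- if (!is.null(x$flags[[mn]])) {
      if (x$flags[[mn]]) "pass" else "FAIL"
    } else ""
    cat(sprintf("  %-11s %8.3f  %s\n", mn, x$metrics[[mn]], flag))
  }
  if (!is.null(x$loo)) {
    cat("  leave-one-out diagnosis:", x$diagnosis,
        if (!is.na(x$loo$implicated_sample))
          paste0("(", x$loo$implicated_sample, ")") else "", "\n")
  }
  cat("  final flag:", x$final_flag, "\n")
  invisible(x)
}

#' Serialize a QC report to JSON
#'
#' @param report a \code{\link{qc_report}}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_qc_json <- function(report, path) {
  x <- list(metrics = report$metrics, flags = report$flags,
            final_flag = report$final_flag,
            diagnosis = report$diagnosis,
            cutoffs = report$cutoffs)
  if (!is.null(report$loo)) x$leave_one_out <- report$loo$table
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
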