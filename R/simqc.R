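#' Simulation configuration for a multi-batch reference study
#'
#' Defines the generative model the toolkit is validated against: four
#' related sample groups profiled in triplicate in every batch, gene-wise
#' additive batch shifts in log2 space (the regime in which ratio-based
#' correction is exact), planted differential genes between groups, and
#' Poisson (optionally negative-binomial) read counts on top of the
#' continuous abundance layer.
#'
#' Per gene and sample, log2 abundance = baseline + group effect (planted
#' differential genes only) + batch shift + replicate noise; the values
#' layer is 2^(log2 abundance) and counts are drawn with mean value *
#' depth_factor.
#'
#' @param n_genes number of genes (default 1000, a desk-scale stand-in for
#'   a transcriptome).
#' @param groups group labels; the first entry after \code{ref_group}
#'   ordering conventions does not matter, effects are planted relative to
#'   \code{ref_group}.
#' @param replicates replicates per group per batch (default 3).
#' @param n_batches number of batches (default 13, mirroring a
#'   high-quality multi-batch corpus).
#' @param ref_group group receiving zero planted effect and serving as the
#'   conventional ratio denominator (default "D6").
#' @param de_fraction probability that a gene carries a planted effect in
#'   a given non-reference group (default 0.1).
#' @param logfc_range planted |log2FC| is uniform on this interval
#'   (default (1, 3)) with random sign.
#' @param noise_sd replicate noise s.d. on the log2 scale (default 0.2).
#' @param batch_sd s.d. of the gene-wise additive batch shift (default 1).
#' @param baseline_mean,baseline_sd log2 baseline abundance distribution
#'   (default Normal(3, 2)).
#' @param depth_factor multiplier from abundance to expected read count
#'   (default 10).
#' @param count_model \code{"poisson"} (default) or \code{"nb"}.
#' @param nb_size negative-binomial size (dispersion) when
#'   \code{count_model = "nb"}.
#' @param batch_scale_sd optional multiplicative-on-log contamination: per
#'   batch, log2 values are additionally scaled by Normal(1,
#'   batch_scale_sd) per gene (default 0 = off; breaks the additive model
#'   on purpose, for robustness checks).
#' @param seed mandatory integer seed.
#' @return a validated \code{sim_config} list.
#' @export
sim_config <- function(n_genes = 1000,
                       groups = c("D5", "D6", "F7", "M8"),
                       replicates = 3, n_batches = 13,
                       ref_group = "D6",
                       de_fraction = 0.1, logfc_range = c(1, 3),
                       noise_sd = 0.2, batch_sd = 1.0,
                       baseline_mean = 3, baseline_sd = 2,
                       depth_factor = 10,
                       count_model = c("poisson", "nb"), nb_size = 10,
                       batch_scale_sd = 0, seed) {
  count_model <- match.arg(count_model)
  if (missing(seed)) stop("seed is mandatory")
  problems <- character(0)
  if (n_genes < 2) problems <- c(problems, "n_genes must be >= 2")
  if (length(groups) < 2) problems <- c(problems, "need >= 2 groups")
  if (!ref_group %in% groups) {
    problems <- c(problems, "ref_group must be one of groups")
  }
  if (replicates < 1) problems <- c(problems, "replicates must be >= 1")
  if (n_batches < 1) problems <- c(problems, "n_batches must be >= 1")
  if (de_fraction < 0 || de_fraction > 1) {
    problems <- c(problems, "de_fraction must be in [0, 1]")
  }
  if (any(logfc_range < 0) || logfc_range[2] < logfc_range[1]) {
    problems <- c(problems, "logfc_range must be an increasing pair >= 0")
  }
  for (nm in c("noise_sd", "batch_sd", "baseline_sd", "batch_scale_sd")) {
    if (get(nm) < 0) problems <- c(problems, paste(nm, "must be >= 0"))
  }
  if (depth_factor <= 0) {
    problems <- c(problems, "depth_factor must be positive")
  }
  if (length(problems) > 0L) {
    stop("invalid simulation config: ", paste(problems, collapse = "; "))
  }
  structure(list(n_genes = n_genes, groups = groups,
                 replicates = replicates, n_batches = n_batches,
                 ref_group = ref_group, de_fraction = de_fraction,
                 logfc_range = logfc_range, noise_sd = noise_sd,
                 batch_sd = batch_sd, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, depth_factor = depth_factor,
                 count_model = count_model, nb_size = nb_size,
                 batch_scale_sd = batch_scale_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a multi-batch reference study
#'
#' Draws a full synthetic study under a \code{\link{sim_config}}:
#' the combined \code{expression_study} (values + counts, design with
#' batch labels), and truth tables (per-group planted effects, per-pair
#' true log2 fold changes and DEG labels, per-batch shifts, an outlier
#' registry).  Regenerating with the same config is bit-identical.
#'
#' @param config a \code{sim_config}.
#' @return class \code{synthetic_study}: \code{study}, \code{truth}
#'   (\code{effects}, \code{pair_fc}, \code{batch_shifts},
#'   \code{outliers}), \code{config}.
#' @export
simulate_study <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("config must be built with sim_config()")
  }
  cf <- config
  set.seed(cf$seed)
  genes <- sprintf("G%05d", seq_len(cf$n_genes))
  baseline <- stats::rnorm(cf$n_genes, cf$baseline_mean, cf$baseline_sd)

  effects <- matrix(0, nrow = cf$n_genes, ncol = length(cf$groups),
                    dimnames = list(genes, cf$groups))
  for (g in setdiff(cf$groups, cf$ref_group)) {
    is_de <- stats::runif(cf$n_genes) < cf$de_fraction
    mag <- stats::runif(cf$n_genes, cf$logfc_range[1], cf$logfc_range[2])
    sgn <- sample(c(-1, 1), cf$n_genes, replace = TRUE)
    effects[, g] <- ifelse(is_de, sgn * mag, 0)
  }
  batches <- sprintf("B%02d", seq_len(cf$n_batches))
  shifts <- matrix(stats::rnorm(cf$n_genes * cf$n_batches, 0, cf$batch_sd),
                   nrow = cf$n_genes,
                   dimnames = list(genes, batches))
  scale_fac <- if (cf$batch_scale_sd > 0) {
    matrix(stats::rnorm(cf$n_genes * cf$n_batches, 1, cf$batch_scale_sd),
           nrow = cf$n_genes, dimnames = list(genes, batches))
  } else NULL

  design <- expand.grid(replicate = seq_len(cf$replicates),
                        group = cf$groups, batch = batches,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design$sample <- paste(design$group, design$replicate, design$batch,
                         sep = "_")
  design <- study_design(design[, c("sample", "group", "replicate",
                                    "batch")])
  n_samp <- nrow(design)
  log2m <- matrix(NA_real_, nrow = cf$n_genes, ncol = n_samp,
                  dimnames = list(genes, design$sample))
  for (i in seq_len(n_samp)) {
    mu <- baseline + effects[, design$group[i]] +
      shifts[, design$batch[i]]
    if (!is.null(scale_fac)) mu <- mu * scale_fac[, design$batch[i]]
    log2m[, i] <- mu + stats::rnorm(cf$n_genes, 0, cf$noise_sd)
  }
  values <- 2^log2m
  lambda <- values * cf$depth_factor
  counts <- matrix(
    if (cf$count_model == "poisson") {
      stats::rpois(length(lambda), lambda)
    } else {
      stats::rnbinom(length(lambda), mu = lambda, size = cf$nb_size)
    },
    nrow = cf$n_genes, dimnames = dimnames(values))

  study <- expression_study(values, design, counts = counts)

  pairs <- utils::combn(cf$groups, 2L, simplify = FALSE)
  pair_fc <- do.call(rbind, lapply(pairs, function(pr) {
    fc <- effects[, pr[1L]] - effects[, pr[2L]]
    data.frame(gene = genes, pair = paste(pr, collapse = "/"),
               true_log2fc = fc,
               label = ifelse(fc >= cf$logfc_range[1], "up",
                       ifelse(fc <= -cf$logfc_range[1], "down", "non-DE")),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  outliers <- data.frame(sample = character(0), severity = numeric(0),
                         stringsAsFactors = FALSE)
  structure(list(study = study,
                 truth = list(effects = effects, pair_fc = pair_fc,
                              batch_shifts = shifts, outliers = outliers),
                 config = cf),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cf <- x$config
  cat("Synthetic study:", cf$n_genes, "genes,", length(cf$groups),
      "groups x", cf$replicates, "replicates x", cf$n_batches,
      "batches (seed", cf$seed, ")\n")
  if (nrow(x$truth$outliers) > 0L) {
    cat("  injected outliers:",
        paste(x$truth$outliers$sample, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Split a multi-batch study into single-batch studies
#'
#' @param study an \code{expression_study} (or \code{synthetic_study}).
#' @return named list of single-batch \code{expression_study} objects.
#' @export
split_batches <- function(study) {
  if (inherits(study, "synthetic_study")) study <- study$study
  d <- study$design
  out <- lapply(unique(d$batch), function(b) {
    keep <- d$sample[d$batch == b]
    d_sub <- d[d$batch == b, , drop = FALSE]
    class(d_sub) <- class(d)
    expression_study(study$values[, keep, drop = FALSE], d_sub,
                     counts = if (!is.null(study$counts)) {
                       study$counts[, keep, drop = FALSE]
                     } else NULL)
  })
  stats::setNames(out, unique(d$batch))
}

#' Inject a single-replicate outlier into a synthetic study
#'
#' Adds an independent gene-wise perturbation Normal(0, severity *
#' replicate noise s.d.) on the log2 scale to one sample's values and
#' registers it in the outlier registry.  Severity 0 leaves the study
#' bit-identical apart from the registry entry.  Counts are left untouched
#' (the perturbation models a post-quantification artifact).
#'
#' @param sstudy a \code{synthetic_study}.
#' @param sample sample identifier to perturb.
#' @param severity multiplier of the replicate noise s.d.
#' @param offset pseudo-value used to move to and from log2 space.
#' @return the modified \code{synthetic_study}.
#' @export
inject_outlier <- function(sstudy, sample, severity, offset = 0.01) {
  if (!inherits(sstudy, "synthetic_study")) {
    stop("sstudy must be a synthetic_study")
  }
  samples <- colnames(sstudy$study$values)
  if (!sample %in% samples) stop("unknown sample: ", sample)
  if (severity > 0) {
    cf <- sstudy$config
    set.seed(cf$seed + 7919L * match(sample, samples))
    delta <- stats::rnorm(cf$n_genes, 0, severity * cf$noise_sd)
    v <- sstudy$study$values[, sample]
    sstudy$study$values[, sample] <-
      pmax(2^(log2(v + offset) + delta) - offset, 0)
  }
  sstudy$truth$outliers <- rbind(
    sstudy$truth$outliers,
    data.frame(sample = sample, severity = severity,
               stringsAsFactors = FALSE))
  sstudy
}

#' Export simulation truth tables as TSV
#'
#' Writes the per-pair true fold-change/DEG table (columns matching the
#' consensus-reference joins) and the outlier registry, so recovery tests
#' are plain joins.
#'
#' @param sstudy a \code{synthetic_study}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
export_truth <- function(sstudy, dir) {
  if (!inherits(sstudy, "synthetic_study")) {
    stop("sstudy must be a synthetic_study")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    pair_fc = file.path(dir, "truth_pair_fc.tsv"),
    outliers = file.path(dir, "truth_outliers.tsv"))
  fc <- sstudy$truth$pair_fc
  fc$true_log2fc <- sprintf("%.17g", fc$true_log2fc)
  utils::write.table(fc, paths[["pair_fc"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sstudy$truth$outliers, paths[["outliers"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' True log2 fold changes for an ordered pair
#'
#' Oriented lookup into the planted effects: numerator-group effect minus
#' denominator-group effect, per gene.
#'
#' @param sstudy a \code{synthetic_study}.
#' @param pair ordered group pair (\code{c(num, den)} or \code{"num/den"}).
#' @return named numeric vector of true log2 fold changes.
#' @export
true_pair_fc <- function(sstudy, pair) {
  pair <- .parse_pair(pair)
  eff <- sstudy$truth$effects
  if (!all(pair %in% colnames(eff))) {
    stop("unknown group(s): ",
         paste(setdiff(pair, colnames(eff)), collapse = ", "))
  }
  stats::setNames(eff[, pair[1L]] - eff[, pair[2L]], rownames(eff))
}
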