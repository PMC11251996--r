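# Shared fixtures and independent oracles.

# Balanced design: m groups x n replicates (x batches), samples named
# <group>_<rep>_<batch>.
make_design <- function(m = 4, n = 3, batches = "B1",
                        groups = paste0("g", seq_len(m))) {
  d <- expand.grid(replicate = seq_len(n), group = groups,
                   batch = batches, KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  d$sample <- paste(d$group, d$replicate, d$batch, sep = "_")
  study_design(d[, c("sample", "group", "replicate", "batch")])
}

# Random log-scale matrix with group separation `sep` and noise `sd`.
make_log_matrix <- function(design, n_genes = 20, sep = 2, sd = 0.3,
                            seed = 1) {
  set.seed(seed)
  groups <- unique(design$group)
  base <- rnorm(n_genes, 5, 2)
  eff <- matrix(rnorm(n_genes * length(groups), 0, sep),
                nrow = n_genes, dimnames = list(NULL, groups))
  m <- sapply(design$sample, function(s) {
    g <- design$group[design$sample == s]
    base + eff[, g] + rnorm(n_genes, 0, sd)
  })
  rownames(m) <- sprintf("G%03d", seq_len(n_genes))
  m
}

# Independent brute-force evaluation of the PCA-weighted SNR: separate
# eigendecomposition of the covariance of the scaled data, explicit
# quadruple loops over group pairs and replicates.
snr_oracle <- function(m, design, n_pcs = 2, scale = TRUE) {
  groups <- design$group[match(colnames(m), design$sample)]
  X <- t(m)
  if (scale) X <- X[, apply(X, 2, sd) > 0, drop = FALSE]
  X <- scale(X, center = TRUE, scale = scale)
  S <- crossprod(X) / (nrow(X) - 1)
  ev <- eigen(S, symmetric = TRUE)
  W_all <- ev$values / sum(ev$values)
  scores <- X %*% ev$vectors
  W <- W_all[seq_len(n_pcs)]
  glv <- unique(groups)
  num <- 0; n_num <- 0
  for (x in seq_len(length(glv) - 1)) {
    for (y in seq.int(x + 1, length(glv))) {
      ix <- which(groups == glv[x]); iy <- which(groups == glv[y])
      for (i in ix) for (j in iy) {
        num <- num + sum(W * (scores[i, seq_len(n_pcs)] -
                              scores[j, seq_len(n_pcs)])^2)
        n_num <- n_num + 1
      }
    }
  }
  den <- 0; n_den <- 0
  for (x in seq_along(glv)) {
    ix <- which(groups == glv[x])
    for (a in seq_len(length(ix) - 1)) {
      for (b in seq.int(a + 1, length(ix))) {
        den <- den + sum(W * (scores[ix[a], seq_len(n_pcs)] -
                              scores[ix[b], seq_len(n_pcs)])^2)
        n_den <- n_den + 1
      }
    }
  }
  10 * log10((num / n_num) / (den / n_den))
}

# Write a small gene x sample TSV and return its path.
write_matrix_tsv <- function(m, sep = "\t") {
  path <- tempfile(fileext = ".tsv")
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}
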