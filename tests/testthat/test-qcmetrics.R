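# Minimal reference for metric tests: n genes, one pair, given fold changes
# and labels.
mk_ref <- function(fc, labels = NULL, pair = "A/D") {
  n <- length(fc)
  if (is.null(labels)) {
    labels <- ifelse(fc >= 1, "up", ifelse(fc <= -1, "down", "non-DEG"))
  }
  reference_dataset(data.frame(
    gene = names(fc), pair = pair, log2fc_ref = unname(fc),
    n_batches = 13L, n_up = 0L, n_down = 0L,
    u_char = NA_real_, u_bb = NA_real_, u_s = NA_real_, u_c = NA_real_,
    k = NA_real_, U = NA_real_, deg_label = labels,
    stringsAsFactors = FALSE), validate = FALSE)
}

test_that("relative correlation and RMSE behave on exact and inverted input", {
  set.seed(10)
  fc <- setNames(rnorm(100, 0, 1), sprintf("G%03d", 1:100))
  ref <- mk_ref(fc)
  expect_equal(relative_correlation(fc, ref, "A/D")$rc, 1)
  expect_equal(relative_correlation(-fc, ref, "A/D")$rc, -1)
  expect_equal(rmse_vs_reference(fc, ref, "A/D")$rmse, 0)
  # uniform offset -> RMSE = |c|
  expect_equal(rmse_vs_reference(fc + 0.7, ref, "A/D")$rmse, 0.7)
  # direct arithmetic on differences (1, 2, 3)
  fc3 <- setNames(c(0, 0, 0), c("G001", "G002", "G003"))
  ref3 <- mk_ref(fc3)
  test3 <- setNames(c(1, 2, 3), names(fc3))
  expect_equal(rmse_vs_reference(test3, ref3, "A/D")$rmse,
               sqrt(14 / 3), tolerance = 1e-12)

  expect_error(relative_correlation(fc[1:2], ref, "A/D"), "fewer than 3")
  expect_error(relative_correlation(setNames(rep(1, 100), names(fc)),
                                    ref, "A/D"), "degenerate")
})

test_that("noisy test ratios attenuate RC as theory predicts", {
  set.seed(20)
  fc <- setNames(rnorm(1000, 0, 1), sprintf("G%04d", 1:1000))
  ref <- mk_ref(fc)
  test <- fc + rnorm(1000, 0, 0.5)
  got <- relative_correlation(test, ref, "A/D")$rc
  expect_equal(got, 1 / sqrt(1.25), tolerance = 0.02)
})

test_that("MCC arithmetic matches the confusion-table formula", {
  expect_equal(mcc_from_counts(3, 4, 1, 2)$mcc,
               (12 - 2) / sqrt(4 * 5 * 5 * 6), tolerance = 1e-12)
  expect_equal(mcc_from_counts(3, 4, 2, 1)$mcc,
               (12 - 2) / sqrt(5 * 4 * 6 * 5), tolerance = 1e-12)
  z <- mcc_from_counts(0, 5, 0, 0)
  expect_equal(z$mcc, 0)
  expect_true(z$degenerate)
})

test_that("MCC against reference labels handles agreement, inversion and direction", {
  genes <- sprintf("G%02d", 1:20)
  labels <- rep(c("up", "down", "non-DEG", "non-DEG"), 5)
  fc <- setNames(ifelse(labels == "up", 2, ifelse(labels == "down", -2, 0)),
                 genes)
  ref <- mk_ref(fc, labels = labels)
  mk_degs <- function(calls) {
    structure(data.frame(gene = genes, call = calls,
                         stringsAsFactors = FALSE),
              pair = c("A", "D"), class = c("deg_table", "data.frame"))
  }
  # perfect agreement
  agree <- mk_degs(ifelse(labels == "non-DEG", "non-DE", labels))
  r1 <- mcc_vs_reference(agree, ref)
  expect_equal(r1$mcc, 1)
  expect_equal(sum(r1$counts), 20)
  # full inversion: DEGs called non-DE, non-DEGs called DE
  invert <- mk_degs(ifelse(labels == "non-DEG", "up", "non-DE"))
  expect_equal(mcc_vs_reference(invert, ref)$mcc, -1)
  # direction mismatch counts as FP and FN under the default
  flip <- mk_degs(ifelse(labels == "up", "down",
                  ifelse(labels == "down", "up", "non-DE")))
  r3 <- mcc_vs_reference(flip, ref)
  expect_equal(unname(r3$counts["TP"]), 0)
  expect_equal(unname(r3$counts["FP"]), 10)
  expect_equal(unname(r3$counts["FN"]), 10)
  # direction-agnostic mode treats a flipped call as a hit
  r4 <- mcc_vs_reference(flip, ref, direction_aware = FALSE)
  expect_equal(r4$mcc, 1)
  expect_equal(sum(r4$counts), 20)
})

test_that("MCC equals a brute-force contingency construction on random calls", {
  set.seed(30)
  genes <- sprintf("G%03d", 1:60)
  for (i in 1:100) {
    labels <- sample(c("up", "down", "non-DEG"), 60, replace = TRUE,
                     prob = c(0.3, 0.3, 0.4))
    if (!any(labels %in% c("up", "down")) || !any(labels == "non-DEG")) next
    calls <- sample(c("up", "down", "non-DE"), 60, replace = TRUE)
    fc <- setNames(ifelse(labels == "up", 2,
                   ifelse(labels == "down", -2, 0)), genes)
    ref <- mk_ref(fc, labels = labels)
    degs <- structure(data.frame(gene = genes, call = calls,
                                 stringsAsFactors = FALSE),
                      pair = c("A", "D"),
                      class = c("deg_table", "data.frame"))
    got <- mcc_vs_reference(degs, ref, direction_aware = FALSE)
    # oracle: explicit 2x2 table over DE/non-DE status
    ref_de <- labels %in% c("up", "down")
    test_de <- calls %in% c("up", "down")
    tp <- sum(ref_de & test_de); tn <- sum(!ref_de & !test_de)
    fp <- sum(!ref_de & test_de); fn <- sum(ref_de & !test_de)
    den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
    oracle <- if (den == 0) 0 else (tp * tn - fp * fn) / den
    expect_equal(got$mcc, oracle, tolerance = 1e-12)
    expect_equal(sum(got$counts), 60)
  }
})

test_that("total score is the clipped geometric mean", {
  expect_equal(total_score(16, 1.0)$score, 4.0)
  expect_equal(total_score(0, 0.9)$score, 0)
  neg <- total_score(-3, 0.9)
  expect_equal(neg$score, 0)
  expect_true(neg$clipped)
})

test_that("cutoffs are mean +/- one sample standard deviation", {
  expect_equal(derive_cutoffs(c(10, 12, 14), "lower-bound"), 10)
  expect_equal(derive_cutoffs(c(0.3, 0.3, 0.3), "upper-bound"), 0.3)
  expect_error(derive_cutoffs(5), ">= 2")
})

test_that("subset-design enumeration has the right combinatorics", {
  cf <- sim_config(n_genes = 120, n_batches = 1, seed = 71)
  b <- split_batches(simulate_study(cf))[[1]]
  tab <- evaluate_subset_designs(b, groups_range = 2, reps_range = 2,
                                 mode = "snr")
  expect_equal(nrow(tab), choose(4, 2) * choose(3, 2)^2)  # 54
  # identity subset reproduces the full-design SNR
  full <- evaluate_subset_designs(b, groups_range = 4, reps_range = 3,
                                  mode = "snr")
  expect_equal(nrow(full), 1)
  expect_equal(full$value,
               snr_pca(log_transform(b), b$design)$snr_db,
               tolerance = 1e-9)
  # more groups helps when separation dominates noise
  g3 <- evaluate_subset_designs(b, groups_range = 3, reps_range = 2,
                                mode = "snr")
  expect_gt(median(g3$value), 0)

  expect_error(evaluate_subset_designs(b, groups_range = 5,
                                       reps_range = 2, mode = "snr"),
               "exceeds")
  expect_error(evaluate_subset_designs(b, groups_range = 1,
                                       reps_range = 2, mode = "snr"),
               "G >= 2")
})

test_that("ratio-denominator mode scores cheap in-batch reference designs", {
  cf <- sim_config(n_genes = 150, n_batches = 1, seed = 72)
  b <- split_batches(simulate_study(cf))[[1]]
  tab <- evaluate_subset_designs(b, groups_range = 4, reps_range = 1,
                                 mode = "ratio-denominator")
  expect_equal(nrow(tab), 3^4)  # one replicate choice per group
  expect_true(all(is.finite(tab$value)))
})

test_that("cross-validation is seed-deterministic and split-independent", {
  # heterogeneous corpus (as in real proficiency panels): 5 clean batches
  # plus 3 degraded ones, so metrics carry real between-batch signal
  cf <- sim_config(n_genes = 250, n_batches = 8, seed = 81)
  ss <- simulate_study(cf)
  d <- ss$study$design
  for (s in d$sample[d$batch %in% c("B01", "B02", "B03")]) {
    ss <- inject_outlier(ss, s, severity = 4)
  }
  bs <- split_batches(ss)
  pairs <- list("D5/D6", "F7/D6")
  cv1 <- cross_validate_reference(bs, pairs, n_rounds = 10, train_size = 5,
                                  seed = 3)
  cv2 <- cross_validate_reference(bs, pairs, n_rounds = 10, train_size = 5,
                                  seed = 3)
  expect_identical(cv1$metrics, cv2$metrics)
  # a batch's metric does not depend on reference membership
  expect_gt(min(cv1$train_validation_correlation, na.rm = TRUE), 0.9)
  expect_error(cross_validate_reference(bs, pairs, train_size = 8,
                                        seed = 1), "smaller")
})

test_that("qc_report assembles metrics, flags and diagnosis", {
  cf <- sim_config(n_genes = 300, n_batches = 6, seed = 61)
  ss <- simulate_study(cf)
  bs <- split_batches(ss)
  pairs <- list("D5/D6", "F7/D6", "M8/D6")
  ref <- build_reference_ratios(bs[2:6], pairs, p_in_batches = 3,
                                min_batches_deg = 3)
  rep1 <- qc_report(bs[[1]], ref = ref)
  expect_equal(rep1$final_flag, "pass")
  expect_true(all(unlist(rep1$flags)))
  expect_equal(rep1$diagnosis, "pass")

  # outlier-injected batch fails with a random-failure diagnosis
  ss2 <- inject_outlier(ss, "D5_1_B01", severity = 15)
  rep2 <- qc_report(split_batches(ss2)[[1]], ref = ref)
  expect_equal(rep2$diagnosis, "random-failure")

  # without a reference only the SNR section exists
  rep3 <- qc_report(bs[[1]])
  expect_false(rep3$reference_used)
  expect_null(rep3$metrics$rc)
})

test_that("systematic degradation keeps SNR high but hurts reference metrics", {
  # emulate a batch whose library chemistry removes / shifts a gene subset:
  # group structure survives (high SNR) but fold changes disagree with the
  # reference built from unperturbed batches.
  cf <- sim_config(n_genes = 300, n_batches = 6, seed = 62)
  ss <- simulate_study(cf)
  bs <- split_batches(ss)
  pairs <- list("D5/D6", "F7/D6", "M8/D6")
  ref <- build_reference_ratios(bs[2:6], pairs, p_in_batches = 3,
                                min_batches_deg = 3)
  b1 <- bs[[1]]
  set.seed(63)
  hit <- sample(rownames(b1$values), 150)
  skew <- matrix(2^rnorm(length(hit) * 4, 0, 1.5), nrow = length(hit))
  # same multiplicative skew for all replicates of a group: coherent bias
  for (gi in seq_along(unique(b1$design$group))) {
    g <- unique(b1$design$group)[gi]
    cols <- b1$design$sample[b1$design$group == g]
    b1$values[hit, cols] <- b1$values[hit, cols] * skew[, gi]
  }
  snr_clean <- qc_report(bs[[1]], ref = ref)
  snr_skew <- qc_report(b1, ref = ref)
  expect_gt(snr_skew$metrics$snr, 12)                      # SNR still high
  expect_lt(snr_skew$metrics$rc, snr_clean$metrics$rc - 0.05)
  expect_gt(snr_skew$metrics$rmse, snr_clean$metrics$rmse)
})

test_that("QC reports serialize to JSON", {
  cf <- sim_config(n_genes = 100, n_batches = 1, seed = 64)
  b <- split_batches(simulate_study(cf))[[1]]
  rep1 <- qc_report(b)
  path <- tempfile(fileext = ".json")
  write_qc_json(rep1, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$metrics$snr, rep1$metrics$snr, tolerance = 1e-9)
  expect_equal(back$final_flag, rep1$final_flag)
})
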