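test_that("reference fold change is the mean of per-batch log2 ratios", {
  # deterministic two-group studies: gene g1 has a per-batch log2 ratio of
  # exactly 1.0 in every batch; g2 is null.
  mk_batch <- function(b) {
    d <- make_design(2, 3, groups = c("A", "D"), batches = b)
    lg <- matrix(5, nrow = 2, ncol = 6, dimnames = list(c("g1", "g2"),
                                                        d$sample))
    lg["g1", d$sample[d$group == "A"]] <- 6 + c(-1e-4, 0, 1e-4)
    vals <- 2^lg - 0.01
    counts <- matrix(50L, nrow = 2, ncol = 6, dimnames = dimnames(lg))
    expression_study(vals, d, counts = counts)
  }
  batches <- lapply(paste0("B", 1:5), mk_batch)
  ref <- build_reference_ratios(batches, list("A/D"), p_in_batches = 4,
                                min_batches_deg = 3)
  expect_equal(ref$log2fc_ref[ref$gene == "g1"], 1.0, tolerance = 1e-6)
  expect_equal(ref$deg_label[ref$gene == "g1"], "up")
  # null gene fails the P-in-batches gate
  expect_false("g2" %in% ref$gene)
})

test_that("detectability gate excludes genes missing in one batch", {
  mk_batch <- function(b, g2_counts) {
    d <- make_design(2, 3, groups = c("A", "D"), batches = b)
    set.seed(match(b, paste0("B", 1:6)))
    lg <- matrix(rnorm(12, 5, 0.1), nrow = 2,
                 dimnames = list(c("g1", "g2"), d$sample))
    lg["g1", d$sample[d$group == "A"]] <-
      lg["g1", d$sample[d$group == "A"]] + 2
    lg["g2", d$sample[d$group == "A"]] <-
      lg["g2", d$sample[d$group == "A"]] + 2
    counts <- matrix(50L, nrow = 2, ncol = 6, dimnames = dimnames(lg))
    counts["g2", ] <- g2_counts
    expression_study(2^lg, d, counts = counts)
  }
  batches <- c(lapply(paste0("B", 1:5), mk_batch, g2_counts = 50L),
               list(mk_batch("B6", g2_counts = 0L)))
  ref <- build_reference_ratios(batches, list("A/D"), p_in_batches = 4,
                                min_batches_deg = 3)
  expect_true("g1" %in% ref$gene)
  expect_false("g2" %in% ref$gene)   # undetected in batch 6
})

test_that("reference values recover planted fold changes and ignore batch order", {
  cf <- sim_config(n_genes = 400, n_batches = 8, seed = 31)
  ss <- simulate_study(cf)
  bs <- split_batches(ss)
  pairs <- list("D5/D6", "F7/D6", "M8/D6")
  ref <- build_reference_ratios(bs, pairs, min_batches_deg = 4)
  expect_gt(nrow(ref), 50)
  err <- unlist(lapply(pairs, function(pr) {
    rr <- ref[ref$pair == pr, ]
    rr$log2fc_ref - true_pair_fc(ss, pr)[rr$gene]
  }))
  expect_lt(abs(mean(err)), 0.05)
  expect_lt(sqrt(mean(err^2)), 0.15)

  perm_ref <- build_reference_ratios(bs[sample(length(bs))], pairs,
                                     min_batches_deg = 4)
  perm_ref <- perm_ref[order(perm_ref$pair, perm_ref$gene), ]
  ref_o <- ref[order(ref$pair, ref$gene), ]
  expect_equal(perm_ref$log2fc_ref, ref_o$log2fc_ref, tolerance = 1e-12)
})

test_that("a 13-batch reference pins most planted fold changes within 0.1", {
  cf <- sim_config(n_genes = 300, n_batches = 13, seed = 32)
  ss <- simulate_study(cf)
  ref <- build_reference_ratios(split_batches(ss), list("D5/D6"))
  rr <- ref[ref$pair == "D5/D6", ]
  err <- rr$log2fc_ref - true_pair_fc(ss, "D5/D6")[rr$gene]
  expect_gte(mean(abs(err) < 0.1), 0.95)
})

test_that("homogeneity ANOVA has the right null behaviour and power", {
  set.seed(55)
  n_genes <- 2000
  units <- c(rep("N1", 9), paste0("N", 2:17))
  # null: unit effect 0, replicate noise only
  null_vals <- matrix(rnorm(n_genes * 25, 0, 0.2), ncol = 25,
                      dimnames = list(sprintf("G%04d", 1:n_genes), NULL))
  hom <- homogeneity_test(null_vals, units)
  expect_equal(mean(hom$p < 0.05), 0.05, tolerance = 0.02)
  expect_gte(mean(hom$pass), 0.99)

  # inhomogeneous: unit effect sd = 3x replicate sd
  unit_eff <- matrix(rnorm(n_genes * 17, 0, 0.6), ncol = 17)
  inh_vals <- null_vals
  inh_vals[, 1:9] <- inh_vals[, 1:9] + unit_eff[, 1]
  for (u in 2:17) inh_vals[, 8 + u] <- inh_vals[, 8 + u] + unit_eff[, u]
  hom2 <- homogeneity_test(inh_vals, units)
  expect_gte(mean(!hom2$pass), 0.80)

  # degenerate gene: all measurements identical
  cv <- null_vals; cv[1, ] <- 1
  hom3 <- homogeneity_test(cv, units)
  expect_true(hom3$degenerate[1])
  expect_true(is.na(hom3$p_adj[1]))

  expect_error(homogeneity_test(null_vals, rep("N1", 25)),
               "single-measurement")
})

test_that("stability regression flags drift and passes stable genes", {
  tp <- c(0, 2, 5, 8, 12, 16, 20, 22, 24, 26)
  # constant series passes
  m <- matrix(1, nrow = 2, ncol = 10,
              dimnames = list(c("g1", "g2"), NULL))
  m[2, ] <- 0.5 * tp   # exact drift: se(b1) = 0 but |b1| > 0
  st <- stability_test(m, tp)
  expect_true(st$pass[1])
  expect_equal(st$b1[1], 0)
  expect_false(st$pass[2])
  expect_equal(st$b1[2], 0.5)

  # null slope, noise: pass rate ~ confidence level
  set.seed(66)
  tp15 <- seq(0, 28, length.out = 15)
  null_m <- matrix(rnorm(2000 * 15, 2, 0.3), ncol = 15,
                   dimnames = list(sprintf("G%04d", 1:2000), NULL))
  st2 <- stability_test(null_m, tp15)
  expect_equal(mean(st2$pass), 0.95, tolerance = 0.02)

  expect_error(stability_test(m[, 1:2], tp[1:2]), "3 distinct")
})

test_that("uncertainty components follow the variance-branch formulas", {
  # zero spread -> zero characterization uncertainty
  char <- matrix(2, nrow = 1, ncol = 13, dimnames = list("g1", NULL))
  ub <- uncertainty_bundle(char)
  expect_equal(ub$u_char, 0)
  expect_equal(ub$U, 2 * ub$u_c)

  # between-unit formulas, both branches
  b1 <- u_bb_from_variances(4, 1, df_s2 = 8, n = 16)
  expect_equal(b1$u_bb, sqrt(3 / 16), tolerance = 1e-12)
  expect_equal(b1$branch, "excess")
  b2 <- u_bb_from_variances(1, 4, df_s2 = 8, n = 16)
  expect_equal(b2$u_bb, sqrt(4 / 16) * (2 / 8)^(1 / 4), tolerance = 1e-12)
  expect_equal(b2$branch, "floor")
  # tie resolves to the floor branch
  expect_equal(u_bb_from_variances(2, 2, 8, 16)$branch, "floor")

  # quadrature identity on random bundles
  set.seed(77)
  char2 <- matrix(rnorm(50 * 13, 2, 0.3), nrow = 50,
                  dimnames = list(sprintf("G%02d", 1:50), NULL))
  units <- c(rep("N1", 9), paste0("N", 2:17))
  hv <- matrix(rnorm(50 * 25, 0, 0.2), nrow = 50,
               dimnames = list(rownames(char2), NULL))
  hom <- homogeneity_test(hv, units)
  sv <- matrix(rnorm(50 * 10, 1, 0.2), nrow = 50,
               dimnames = list(rownames(char2), NULL))
  st <- stability_test(sv, c(0, 2, 5, 8, 12, 16, 20, 22, 24, 26))
  ub2 <- uncertainty_bundle(char2, hom = hom, stab = st)
  expect_lt(max(abs(ub2$u_c^2 -
                      (ub2$u_char^2 + ub2$u_bb^2 + ub2$u_s^2))), 1e-12)
  expect_equal(ub2$U, 2 * ub2$u_c)

  # near-zero mean flagged unquantifiable
  char3 <- matrix(c(1e-9, -1e-9, 1e-9), nrow = 1,
                  dimnames = list("g0", NULL))
  expect_false(uncertainty_bundle(char3)$quantifiable)
  expect_error(uncertainty_bundle(char[, 1, drop = FALSE]), ">= 2")
})

test_that("most well-behaved genes get expanded uncertainty below 30%", {
  cf <- sim_config(n_genes = 600, n_batches = 13, seed = 91)
  ss <- simulate_study(cf)
  bs <- split_batches(ss)
  pairs <- list("D5/D6", "F7/D6", "M8/D6")
  ref <- build_reference_ratios(bs, pairs)
  set.seed(92)
  genes <- rownames(ss$study$values)
  units <- c(rep("N1", 9), paste0("N", 2:17))
  hv <- matrix(rnorm(length(genes) * 25, 0, cf$noise_sd), ncol = 25,
               dimnames = list(genes, NULL))
  hom <- homogeneity_test(hv, units)
  tp <- c(0, 2, 5, 8, 12, 16, 20, 22, 24, 26)
  sv <- matrix(rnorm(length(genes) * 10, 1, cf$noise_sd), ncol = 10,
               dimnames = list(genes, NULL))
  st <- stability_test(sv, tp)
  ref2 <- add_uncertainty(ref, hom = hom, stab = st)
  frac <- mean(ref2$U < 0.30, na.rm = TRUE)
  expect_gte(frac, 0.80)
})
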