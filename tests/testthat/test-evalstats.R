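test_that("AUROC matches hand-enumerable cases", {
  expect_equal(auroc(c(1, 1), c(1, 1)), 0.5)          # all ties
  expect_equal(auroc(c(5, 6), c(1, 2)), 1)
  expect_equal(auroc(c(0.9, 0.4), c(0.5, 0.3)), 0.75)
  expect_error(auroc(numeric(), c(1)), "empty")
})

test_that("AUROC equals the pair-counting oracle with ties and NAs", {
  set.seed(101)
  for (i in 1:50) {
    np <- sample(1:12, 1); nn <- sample(1:12, 1)
    pos <- sample(seq(0, 1, 0.1), np, replace = TRUE)
    neg <- sample(seq(0, 1, 0.1), nn, replace = TRUE)
    expect_equal(auroc(pos, neg), pair_count_auroc(pos, neg))
  }
})

test_that("AUROC and DeLong variance agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(808)
  pos <- rnorm(40, 0.8); neg <- rnorm(30)
  r <- pROC::roc(response = rep(c(1, 0), c(40, 30)),
                 predictor = c(pos, neg), quiet = TRUE,
                 direction = "<")
  expect_equal(auroc(pos, neg), as.numeric(pROC::auc(r)))
  expect_equal(delong_auc_test(pos, neg)$variance,
               as.numeric(pROC::var(r, method = "delong")))
})

test_that("DeLong one-sample test is exact on structural components", {
  # symmetric scores with AUROC exactly 0.5
  res <- delong_auc_test(c(1, 4), c(2, 3))
  expect_equal(res$auc, 0.5)
  expect_equal(res$z, 0)
  expect_equal(res$p, 1)

  # 3 vs 3: compare against the defining double loop
  pos <- c(0.9, 0.5, 0.3); neg <- c(0.6, 0.4, 0.1)
  got <- delong_auc_test(pos, neg)
  oracle <- brute_force_delong(pos, neg)
  expect_equal(got$auc, oracle$auc)
  expect_equal(got$variance, oracle$variance)

  # paired mode with identical tools degenerates to p = 1
  paired <- delong_auc_test(pos, neg, pos_scores2 = pos, neg_scores2 = neg)
  expect_equal(paired$delta, 0)
  expect_equal(paired$p, 1)

  # perfect separation flags degeneracy with p = 0
  expect_warning(deg <- delong_auc_test(c(3, 4), c(1, 2)), "separation")
  expect_equal(deg$p, 0)
  expect_true(deg$degenerate)
})

test_that("signed-rank and paired-t behave on canonical inputs", {
  expect_equal(wilcoxon_signed_rank(rep(1, 10)), 2 / 1024)
  expect_error(wilcoxon_signed_rank(rep(0, 4)), "zero")
  d <- c(-2, -1, 1, 2)                      # symmetric about 0
  expect_equal(paired_t_one_sided(d), 0.5)
  expect_error(paired_t_one_sided(1), ">= 2")
})

test_that("success rate half-credits ties so allele-invariant tools score
           exactly 50%", {
  apairs <- structure(
    data.frame(chrom = "chr1", pos = c(100L, 200L, 300L), ref = "A",
               pathogenic_alt = c("G", "G", "G"),
               nonpathogenic_alt = c("C", "C", "C"),
               stringsAsFactors = FALSE),
    class = c("allele_pair_set", "data.frame"))
  v <- data.frame(chrom = "chr1", pos = rep(c(100L, 200L, 300L), 2),
                  alt = rep(c("G", "C"), each = 3))
  flat <- simulate_scores(v, rep(FALSE, 6),
                          score_model_params(sigma_positional = 1,
                                             sigma_allelic = 0,
                                             allele_specific = FALSE),
                          seed = 2)
  res <- success_rate(apairs, flat, "sim")
  expect_identical(res$value[1], 0.5)
  expect_equal(res$n_used[1], 3)

  # strictly higher pathogenic scores give rate 1, missing scores counted
  sc <- score_table(data.frame(chrom = "chr1",
                               pos = c(100L, 100L, 200L, 200L),
                               alt = c("G", "C", "G", "C"), tool = "t",
                               score = c(2, 1, 5, 4)), c(t = TRUE))
  res2 <- success_rate(apairs, sc, "t")
  expect_equal(res2$value[1], 1)
  expect_equal(res2$n_missing[1], 1)
})

test_that("success rate stratification reports per-stratum rates and warns
           on empty strata", {
  apairs <- structure(
    data.frame(chrom = "chr1", pos = c(1L, 2L), ref = "A",
               pathogenic_alt = "G", nonpathogenic_alt = "C",
               stringsAsFactors = FALSE),
    class = c("allele_pair_set", "data.frame"))
  sc <- score_table(data.frame(chrom = "chr1", pos = c(1L, 1L, 2L, 2L),
                               alt = c("G", "C", "G", "C"), tool = "t",
                               score = c(2, 1, 0, 1)), c(t = TRUE))
  res <- success_rate(apairs, sc, "t", strata = c("ultra", "least"))
  expect_equal(res$value[res$stratum == "ultra"], 1)
  expect_equal(res$value[res$stratum == "least"], 0)

  sc2 <- score_table(data.frame(chrom = "chr1", pos = c(1L, 1L),
                                alt = c("G", "C"), tool = "t",
                                score = c(2, 1)), c(t = TRUE))
  expect_warning(success_rate(apairs, sc2, "t",
                              strata = c("ultra", "least")),
                 "least")
})

test_that("score correlation by distance recovers the GP variance ratio", {
  set.seed(55)
  L <- 500
  n <- 3000
  pos <- sort(sample.int(3000000L, n))
  v <- data.frame(chrom = "chr1", pos = pos, alt = "C")
  sig_r <- 1; sig_n <- 0.5
  st <- simulate_scores(v, rep(FALSE, n),
                        score_model_params(delta_allelic = 0,
                                           sigma_allelic = sig_n,
                                           sigma_regional = sig_r,
                                           corr_length_bp = L),
                        seed = 56)
  res <- score_correlation_by_distance(v, st, "sim",
                                       bin_edges = c(50, 5000))
  ratio <- sig_r^2 / (sig_r^2 + sig_n^2)      # r at d ~ 0
  expect_lt(abs(res$r[1] - ratio * exp(-25 / L)), 0.1)

  # independent scores decorrelate
  st2 <- simulate_scores(v, rep(FALSE, n),
                         score_model_params(delta_allelic = 0,
                                            sigma_allelic = 1),
                         seed = 57)
  res2 <- score_correlation_by_distance(v, st2, "sim",
                                        bin_edges = c(5000))
  expect_lt(abs(res2$r[1]), 0.1)

  # a bin with fewer than 3 pairs is reported NA
  v3 <- data.frame(chrom = "chr1", pos = c(10L, 20L), alt = "C")
  st3 <- score_table(data.frame(chrom = "chr1", pos = c(10L, 20L),
                                alt = "C", tool = "t", score = c(1, 2)),
                     c(t = TRUE))
  res3 <- score_correlation_by_distance(v3, st3, "t", bin_edges = 100)
  expect_true(is.na(res3$r[1]))
})

test_that("anchor-to-neighbour correlations separate smooth and noisy
           features", {
  set.seed(66)
  n <- 400
  pos <- sort(sample.int(200000L, n))
  v <- data.frame(chrom = "chr1", pos = pos, alt = "C")
  smooth <- simulate_scores(v, rep(FALSE, n),
                            score_model_params(delta_allelic = 0,
                                               sigma_allelic = 0,
                                               sigma_regional = 1,
                                               corr_length_bp = 20000),
                            seed = 67)$score
  tab <- data.frame(chrom = "chr1", pos = pos,
                    smooth = smooth, noise = rnorm(n), flat = 1)
  anchors <- seq_len(n) %in% sample.int(n, 40)
  res <- predictor_distance_correlation(tab, anchors,
                                        bin_edges = c(100, 1000, 50000))
  expect_false("flat" %in% rownames(res))
  expect_gt(res["smooth", 2], 0.6)
  expect_gt(res["smooth", 2], res["smooth", 3])
  expect_lt(abs(res["noise", 3]), 0.2)
})

test_that("average precision matches hand enumeration and the threshold
           oracle", {
  expect_equal(auprc(c(1, 1, 0, 0), c(4, 3, 2, 1)), 1)
  expect_equal(auprc(c(1, 0, 1, 0), c(4, 3, 2, 1)),
               0.5 * 1 + 0.5 * (2 / 3))
  expect_error(auprc(c(0, 0), c(1, 2)), "no positives")

  set.seed(202)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    labels <- c(TRUE, sample(c(TRUE, FALSE), n - 1, replace = TRUE))
    scores <- sample(1:5, n, replace = TRUE)     # forced ties
    expect_equal(auprc(labels, scores),
                 threshold_set_auprc(labels, scores))
  }
})

test_that("random balanced scores give AUPRC near one half", {
  set.seed(303)
  ap <- replicate(60, auprc(rep(c(TRUE, FALSE), each = 100), rnorm(200)))
  expect_lt(abs(mean(ap) - 0.5), 0.03)
})

test_that("top-percentile precision is 1 for a perfect scorer up to 9:1", {
  for (rho in c(1, 5, 9)) {
    n_p <- 30; n_n <- rho * n_p
    labels <- rep(c(TRUE, FALSE), c(n_p, n_n))
    scores <- c(rnorm(n_p, 10), rnorm(n_n, 0))
    expect_equal(top_percentile_precision(labels, scores, 10), 1)
  }
})

test_that("mixing sweep AUPRC tracks prevalence for random scores and
           declines with the ratio for a mid-strength scorer", {
  set.seed(404)
  mk_mix <- function(rho, n_p = 60) {
    n_n <- rho * n_p
    structure(data.frame(chrom = "chr1",
                         pos = seq_len(n_p + n_n) * 2000L, alt = "C",
                         pathogenic = rep(c(TRUE, FALSE), c(n_p, n_n))),
              mixing_ratio = rho,
              class = c("mixture_set", "data.frame"))
  }
  # random scorer at 4:1: AUPRC ~ 1/(1+4), averaged over seeds
  rho <- 4
  aps <- replicate(40, {
    m <- mk_mix(rho)
    sc <- score_table(data.frame(chrom = m$chrom, pos = m$pos, alt = m$alt,
                                 tool = "r", score = rnorm(nrow(m))),
                      c(r = TRUE))
    mixing_sweep(list(m), sc, "r")$auprc
  })
  expect_lt(abs(mean(aps) - 1 / (1 + rho)), 0.04)

  # mid-strength scorer: AUPRC at 1:1 beats 100:1 by > 3 SE
  ap_at <- function(rho, seed) {
    m <- mk_mix(rho)
    set.seed(seed)
    sc <- score_table(data.frame(chrom = m$chrom, pos = m$pos, alt = m$alt,
                                 tool = "m",
                                 score = m$pathogenic * 1.5 + rnorm(nrow(m))),
                      c(m = TRUE))
    mixing_sweep(list(m), sc, "m")$auprc
  }
  a1 <- vapply(1:12, function(s) ap_at(1, s), 0)
  a100 <- vapply(1:12, function(s) ap_at(100, 100 + s), 0)
  se <- sqrt(var(a1) / 12 + var(a100) / 12)
  expect_gt(mean(a1) - mean(a100), 3 * se)
})

test_that("max ratio at target interpolates between tested ratios", {
  sweep <- data.frame(ratio = c(1, 10, 100),
                      auprc = c(0.95, 0.85, 0.45))
  # crosses 0.8 between 10 and 100: 10 + 0.05/0.40 * 90
  expect_equal(max_ratio_at_target(sweep, 0.8), 10 + 0.05 / 0.40 * 90)
  expect_equal(max_ratio_at_target(data.frame(ratio = c(1, 10),
                                              auprc = c(0.6, 0.4)), 0.8), 0)
  expect_equal(max_ratio_at_target(data.frame(ratio = c(1, 10),
                                              auprc = c(0.95, 0.9)), 0.8),
               10)
})

test_that("balanced-accuracy cutoff maximises TPR + TNR", {
  res <- balanced_accuracy_cutoff(c(3, 2), c(1, 0))
  expect_equal(res$cutoff, 1.5)
  expect_equal(res$tpr, 1)
  expect_equal(res$tnr, 1)

  # identical distributions: no discrimination, TPR + TNR ~ 1
  set.seed(505)
  x <- rnorm(4000)
  res2 <- balanced_accuracy_cutoff(x, rnorm(4000))
  expect_lt(res2$tpr + res2$tnr, 1.1)
})

test_that("odds ratios and ANOVA reduce to textbook values", {
  expect_equal(fisher_exact_or(matrix(c(10, 10, 10, 10), 2))$odds_ratio, 1)
  expect_equal(fisher_exact_or(matrix(c(10, 10, 10, 10), 2))$p, 1)

  tab <- matrix(c(8, 2, 2, 8), 2)
  got <- fisher_exact_or(tab)
  expect_equal(got$odds_ratio, 16)
  # hypergeometric enumeration of the two-sided exact p
  probs <- dhyper(0:10, 10, 10, 10)
  obs <- dhyper(8, 10, 10, 10)
  expect_equal(got$p, sum(probs[probs <= obs + 1e-12]))

  g <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  res <- one_way_anova(g)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  expect_error(one_way_anova(list(1:3)), ">= 2 groups")
})
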