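# association statistics: contingency tables, chi-square, Fisher,
# Bonferroni, rank tests, expression tiers, repeat fractions.

test_that("feature-by-cluster tables count correctly", {
  ids <- sprintf("p%02d", 1:20)
  labels <- rep(c("upstream", "centered", "downstream"), c(6, 8, 6))
  res <- structure(list(k = 3L, labels = c("upstream", "centered",
                                           "downstream"),
                        assignment = setNames(rep(1:3, c(6, 8, 6)), ids),
                        labelled_assignment = setNames(labels, ids),
                        medoid_ids = ids[1:3], objective = 0),
                   class = "cluster_result")
  ann <- data.frame(id = ids,
                    architecture = rep(c("SP", "BR"), 10),
                    cpg = rep(c(TRUE, FALSE), each = 10),
                    gene = TRUE, lincrna = FALSE,
                    repeat_flag = c(rep(TRUE, 5), rep(FALSE, 15)),
                    repeat_class = c(rep("SINE", 3), rep("LINE", 2),
                                     rep(NA, 15)),
                    tata = FALSE, tata_score = 0.1,
                    stringsAsFactors = FALSE)
  tab <- feature_by_cluster_table(res, ann, "architecture")
  # brute-force recount
  for (cl in rownames(tab)) for (a in colnames(tab))
    expect_equal(tab[cl, a], sum(labels == cl & ann$architecture == a))
  expect_equal(sum(tab), 20)
  tabr <- feature_by_cluster_table(res, ann, "repeat_class")
  expect_equal(sum(tabr), 5)   # only flagged promoters counted
  # all-SP -> BR column all zero
  ann2 <- ann
  ann2$architecture <- "SP"
  expect_equal(unname(feature_by_cluster_table(res, ann2,
                                               "architecture")[, "BR"]),
               rep(0L, 3))
  expect_error(feature_by_cluster_table(res, ann, "bogus"), "unknown")
})

test_that("chi-square statistic matches hand formula and oracle", {
  # perfectly proportional table -> statistic 0, p = 1
  prop <- outer(c(10, 20, 30), c(2, 3)) / 5
  r <- chi_square_test(prop)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  # hand-computed 2x2
  r2 <- chi_square_test(matrix(c(10, 0, 0, 10), 2))
  expect_equal(r2$statistic, 20)
  expect_identical(r2$df, 1L)
  # printed 3x3 concordance table vs an independent implementation
  tab <- matrix(c(513, 417, 552, 387, 711, 635, 246, 366, 654), 3,
                byrow = TRUE)
  mine <- chi_square_test(tab)
  ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p, unname(ref$p.value), tolerance = 1e-12)
  expect_identical(mine$df, 4L)
  # permutation invariance
  perm <- chi_square_test(tab[c(2, 3, 1), c(3, 1, 2)])
  expect_equal(perm$statistic, mine$statistic)
  expect_error(chi_square_test(matrix(c(0, 0, 1, 2), 2)), "marginal")
})

test_that("Fisher's exact p equals hypergeometric enumeration", {
  ext <- fisher_exact(matrix(c(0, 5, 5, 0), 2))
  expect_equal(ext$p, oracle_fisher_p(matrix(c(0, 5, 5, 0), 2)))
  same <- fisher_exact(matrix(c(4, 4, 6, 6), 2, byrow = TRUE))
  expect_equal(same$p, 1)
  set.seed(71)
  for (i in 1:30) {
    tab <- matrix(sample(0:12, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab)$p, oracle_fisher_p(tab),
                 tolerance = 1e-12)
    ref <- stats::fisher.test(tab)
    expect_equal(fisher_exact(tab)$p, ref$p.value, tolerance = 1e-9)
  }
  expect_error(fisher_exact(matrix(1, 3, 2)), "2x2")
})

test_that("bonferroni caps at 1", {
  expect_equal(bonferroni(0.01, 3), 0.03)
  expect_equal(bonferroni(0.5, 4), 1)
  expect_equal(bonferroni(0.2, 1), 0.2)
  expect_error(bonferroni(0.1, 0), "m")
})

test_that("rank tests match enumeration and an independent implementation", {
  # identical groups -> KW statistic 0
  same <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$statistic, 0)
  # 30-value fixture vs stats::kruskal.test (tie-corrected)
  set.seed(72)
  g <- list(rnorm(10), rnorm(10, 1), round(rnorm(10, 2), 1))
  mine <- kruskal_wallis(g)
  ref <- stats::kruskal.test(g)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p, unname(ref$p.value), tolerance = 1e-12)
  expect_error(kruskal_wallis(list(1:3)), "groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "groups")

  # rank-sum two-sided on {1,2,3} vs {4,5,6}: both one-sided tails are
  # 1/20 and 20/20 -> two-sided = 2/20
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$p, 2 / 20)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6),
                                 alternative = "less")$p, 1 / 20)
  # agreement with stats::wilcox.test where both are exact
  set.seed(73)
  for (i in 1:10) {
    a <- rnorm(6); b <- rnorm(7)
    expect_equal(wilcoxon_rank_sum(a, b)$p,
                 stats::wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # tie-corrected approximation path agrees with wilcox.test(correct=TRUE)
  a <- rep(1:5, 8); b <- rep(2:6, 8)
  expect_equal(wilcoxon_rank_sum(a, b)$p,
               stats::wilcox.test(a, b, exact = FALSE,
                                  correct = TRUE)$p.value,
               tolerance = 1e-9)
})

test_that("expression tiers have exact sizes, ties broken by id", {
  pr <- generate_promoters(synth_config(n_promoters = 100, seed = 74,
                                        proximal_pair_rate = 0))$promoters
  tiers <- expression_tiers(pr)
  expect_equal(sum(tiers$tier == "low"), 10)
  expect_equal(sum(tiers$tier == "high"), 10)
  expect_equal(sum(tiers$tier == "medium"), 80)
  # low tpm max <= medium tpm min <= high tpm min
  expect_lte(tiers$cuts[2, "low"], min(pr$tpm_0h[tiers$tier == "medium"]))
  # massive ties: sizes still exact and resolved by id order
  pr2 <- mk_promoters(seq(10000L, by = 10000L, length.out = 20),
                      tpm = rep(5, 20))
  t2 <- expression_tiers(pr2)
  expect_equal(sum(t2$tier == "low"), 2)
  expect_equal(sum(t2$tier == "high"), 2)
  expect_identical(names(which(t2$tier == "low")), c("q001", "q002"))
  expect_identical(names(which(t2$tier == "high")), c("q019", "q020"))
  expect_error(expression_tiers(mk_promoters(10000L)), "too small")
})

test_that("repeat fractions per tier match a hand count", {
  ids <- sprintf("p%02d", 1:20)
  pr <- promoter_table(ids, "chr1", "+",
                       seq(10000L, by = 10000L, length.out = 20),
                       lapply(seq_len(20), function(i)
                         data.frame(pos = 10000L * i, tags = 10L)),
                       list(tpm_0h = 1:20))
  ann <- data.frame(id = ids, repeat_flag = rep(c(TRUE, FALSE), 10))
  tiers <- expression_tiers(pr)
  frac <- repeat_fraction_by_tier(tiers, ann)
  for (t in c("low", "medium", "high")) {
    sel <- names(tiers$tier)[tiers$tier == t]
    expect_equal(unname(frac[t]),
                 mean(ann$repeat_flag[match(sel, ann$id)]))
  }
  ann_all <- transform(ann, repeat_flag = TRUE)
  expect_equal(unname(repeat_fraction_by_tier(tiers, ann_all)),
               c(1, 1, 1))
  ann_none <- transform(ann, repeat_flag = FALSE)
  expect_equal(unname(repeat_fraction_by_tier(tiers, ann_none)),
               c(0, 0, 0))
})

test_that("tier-conditional metagene amplitude orders high above low (noiseless)", {
  cfg <- small_synth(n = 60, seed = 75, noise_sd = 0, gap_rate = 0,
                     proximal_pair_rate = 0)
  ds <- generate_synthetic_dataset(cfg)
  filt <- filter_promoters(ds$promoters, ds$track)
  prof <- bin_scores(filt$promoters, ds$track)
  truth <- ds$truth[match(rownames(prof), ds$truth$id), ]
  hi <- metagene_histogram(prof[truth$tier == "high", , drop = FALSE])
  lo <- metagene_histogram(prof[truth$tier == "low", , drop = FALSE])
  expect_true(all(hi$score >= lo$score))
})
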