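test_that("dependency dichotomization uses a strict cutoff", {
  expect_true(dichotomize_dependency(-1.8))
  expect_false(dichotomize_dependency(-0.18))
  expect_false(dichotomize_dependency(-1.0))
  expect_equal(dichotomize_dependency(c(-2, -1, 0.5)),
               c(TRUE, FALSE, FALSE))
})

test_that("Kruskal-Wallis matches hand ranks and the rank-sum oracle", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(10, 11, 12)))
  expect_equal(kw$H, 27 / 7, tolerance = 1e-9)
  ident <- kruskal_wallis(list(c(5, 6, 7), c(5, 6, 7)))
  expect_equal(ident$H, 0, tolerance = 1e-12)
  expect_equal(ident$p_value, 1, tolerance = 1e-12)
  expect_error(kruskal_wallis(list(1:3)), "two groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
  # exhaustive: every 3-vs-3 split of 1..6 (tie-free) equals the oracle
  splits <- combn(6, 3, simplify = FALSE)
  for (s in splits) {
    g <- list(s, setdiff(1:6, s))
    expect_equal(kruskal_wallis(g)$H, kw_oracle(g), tolerance = 1e-9)
  }
})

test_that("Spearman correlation matches hand ranks and handles degeneracy", {
  expect_equal(spearman_correlation(1:5, 1:5)$rho, 1)
  expect_equal(spearman_correlation(1:5, 5:1)$rho, -1)
  expect_equal(spearman_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4))$rho, 0.8,
               tolerance = 1e-9)
  expect_true(is.na(spearman_correlation(c(1, 2, 3), c(7, 7, 7))$rho))
  expect_error(spearman_correlation(1:2, 1:2), ">= 3")
})

test_that("ROC AUC equals brute-force pair counting", {
  expect_equal(roc_auc(c(2, 3, 1, 3), c(TRUE, TRUE, FALSE, FALSE))$auc, 0.625)
  perfect <- roc_auc(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(perfect$auc, 1)
  anti <- roc_auc(c(1, 2, 5, 6), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(anti$auc, 0)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "positive and one negative")
  set.seed(17)
  for (i in 1:25) {
    n <- sample(6:20, 1)
    scores <- sample(1:8, n, replace = TRUE)   # ties likely
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, auc_oracle(scores, labels), tolerance = 1e-9)
    # trapezoidal integration of the curve reproduces the pair-count AUC
    trap <- sum(diff(r$curve$fpr) *
                  (head(r$curve$tpr, -1) + tail(r$curve$tpr, -1)) / 2)
    expect_equal(trap, r$auc, tolerance = 1e-9)
    # negating scores mirrors the AUC
    expect_equal(roc_auc(-scores, labels)$auc, 1 - r$auc, tolerance = 1e-9)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(18)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, 0.4) == 1
  ours <- roc_auc(scores, labels)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-9)
})

test_that("KW H preserves the rank-space F ordering on tie-free groups", {
  set.seed(19)
  stats <- replicate(10, {
    g1 <- sample(1:100, 8); g2 <- sample(101:200, 8)
    mix <- sample(c(g1, g2))
    weak <- list(mix[1:8], mix[9:16])
    strong <- list(g1, g2)
    c(kruskal_wallis(strong)$H - kruskal_wallis(weak)$H)
  })
  expect_true(all(stats > 0))
})

test_that("benchmark recovers planted dependency structure", {
  sim <- simulate_cohort(sim_config(n_genes = 200, n_tumor = 60, n_normal = 15,
                                    planting = "composite", seed = 4))
  fit <- suppressMessages(cki(sim$bundle))
  bm <- benchmark_cohort(fit$scorecards, sim$bundle$dependency,
                         cohort = "SIM")
  expect_gt(bm$tissue$mean_cki_dependent, bm$tissue$mean_cki_not_dependent)
  expect_lt(bm$tissue$kw_p, 0.05)
  expect_gt(bm$tissue$auc, 0.8)
  expect_equal(bm$n_shared_genes, nrow(fit$scorecards))
  expect_lt(bm$tissue$spearman_rho, 0)   # more dependent = more negative
})

test_that("dependency unrelated to CKI gives chance-level AUC", {
  # dependent genes planted, but no expression/survival/clinical effects:
  # the score carries no information about dependency
  sim <- simulate_cohort(sim_config(n_genes = 300, n_tumor = 50, n_normal = 15,
                                    frac_dge = 0, frac_surv = 0,
                                    frac_clinical = 0, frac_hotspot = 0,
                                    frac_dependent = 0.2, seed = 5))
  fit <- suppressMessages(cki(sim$bundle))
  bm <- benchmark_cohort(fit$scorecards, sim$bundle$dependency,
                         cohort = "SIM")
  expect_gt(bm$tissue$auc, 0.4)
  expect_lt(bm$tissue$auc, 0.6)
})

test_that("cell lines without both dependency classes are skipped with a reason", {
  cards <- data.frame(gene = c("a", "b", "c", "d"), cohort = "X",
                      cki_percent = c(50, 40, 30, 20))
  dep <- dependency_matrix(
    matrix(c(-0.2, -0.1, 0, 0.1), 4, 1,
           dimnames = list(c("a", "b", "c", "d"), "CL1")),
    data.frame(cell_line = "CL1", tissue = "t"))
  bm <- benchmark_cohort(cards, dep, cohort = "X")
  expect_null(bm$per_line)
  expect_match(bm$skipped[["CL1"]], "no dependent genes")
  expect_null(bm$tissue)
})

test_that("unmatched genes between scorecards and screen are counted", {
  cards <- data.frame(gene = c("a", "b", "c", "d", "e"), cohort = "X",
                      cki_percent = c(90, 60, 50, 30, 10))
  dep <- dependency_matrix(
    matrix(c(-1.7, -1.5, 0, 0.2, -0.1), 5, 1,
           dimnames = list(c("a", "b", "c", "d", "zzz"), "CL1")),
    data.frame(cell_line = "CL1", tissue = "t"))
  bm <- benchmark_cohort(cards, dep, cohort = "X")
  expect_equal(bm$n_shared_genes, 4)
  expect_equal(bm$n_unmatched_scorecards, 1)
  expect_equal(bm$n_unmatched_dependency, 1)
  expect_equal(bm$tissue$n_dependent, 2)
  expect_equal(bm$tissue$auc, 1)   # dependent genes a,b have top CKI
})
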