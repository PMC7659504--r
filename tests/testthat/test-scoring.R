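test_that("scorecard arithmetic matches the scoring rule", {
  clin <- matrix(0, 1, 3, dimnames = list(NULL, c("T", "N", "M")))
  zero <- assemble_scorecards("g", 0, 0, 0, clin)
  expect_equal(zero$raw_score, 0)
  expect_equal(zero$cki_percent, 0)
  full <- assemble_scorecards("g", 1, 1, 1, clin + 1)
  expect_equal(full$raw_score, 6)
  expect_equal(full$max_score, 6)
  expect_equal(full$cki_percent, 100)
  # the top printed score in a 6-point cohort: raw 4.25 -> 70.83%
  top <- assemble_scorecards("g", 1, 1, 1,
                             matrix(c(1, 0.25, 0), 1,
                                    dimnames = list(NULL, c("T", "N", "M"))))
  expect_equal(top$raw_score, 4.25)
  expect_equal(round(top$cki_percent, 2), 70.83)
})

test_that("unavailable components shrink the maximum score", {
  clin <- matrix(c(0.5, NA), 1, 2, dimnames = list(NULL, c("T", "N")))
  cards <- assemble_scorecards("g", NA, 1, 0, clin,
                               components_available = c(dge = FALSE,
                                                        survival = TRUE,
                                                        hotspot = TRUE))
  expect_equal(cards$max_score, 2 + 1)   # survival + hotspot + T
  expect_equal(cards$raw_score, 1.5)
  no_clin <- assemble_scorecards("g", 1, 0, 0, NULL)
  expect_equal(no_clin$max_score, 3)
})

test_that("CKI is monotone in every component", {
  set.seed(15)
  for (i in 1:50) {
    dge <- rbinom(1, 1, 0.5); surv <- rbinom(1, 1, 0.5)
    hot <- rbinom(1, 1, 0.5)
    clin <- matrix(runif(4), 1, dimnames = list(NULL, c("T", "N", "M", "grade")))
    base <- assemble_scorecards("g", dge, surv, hot, clin)$cki_percent
    # bump one component upward
    which_comp <- sample(1:7, 1)
    d2 <- dge; s2 <- surv; h2 <- hot; c2 <- clin
    if (which_comp == 1) d2 <- 1
    else if (which_comp == 2) s2 <- 1
    else if (which_comp == 3) h2 <- 1
    else c2[which_comp - 3] <- min(1, c2[which_comp - 3] + runif(1))
    bumped <- assemble_scorecards("g", d2, s2, h2, c2)$cki_percent
    expect_gte(bumped, base - 1e-12)
  }
})

test_that("competition ranking shares minimum ranks across ties", {
  cards <- data.frame(gene = c("a", "b", "c", "d"), cohort = "X",
                      cki_percent = c(90, 70, 70, 10))
  r <- rank_cohort(cards)
  expect_equal(r$rank, c(1, 2, 2, 4))
  all_eq <- rank_cohort(data.frame(gene = letters[1:3], cohort = "X",
                                   cki_percent = 5))
  expect_equal(all_eq$rank, rep(1, 3))
  set.seed(16)
  distinct <- rank_cohort(data.frame(gene = letters[1:8], cohort = "X",
                                     cki_percent = sample(8)))
  expect_equal(sort(distinct$rank), 1:8)
  expect_equal(distinct$cki_percent, sort(distinct$cki_percent,
                                          decreasing = TRUE))
})

test_that("cross-cohort Spearman handles self, reversal and shared planting", {
  m <- cbind(A = c(10, 20, 30, 40), B = c(40, 30, 20, 10))
  rho <- cross_cohort_spearman(m)
  expect_equal(diag(rho), c(A = 1, B = 1))
  expect_equal(rho["A", "B"], -1)
  # two cohorts simulated with the same planted genes but independent noise
  cfgA <- sim_config(n_genes = 60, n_tumor = 40, n_normal = 12,
                     planting = "composite", seed = 2)
  cfgB <- sim_config(n_genes = 60, n_tumor = 50, n_normal = 12,
                     planting = "composite", seed = 2, cohort = "SIMB")
  fitA <- suppressMessages(cki(simulate_cohort(cfgA)$bundle))
  fitB <- suppressMessages(cki(simulate_cohort(cfgB)$bundle))
  rho2 <- cross_cohort_spearman(list(A = fitA$scorecards, B = fitB$scorecards))
  expect_gt(rho2["A", "B"], 0)
})

test_that("insufficient overlap yields a missing correlation", {
  m <- cbind(A = c(1, 2, NA, NA), B = c(NA, NA, 3, 4))
  rho <- cross_cohort_spearman(m)
  expect_true(is.na(rho["A", "B"]))
})

test_that("top-quartile overlap counts boundary ties and swaps correctly", {
  cards <- data.frame(gene = sprintf("g%03d", 1:100), cohort = "X",
                      cki_percent = 100:1)
  self <- top_quartile_overlap(cards, cards)
  expect_equal(self$jaccard, 1)
  expect_equal(self$shared, 25)
  # swap 5 of the top 25 for genes outside
  cards2 <- cards
  cards2$cki_percent[1:5] <- 0.5       # demote 5 top genes
  cards2$cki_percent[96:100] <- 99.5   # promote 5 bottom genes
  ov <- top_quartile_overlap(cards, cards2)
  expect_equal(ov$shared, 20)
  disjoint <- cards
  disjoint$cki_percent <- rev(cards$cki_percent)
  expect_equal(top_quartile_overlap(cards, disjoint)$shared, 0)
})

test_that("annotation strata summaries recover planted relevance", {
  sim <- simulate_cohort(sim_config(n_genes = 80, n_tumor = 60, n_normal = 15,
                                    planting = "composite", seed = 3))
  fit <- suppressMessages(cki(sim$bundle))
  res <- summarize_by_annotation(fit$scorecards, sim$bundle$annotations,
                                 stratum = "moa")
  moa_mean <- res$summary$mean_cki[res$summary$stratum == "MOA"]
  other_mean <- res$summary$mean_cki[res$summary$stratum == "non-MOA"]
  expect_gt(moa_mean, other_mean)
  expect_lt(res$kw$p_value, 0.05)
})

test_that("degenerate strata are handled descriptively", {
  cards <- data.frame(gene = c("a", "b", "c"), cohort = "X",
                      cki_percent = c(10, 20, 30))
  cat1 <- annotation_catalog(data.frame(
    gene = c("a", "b", "c"), tdl = "Tbio", understudied = FALSE,
    kinase_group = "TK", kinase_family = "TK-A",
    moa_target_cancers = "", in_trial_cancers = ""))
  res <- summarize_by_annotation(cards, cat1, stratum = "tdl")
  expect_null(res$kw)
  expect_equal(nrow(res$summary), 1)
  # two strata with identical score distributions -> KW p = 1
  cards2 <- data.frame(gene = letters[1:6], cohort = "X",
                       cki_percent = rep(c(10, 20, 30), 2))
  cat2 <- annotation_catalog(data.frame(
    gene = letters[1:6], tdl = rep(c("Tbio", "Tdark"), each = 3),
    understudied = FALSE, kinase_group = "TK", kinase_family = "TK-A",
    moa_target_cancers = "", in_trial_cancers = ""))
  res2 <- summarize_by_annotation(cards2, cat2, stratum = "tdl")
  expect_equal(res2$kw$p_value, 1)
})

test_that("catalog summaries express headline percentages", {
  n <- 634
  cat <- annotation_catalog(data.frame(
    gene = sprintf("K%03d", 1:n),
    tdl = c(rep("Tclin", 49), rep("Tchem", 200), rep("Tbio", 285),
            rep("Tdark", 100)),
    understudied = c(rep(FALSE, n - 151), rep(TRUE, 151)),
    kinase_group = "TK", kinase_family = "TK-A",
    moa_target_cancers = "", in_trial_cancers = ""))
  cs <- catalog_summary(cat)
  expect_equal(round(cs$pct_understudied, 1), 23.8)
  expect_equal(round(cs$pct_tclin), 8)
})
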