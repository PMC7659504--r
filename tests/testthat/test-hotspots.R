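mk_mut <- function(gene, pos, class = "missense",
                   sample = sprintf("S%03d", seq_along(pos))) {
  mutation_table(data.frame(gene = gene, protein_position = pos,
                            variant_class = class, sample = sample,
                            stringsAsFactors = FALSE))
}

test_that("positional counts keep qualifying classes and dedupe per sample", {
  mt <- mk_mut("BRAF", rep(600, 5))
  expect_equal(positional_counts(mt, "BRAF", 766), c("600" = 5L))
  # silent excluded
  mt2 <- mk_mut("BRAF", c(600, 600), class = c("missense", "silent"))
  expect_equal(positional_counts(mt2, "BRAF", 766), c("600" = 1L))
  # duplicate (sample, residue) pairs count once
  mt3 <- mk_mut("BRAF", c(600, 600, 600), class = "insertion",
                sample = c("S1", "S1", "S2"))
  expect_equal(positional_counts(mt3, "BRAF", 766), c("600" = 2L))
  # empty table
  empty <- mutation_table(data.frame(gene = character(0),
                                     protein_position = numeric(0),
                                     variant_class = character(0),
                                     sample = character(0)))
  expect_equal(length(positional_counts(empty, "BRAF", 766)), 0)
  # positions beyond the protein are dropped with a warning
  expect_warning(pc <- positional_counts(mk_mut("X", c(5, 900)), "X", 100),
                 "beyond protein length")
  expect_equal(pc, c("5" = 1L))
})

test_that("cluster detection follows the binomial seed rule", {
  # uniform single hits never seed (binomial threshold >= 1 for n >= 10)
  counts <- setNames(rep(1L, 20), seq(10, 200, by = 10))
  cl <- detect_clusters(counts, 500, 20)
  expect_equal(nrow(cl), 0)
  # maximal concentration: one single-residue cluster with all mutations
  cl2 <- detect_clusters(c("300" = 10L), 500, 10)
  expect_equal(nrow(cl2), 1)
  expect_equal(cl2$start, 300)
  expect_equal(cl2$end, 300)
  expect_equal(cl2$n_mutations, 10L)
  # two seeds three residues apart merge under max_gap = 5
  counts3 <- c("100" = 5L, "103" = 5L)
  cl3 <- detect_clusters(counts3, 500, 10, max_gap = 5)
  expect_equal(nrow(cl3), 1)
  expect_equal(c(cl3$start, cl3$end), c(100, 103))
  expect_equal(cl3$n_mutations, 10L)
  # beyond the gap they stay separate
  counts4 <- c("100" = 5L, "110" = 5L)
  cl4 <- detect_clusters(counts4, 500, 10, max_gap = 5)
  expect_equal(nrow(cl4), 2)
})

test_that("clustering score sums per-cluster mutation fractions", {
  all_in <- data.frame(start = 10, end = 12, n_mutations = 20L)
  expect_equal(gene_clustering_score(all_in, 20), 1)
  none <- data.frame(start = integer(0), end = integer(0),
                     n_mutations = integer(0))
  expect_equal(gene_clustering_score(none, 20), 0)
  two <- data.frame(start = c(1, 50), end = c(2, 51),
                    n_mutations = c(10L, 4L))
  expect_equal(gene_clustering_score(two, 20), 0.7)
})

test_that("degenerate backgrounds give z 0, p 0.5 and no flags", {
  sc <- data.frame(gene = sprintf("g%d", 1:30), total_mutations = 10L,
                   clustering_score = 0.2)
  res <- hotspot_significance(sc)
  expect_true(all(res$z == 0))
  expect_true(all(res$p_value == 0.5))
  expect_false(any(res$hotspot_flag))
  expect_true(all(res$degenerate))
})

test_that("a significant gene below five mutations is never flagged", {
  sc <- data.frame(gene = c(sprintf("bg%d", 1:30), "hot"),
                   total_mutations = c(rep(20L, 30), 4L),
                   clustering_score = c(rnorm(30, 0.05, 0.01), 0.9))
  res <- hotspot_significance(sc, min_mutations = 5, alpha = 0.05)
  hot <- res[res$gene == "hot", ]
  expect_lt(hot$p_value, 0.05)
  expect_false(hot$hotspot_flag)
})

test_that("a planted hotspot among uniform genes is flagged", {
  set.seed(1)
  recs <- lapply(1:100, function(i) {
    pos <- sample.int(500, 20, replace = TRUE)
    if (i == 1) pos[runif(20) < 0.6] <- 250
    data.frame(gene = sprintf("G%03d", i), protein_position = pos,
               variant_class = "missense",
               sample = sprintf("G%03d-S%03d", i, 1:20),
               stringsAsFactors = FALSE)
  })
  mt <- mutation_table(do.call(rbind, recs))
  h <- mutation_hotspots(mt, protein_lengths =
                           setNames(rep(500, 100), sprintf("G%03d", 1:100)))
  expect_true(h$hotspot_flag[h$gene == "G001"])
  expect_gt(h$clustering_score[h$gene == "G001"], 0.4)
})

test_that("clustering is invariant to record order and sample barcodes", {
  set.seed(2)
  recs <- lapply(1:25, function(i)
    data.frame(gene = sprintf("G%02d", i),
               protein_position = sample.int(400, 15, replace = TRUE),
               variant_class = "missense",
               sample = sprintf("G%02d-S%02d", i, 1:15),
               stringsAsFactors = FALSE))
  mt <- mutation_table(do.call(rbind, recs))
  h1 <- mutation_hotspots(mt)
  shuffled <- mt[sample(nrow(mt)), ]
  shuffled$sample <- paste0("XX-", shuffled$sample)
  h2 <- mutation_hotspots(mutation_table(shuffled))
  expect_equal(h1$clustering_score, h2$clustering_score)
  expect_equal(h1$hotspot_flag, h2$hotspot_flag)
})

test_that("flags agree with a permutation oracle on a simulated panel", {
  set.seed(3)
  n_genes <- 50
  L <- 400
  recs <- lapply(seq_len(n_genes), function(i) {
    n <- rpois(1, 15) + 1
    pos <- sample.int(L, n, replace = TRUE)
    if (i <= 5) pos[runif(n) < 0.5] <- 200   # a few true hotspots
    data.frame(gene = sprintf("G%02d", i), protein_position = pos,
               variant_class = "missense",
               sample = sprintf("G%02d-S%03d", i, seq_len(n)),
               stringsAsFactors = FALSE)
  })
  mt <- mutation_table(do.call(rbind, recs))
  plens <- setNames(rep(L, n_genes), sprintf("G%02d", seq_len(n_genes)))
  h <- mutation_hotspots(mt, protein_lengths = plens)

  perm_flag <- vapply(seq_len(n_genes), function(i) {
    g <- h$gene[i]
    tot <- h$total_mutations[i]
    if (tot < 5) return(FALSE)
    obs <- h$clustering_score[i]
    n_perm <- 2000
    ge <- 0
    for (b in seq_len(n_perm)) {
      pos <- sample.int(L, tot, replace = TRUE)
      tab <- table(pos)
      cl <- detect_clusters(setNames(as.integer(tab), names(tab)), L, tot)
      if (gene_clustering_score(cl, tot) >= obs) ge <- ge + 1
    }
    (ge + 1) / (n_perm + 1) < 0.05
  }, TRUE)
  expect_gte(mean(h$hotspot_flag == perm_flag), 0.9)
})
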