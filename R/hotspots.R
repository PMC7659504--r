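#' Per-residue counts of qualifying mutations for one gene
#'
#' Qualifying classes are missense, nonsense, insertion and deletion;
#' silent and other variants are excluded. Multiple records from one sample
#' at one residue count once (one (sample, residue) pair = one mutation).
#' Records with missing position are skipped; positions beyond the protein
#' length are dropped with a warning.
#'
#' @param mutations [mutation_table()] object
#' @param gene gene symbol
#' @param protein_length protein length in residues (>= 1)
#' @return named integer vector: counts indexed by residue (as character);
#'   empty when no qualifying mutations
#' @export
positional_counts <- function(mutations, gene, protein_length) {
  if (protein_length < 1) stop_cki("protein_length must be >= 1")
  sub <- mutations[mutations$gene == gene &
                     mutations$variant_class %in%
                       c("missense", "nonsense", "insertion", "deletion") &
                     !is.na(mutations$protein_position), , drop = FALSE]
  if (nrow(sub) == 0) return(stats::setNames(integer(0), character(0)))
  over <- sub$protein_position > protein_length
  if (any(over)) {
    warning(sprintf("%s: dropped %d mutation(s) beyond protein length %d",
                    gene, sum(over), protein_length), call. = FALSE)
    sub <- sub[!over, , drop = FALSE]
  }
  sub <- sub[!duplicated(paste(sub$sample, sub$protein_position)), , drop = FALSE]
  if (nrow(sub) == 0) return(stats::setNames(integer(0), character(0)))
  tab <- table(sub$protein_position)
  stats::setNames(as.integer(tab), names(tab))
}

#' Detect positional mutation clusters
#'
#' Seed residues are positions whose mutation count exceeds the
#' `1 - seed_q` quantile of Binomial(`total_mutations`, 1/`protein_length`)
#' — the count distribution expected at any single residue under uniform
#' placement. Seeds within `max_gap` residues of each other merge into one
#' cluster, and clusters extend stepwise to neighbouring mutated residues
#' (within `max_gap`) whose count exceeds the uniform background rate
#' `total_mutations / protein_length`. Resulting clusters are
#' non-overlapping intervals.
#'
#' @param counts residue histogram from [positional_counts()]
#' @param protein_length protein length in residues
#' @param total_mutations total qualifying mutations for the gene
#' @param seed_q seed tail probability (default 0.01)
#' @param max_gap maximal residue gap bridged when merging/extending
#'   (default 5)
#' @return data.frame: `start`, `end`, `n_mutations` (zero rows when no
#'   cluster)
#' @export
detect_clusters <- function(counts, protein_length, total_mutations,
                            seed_q = 0.01, max_gap = 5) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      n_mutations = integer(0))
  if (length(counts) == 0 || total_mutations < 1) return(empty)
  pos <- as.integer(names(counts))
  o <- order(pos); pos <- pos[o]; ct <- as.integer(counts)[o]
  thr <- stats::qbinom(1 - seed_q, total_mutations, 1 / protein_length)
  seed <- ct > thr
  if (!any(seed)) return(empty)
  bg <- total_mutations / protein_length
  # merge seeds within max_gap into preliminary clusters
  sp <- pos[seed]
  brk <- c(0, which(diff(sp) > max_gap), length(sp))
  clusters <- lapply(seq_len(length(brk) - 1), function(i)
    c(sp[brk[i] + 1], sp[brk[i + 1]]))
  # extend each cluster stepwise over directly adjacent mutated residues
  # whose count stays above the uniform background rate
  extend <- function(cl) {
    while (any(pos == cl[1] - 1 & ct > bg)) cl[1] <- cl[1] - 1L
    while (any(pos == cl[2] + 1 & ct > bg)) cl[2] <- cl[2] + 1L
    cl
  }
  clusters <- lapply(clusters, extend)
  # merge any overlaps introduced by extension
  m <- do.call(rbind, clusters)
  m <- m[order(m[, 1]), , drop = FALSE]
  merged <- list(m[1, ])
  if (nrow(m) > 1) for (i in 2:nrow(m)) {
    last <- merged[[length(merged)]]
    if (m[i, 1] <= last[2] + 1) {   # overlapping or adjacent after extension
      merged[[length(merged)]] <- c(last[1], max(last[2], m[i, 2]))
    } else {
      merged[[length(merged) + 1]] <- m[i, ]
    }
  }
  out <- data.frame(start = vapply(merged, `[`, 1L, 1),
                    end = vapply(merged, `[`, 1L, 2))
  out$n_mutations <- vapply(seq_len(nrow(out)), function(i)
    sum(ct[pos >= out$start[i] & pos <= out$end[i]]), integer(1))
  out
}

#' Clustering score of one gene
#'
#' Fraction of the gene's qualifying mutations that fall inside detected
#' clusters: the sum over clusters of `n_mutations / total_mutations`.
#' 1 when a single cluster holds every mutation, 0 when no cluster exists.
#'
#' @param clusters [detect_clusters()] output
#' @param total_mutations total qualifying mutations (>= 1)
#' @return score in \[0, 1\]
#' @export
gene_clustering_score <- function(clusters, total_mutations) {
  if (total_mutations < 1) stop_cki("total_mutations must be >= 1")
  if (nrow(clusters) == 0) return(0)
  sum(clusters$n_mutations) / total_mutations
}

#' Hotspot significance against a cross-gene background
#'
#' Standardizes each gene's clustering score against the distribution of
#' scores over all *other* genes with at least 3 mutations (leave-one-out
#' background), yielding a z score and a one-sided upper-tail normal p
#' value. A gene is flagged iff p < `alpha` (optionally BH-adjusted across
#' genes) and it has at least `min_mutations` qualifying mutations. When
#' the background is degenerate (zero spread), p is 1 unless the gene's
#' score exceeds the common value, in which case p is 0 and the result is
#' marked degenerate.
#'
#' @param scores data.frame with columns `gene`, `total_mutations`,
#'   `clustering_score` (one row per gene)
#' @param min_mutations minimum mutation count for a flag (default 5)
#' @param alpha significance level (default 0.05)
#' @param adjust `"none"` (raw p) or `"BH"`
#' @return the input with added columns `z`, `p_value`, `hotspot_flag`,
#'   `degenerate`
#' @export
hotspot_significance <- function(scores, min_mutations = 5, alpha = 0.05,
                                 adjust = "none") {
  stopifnot(all(c("gene", "total_mutations", "clustering_score") %in% names(scores)))
  bg_all <- scores$clustering_score[scores$total_mutations >= 3]
  scores$z <- NA_real_
  scores$p_value <- NA_real_
  scores$degenerate <- FALSE
  for (i in seq_len(nrow(scores))) {
    s <- scores$clustering_score[i]
    bg <- if (scores$total_mutations[i] >= 3)
      bg_all[-match(s, bg_all)] else bg_all   # leave one occurrence out
    if (length(bg) < 2) next
    mu <- mean(bg); sdv <- stats::sd(bg)
    if (sdv == 0) {
      scores$degenerate[i] <- TRUE
      scores$z[i] <- if (s == mu) 0 else Inf * sign(s - mu)
      scores$p_value[i] <- if (s > mu) 0 else if (s < mu) 1 else 0.5
    } else {
      scores$z[i] <- (s - mu) / sdv
      scores$p_value[i] <- stats::pnorm(scores$z[i], lower.tail = FALSE)
    }
  }
  p_eff <- scores$p_value
  if (adjust == "BH" && any(!is.na(p_eff)))
    p_eff[!is.na(p_eff)] <- bh_adjust(p_eff[!is.na(p_eff)])
  scores$hotspot_flag <- !is.na(p_eff) & p_eff < alpha &
    scores$total_mutations >= min_mutations
  scores
}

#' Full hotspot analysis over a gene panel
#'
#' Runs [positional_counts()], [detect_clusters()],
#' [gene_clustering_score()] and [hotspot_significance()] for every gene.
#' Protein lengths come from `protein_lengths` (e.g. the annotation
#' catalog); for genes without a known length, 1.1 times the maximum
#' observed position (rounded up) is used.
#'
#' @param mutations [mutation_table()] object
#' @param genes gene panel (default: genes present in `mutations`)
#' @param protein_lengths named numeric vector of protein lengths (residues)
#' @param seed_q,max_gap,min_mutations,alpha,adjust see the stage functions
#' @return data.frame of class `cki_hotspots`: gene, total_mutations,
#'   n_clusters, clustering_score, z, p_value, hotspot_flag, degenerate;
#'   cluster intervals in the `"clusters"` attribute (named list)
#' @export
mutation_hotspots <- function(mutations, genes = NULL, protein_lengths = NULL,
                              seed_q = 0.01, max_gap = 5, min_mutations = 5,
                              alpha = 0.05, adjust = "none") {
  if (is.null(genes)) genes <- sort(unique(mutations$gene))
  n <- length(genes)
  res <- data.frame(gene = genes, total_mutations = 0L, n_clusters = 0L,
                    clustering_score = 0, stringsAsFactors = FALSE)
  cluster_list <- stats::setNames(vector("list", n), genes)
  for (i in seq_len(n)) {
    g <- genes[i]
    L <- protein_lengths[g]
    if (is.null(L) || is.na(L)) {
      obs <- mutations$protein_position[mutations$gene == g]
      obs <- obs[!is.na(obs)]
      L <- if (length(obs)) ceiling(max(obs) * 1.1) else 1
    }
    counts <- positional_counts(mutations, g, L)
    tot <- sum(counts)
    res$total_mutations[i] <- tot
    if (tot >= 1) {
      cl <- detect_clusters(counts, L, tot, seed_q = seed_q, max_gap = max_gap)
      cluster_list[[g]] <- cl
      res$n_clusters[i] <- nrow(cl)
      res$clustering_score[i] <- gene_clustering_score(cl, tot)
    }
  }
  res <- hotspot_significance(res, min_mutations = min_mutations,
                              alpha = alpha, adjust = adjust)
  attr(res, "clusters") <- cluster_list
  class(res) <- c("cki_hotspots", "data.frame")
  res
}
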