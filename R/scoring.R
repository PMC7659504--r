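#' Assemble per-gene scorecards
#'
#' The raw score of a gene is the sum of its four evidence components:
#' overexpression (0/1), adverse survival (0/1), mutational hotspot (0/1)
#' and the clinical stage-trend scores (each in \[0, 1\] per parameter).
#' The maximum attainable score is the number of available binary
#' components (3 when expression, survival and mutation data are all
#' usable) plus the number of clinical parameters with sufficient data in
#' the cohort. The CKI percentage is `100 * raw / max`. A component only
#' accrues when increased expression goes with progression, worse survival
#' or significant mutation clustering — never from the protective
#' direction.
#'
#' @param genes character vector of scored genes
#' @param dge_component 0/1 (or NA when unavailable) per gene
#' @param survival_component 0/1 (or NA) per gene
#' @param hotspot_component 0/1 (or NA) per gene
#' @param clinical_components numeric matrix genes x parameters, entries in
#'   \[0, 1\], NA columns = parameter unavailable; NULL when no clinical
#'   data
#' @param cohort cohort code
#' @param components_available named logical: which of dge/survival/hotspot
#'   count toward the maximum (default all TRUE)
#' @return data.frame: gene, cohort, dge, survival, hotspot, one
#'   `clinical_*` column per parameter, raw_score, max_score, cki_percent
#' @export
assemble_scorecards <- function(genes, dge_component, survival_component,
                                hotspot_component, clinical_components = NULL,
                                cohort = "COHORT",
                                components_available = c(dge = TRUE,
                                                         survival = TRUE,
                                                         hotspot = TRUE)) {
  n <- length(genes)
  fix <- function(v) { v <- as.numeric(v); v[is.na(v)] <- 0; v }
  comp <- cbind(dge = fix(dge_component), survival = fix(survival_component),
                hotspot = fix(hotspot_component))
  if (any(comp < 0 | comp > 1)) stop_cki("binary components must lie in [0, 1]")
  comp[, !components_available[colnames(comp)]] <- 0
  clin_total <- rep(0, n); params_avail <- 0L
  if (!is.null(clinical_components)) {
    clinical_components <- as.matrix(clinical_components)
    if (any(clinical_components < 0 | clinical_components > 1, na.rm = TRUE))
      stop_cki("clinical per-parameter scores must lie in [0, 1]")
    avail_col <- colSums(!is.na(clinical_components)) > 0
    params_avail <- sum(avail_col)
    if (params_avail > 0) {
      cc <- clinical_components[, avail_col, drop = FALSE]
      cc[is.na(cc)] <- 0
      clin_total <- rowSums(cc)
    }
  }
  raw <- rowSums(comp) + clin_total
  max_score <- sum(components_available) + params_avail
  cards <- data.frame(gene = genes, cohort = cohort,
                      dge = comp[, "dge"], survival = comp[, "survival"],
                      hotspot = comp[, "hotspot"],
                      stringsAsFactors = FALSE)
  if (!is.null(clinical_components))
    for (p in colnames(clinical_components))
      cards[[paste0("clinical_", p)]] <- clinical_components[, p]
  cards$raw_score <- raw
  cards$max_score <- max_score
  cards$cki_percent <- 100 * raw / max_score
  stopifnot(all(cards$cki_percent >= 0 - 1e-12),
            all(cards$cki_percent <= 100 + 1e-12))
  cards
}

#' Rank scorecards within a cohort
#'
#' Competition ranking on descending CKI (ties share the minimum rank);
#' rows are ordered by descending CKI, then lexicographically by gene.
#'
#' @param cards scorecard data.frame
#' @return same data.frame with a `rank` column, reordered
#' @export
rank_cohort <- function(cards) {
  cards$rank <- competition_rank(cards$cki_percent)
  cards[order(-cards$cki_percent, cards$gene), , drop = FALSE]
}

#' Cross-cohort Spearman correlation of CKI scores
#'
#' @param score_table numeric matrix or data.frame, genes x cohorts (NA for
#'   genes unscored in a cohort), or a named list of scorecard data.frames
#' @param min_shared minimum shared genes per cohort pair (default 3)
#' @return cohort x cohort correlation matrix (diagonal 1; NA where the
#'   overlap is insufficient)
#' @export
cross_cohort_spearman <- function(score_table, min_shared = 3) {
  if (is.list(score_table) && !is.data.frame(score_table)) {
    genes <- sort(unique(unlist(lapply(score_table, `[[`, "gene"))))
    m <- sapply(score_table, function(cc)
      cc$cki_percent[match(genes, cc$gene)])
    rownames(m) <- genes
    score_table <- m
  }
  m <- as.matrix(score_table)
  k <- ncol(m)
  out <- matrix(NA_real_, k, k, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ok <- !is.na(m[, i]) & !is.na(m[, j])
    if (i == j) { out[i, j] <- 1 }
    else if (sum(ok) >= min_shared)
      out[i, j] <- stats::cor(m[ok, i], m[ok, j], method = "spearman")
  }
  out
}

#' Overlap of top-quartile gene sets between two cohorts
#'
#' The top set contains the `ceiling(n / 4)` highest-scoring genes, with
#' ties at the boundary score included.
#'
#' @param cards_a,cards_b scorecard data.frames
#' @return list: `shared` (intersection size), `jaccard`, `set_a`, `set_b`
#' @export
top_quartile_overlap <- function(cards_a, cards_b) {
  top_set <- function(cards) {
    n_top <- ceiling(nrow(cards) / 4)
    cut <- sort(cards$cki_percent, decreasing = TRUE)[n_top]
    cards$gene[cards$cki_percent >= cut]
  }
  a <- top_set(cards_a); b <- top_set(cards_b)
  inter <- length(intersect(a, b))
  uni <- length(union(a, b))
  list(shared = inter, jaccard = if (uni == 0) NA_real_ else inter / uni,
       set_a = a, set_b = b)
}

#' Summarize CKI scores by annotation stratum
#'
#' Groups scorecards by target development level, understudied flag,
#' cohort-specific MOA-target status, or kinase group; reports per-stratum
#' n / mean / median CKI, an omnibus Kruskal-Wallis test over strata with
#' at least 2 genes, and pairwise two-sided rank-sum tests.
#'
#' @param cards scorecard data.frame
#' @param catalog [annotation_catalog()] object
#' @param stratum one of `"tdl"`, `"understudied"`, `"moa"`,
#'   `"kinase_group"`
#' @return list: `summary` (data.frame stratum/n/mean/median),
#'   `kw` (list H, p_value; NULL when < 2 testable strata),
#'   `pairwise` (matrix of rank-sum p values or NULL)
#' @export
summarize_by_annotation <- function(cards, catalog, stratum = c("tdl",
                                                                "understudied",
                                                                "moa",
                                                                "kinase_group")) {
  stratum <- match.arg(stratum)
  idx <- match(cards$gene, catalog$gene)
  grp <- switch(stratum,
    tdl = ifelse(is.na(idx), "unknown", catalog$tdl[idx]),
    understudied = ifelse(is.na(idx), NA,
                          ifelse(catalog$understudied[idx], "understudied",
                                 "studied")),
    moa = {
      moa <- strsplit(ifelse(is.na(idx), "", catalog$moa_target_cancers[idx]),
                      ",")
      mapply(function(set, coh) coh %in% trimws(set),
             moa, cards$cohort)
    },
    kinase_group = ifelse(is.na(idx), "unknown", catalog$kinase_group[idx]))
  if (stratum == "moa") grp <- ifelse(grp, "MOA", "non-MOA")
  grp <- as.character(grp)
  keep <- !is.na(grp)
  v <- cards$cki_percent[keep]; grp <- grp[keep]
  strata <- sort(unique(grp))
  summ <- data.frame(stratum = strata,
                     n = vapply(strata, function(s) sum(grp == s), 1L),
                     mean_cki = vapply(strata, function(s) mean(v[grp == s]), 1),
                     median_cki = vapply(strata, function(s)
                       stats::median(v[grp == s]), 1),
                     row.names = NULL, stringsAsFactors = FALSE)
  testable <- summ$stratum[summ$n >= 2]
  kw <- NULL; pairwise <- NULL
  if (length(testable) >= 2) {
    groups <- lapply(testable, function(s) v[grp == s])
    kw <- kruskal_wallis(groups)
    k <- length(testable)
    pairwise <- matrix(NA_real_, k, k, dimnames = list(testable, testable))
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      wt <- suppressWarnings(stats::wilcox.test(groups[[i]], groups[[j]],
                                                exact = FALSE))
      pairwise[i, j] <- pairwise[j, i] <- wt$p.value
    }
  }
  list(summary = summ, kw = kw, pairwise = pairwise)
}

#' Headline counts of an annotation catalog
#'
#' Tabulates the catalog by target development level and understudied flag
#' and expresses each as a percentage of the catalog.
#'
#' @param catalog [annotation_catalog()] object
#' @return list: `n_genes`, `n_understudied`, `pct_understudied`,
#'   `tdl_counts` (named), `pct_tclin`
#' @export
catalog_summary <- function(catalog) {
  n <- nrow(catalog)
  n_u <- sum(catalog$understudied, na.rm = TRUE)
  tdl <- table(factor(catalog$tdl,
                      levels = c("Tclin", "Tchem", "Tbio", "Tdark", "unknown")))
  list(n_genes = n, n_understudied = n_u,
       pct_understudied = 100 * n_u / n,
       tdl_counts = stats::setNames(as.integer(tdl), names(tdl)),
       pct_tclin = 100 * unname(tdl["Tclin"]) / n)
}
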