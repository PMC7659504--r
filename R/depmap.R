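#' Dichotomize dependency scores
#'
#' A gene is dependent in a cell line iff its score is strictly below the
#' cutoff; a score of exactly -1 is not dependent. Missing scores yield NA
#' (such genes are excluded from the benchmark and counted by the caller).
#'
#' @param scores numeric vector
#' @param cutoff dependency cutoff (default -1)
#' @return logical vector (NA for missing scores)
#' @export
dichotomize_dependency <- function(scores, cutoff = -1) {
  scores < cutoff
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic referred to chi-square with k - 1 degrees of
#' freedom.
#'
#' @param groups list of 2+ non-empty numeric vectors
#' @return list with `H` and `p_value`
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop_cki("kruskal_wallis needs at least two groups")
  if (any(lengths(groups) == 0)) stop_cki("all groups must be non-empty")
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (tie-aware), with the t-approximation p
#' value. Undefined (NA) when either vector has zero variance.
#'
#' @param x,y paired numeric vectors, n >= 3
#' @return list with `rho` and `p_value`
#' @export
spearman_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop_cki("spearman needs >= 3 paired finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = unname(ct$p.value))
}

#' ROC curve and AUC
#'
#' AUC is the probability that a randomly drawn positive out-scores a
#' randomly drawn negative, ties counting one half (the rank / Mann-Whitney
#' formulation). The curve is traced over all distinct score thresholds.
#'
#' @param scores numeric vector (higher = more positive-like)
#' @param labels logical vector (TRUE = positive class)
#' @return list: `auc`, `curve` (data.frame `threshold`, `fpr`, `tpr`)
#' @export
roc_auc <- function(scores, labels) {
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- as.logical(labels[ok])
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop_cki("roc_auc needs at least one positive and one negative label")
  r <- rank(scores)
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  distinct <- c(which(diff(s) != 0), length(s))   # last index of each threshold
  tp <- cumsum(l)[distinct]; fp <- cumsum(!l)[distinct]
  curve <- data.frame(threshold = c(Inf, s[distinct]),
                      fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  list(auc = auc, curve = curve)
}

# least-squares slope/intercept/R^2 with slope t-test, for the report
linear_fit <- function(x, y) {
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2, 4])
}

#' Benchmark CKI scores against a dependency screen
#'
#' Reconciles genes between scorecards and the dependency matrix, selects
#' the cell lines mapped to the cohort's tissue, and for every cell line
#' dichotomizes dependency at `cutoff`, compares CKI between dependent and
#' non-dependent genes (Kruskal-Wallis), correlates CKI with the dependency
#' score (Spearman) and computes the ROC AUC of CKI predicting dependency.
#' The same statistics (plus a least-squares fit) are repeated at tissue
#' level on the per-gene mean dependency across the mapped cell lines.
#' Cell lines with a single dependency class are skipped with a reason.
#'
#' @param scorecards scorecard data.frame (columns `gene`, `cki_percent`)
#' @param dependency [dependency_matrix()] object
#' @param tissue_map named character vector mapping cohort code -> tissue
#'   (e.g. `c(LUAD = "lung", LUSC = "lung")`); NULL uses all cell lines
#' @param cohort cohort code (defaults to the scorecards' cohort column)
#' @param cutoff dependency cutoff (default -1)
#' @return list of class `cki_benchmark`: `per_line` (data.frame), `tissue`
#'   (list), `n_shared_genes`, `n_unmatched_scorecards`,
#'   `n_unmatched_dependency`, `skipped` (named reasons)
#' @export
benchmark_cohort <- function(scorecards, dependency, tissue_map = NULL,
                             cohort = NULL, cutoff = -1) {
  stopifnot(inherits(dependency, "cki_dependency"))
  if (is.null(cohort)) cohort <- scorecards$cohort[1]
  shared <- intersect(scorecards$gene, rownames(dependency$scores))
  if (length(shared) < 3) stop_cki("fewer than 3 genes shared with the dependency matrix")
  cki <- scorecards$cki_percent[match(shared, scorecards$gene)]
  dep <- dependency$scores[shared, , drop = FALSE]

  lines <- colnames(dep)
  if (!is.null(tissue_map) && !is.na(tissue_map[cohort])) {
    tis <- tissue_map[[cohort]]
    lines <- dependency$cell_lines$cell_line[dependency$cell_lines$tissue == tis]
    lines <- intersect(colnames(dep), lines)
    if (length(lines) == 0) stop_cki("no cell lines mapped to tissue '%s'", tis)
  }

  skipped <- character(0)
  rows <- list()
  line_stats <- function(scores_line, label) {
    miss <- !is.finite(scores_line)
    flags <- dichotomize_dependency(scores_line[!miss], cutoff)
    v <- cki[!miss]
    if (!any(flags) || all(flags)) {
      skipped[[label]] <<- if (!any(flags)) "no dependent genes" else "all genes dependent"
      return(NULL)
    }
    kw <- kruskal_wallis(list(v[flags], v[!flags]))
    sp <- spearman_correlation(v, scores_line[!miss])
    roc <- roc_auc(v, flags)
    data.frame(cell_line = label, n_genes = length(v),
               n_missing = sum(miss), n_dependent = sum(flags),
               mean_cki_dependent = mean(v[flags]),
               mean_cki_not_dependent = mean(v[!flags]),
               kw_H = kw$H, kw_p = kw$p_value,
               spearman_rho = sp$rho, spearman_p = sp$p_value,
               auc = roc$auc, stringsAsFactors = FALSE)
  }
  for (cl in lines) {
    r <- line_stats(dep[, cl], cl)
    if (!is.null(r)) rows[[cl]] <- r
  }
  per_line <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
              else NULL

  mean_dep <- rowMeans(dep[, lines, drop = FALSE], na.rm = TRUE)
  flags <- dichotomize_dependency(mean_dep, cutoff)
  tissue <- NULL
  if (any(flags, na.rm = TRUE) && !all(flags, na.rm = TRUE)) {
    ok <- !is.na(flags)
    kw <- kruskal_wallis(list(cki[ok][flags[ok]], cki[ok][!flags[ok]]))
    sp <- spearman_correlation(cki[ok], mean_dep[ok])
    roc <- roc_auc(cki[ok], flags[ok])
    lf <- linear_fit(mean_dep[ok], cki[ok])
    tissue <- list(n_genes = sum(ok), n_dependent = sum(flags[ok]),
                   mean_cki_dependent = mean(cki[ok][flags[ok]]),
                   mean_cki_not_dependent = mean(cki[ok][!flags[ok]]),
                   kw_H = kw$H, kw_p = kw$p_value,
                   spearman_rho = sp$rho, spearman_p = sp$p_value,
                   auc = roc$auc, roc_curve = roc$curve, linear = lf)
  } else {
    skipped[["tissue_mean"]] <- "single dependency class"
  }
  structure(list(cohort = cohort, per_line = per_line, tissue = tissue,
                 n_shared_genes = length(shared),
                 n_unmatched_scorecards = nrow(scorecards) - length(shared),
                 n_unmatched_dependency = nrow(dependency$scores) - length(shared),
                 skipped = skipped),
            class = "cki_benchmark")
}

#' @export
print.cki_benchmark <- function(x, ...) {
  cat(sprintf("<cki_benchmark> cohort %s: %d shared genes, %d cell line(s)\n",
              x$cohort, x$n_shared_genes,
              if (is.null(x$per_line)) 0L else nrow(x$per_line)))
  if (!is.null(x$tissue))
    cat(sprintf("  tissue-mean: AUC %.3f, KW p %.3g, dependent mean CKI %.1f vs %.1f\n",
                x$tissue$auc, x$tissue$kw_p, x$tissue$mean_cki_dependent,
                x$tissue$mean_cki_not_dependent))
  invisible(x)
}
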