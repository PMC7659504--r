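#' Counts-per-million normalization
#'
#' Scales each sample to counts per million and returns `log2(CPM + pseudo)`.
#' Library size is the sample's total count over all genes in the matrix.
#'
#' @param x [expression_matrix()] object or a plain count matrix
#' @param pseudo positive offset added before the log (default 1, so zero
#'   counts map to `log2(pseudo)` = 0)
#' @return numeric matrix of log2(CPM + pseudo), same dimnames as the counts
#' @export
cpm_normalize <- function(x, pseudo = 1) {
  counts <- if (inherits(x, "cki_expression")) x$counts else as.matrix(x)
  if (pseudo <= 0) stop_cki("pseudo must be > 0")
  lib <- colSums(counts)
  if (any(lib == 0))
    stop_cki("all-zero library for sample '%s'", colnames(counts)[lib == 0][1])
  cpm <- sweep(counts, 2, lib, `/`) * 1e6
  log2(cpm + pseudo)
}

# raw CPM (no log), used by the low-expression filter
cpm_raw <- function(counts) {
  lib <- colSums(counts)
  if (any(lib == 0))
    stop_cki("all-zero library for sample '%s'", colnames(counts)[lib == 0][1])
  sweep(counts, 2, lib, `/`) * 1e6
}

#' Filter lowly expressed genes
#'
#' Keeps a gene iff its CPM is at least `min_cpm` in at least `min_samples`
#' samples — the usual detectable-expression rule applied before testing.
#'
#' @param x [expression_matrix()] object
#' @param min_cpm CPM threshold (default 1)
#' @param min_samples minimum number of samples meeting the threshold;
#'   default is the smaller of the tumor and normal group sizes
#' @return named logical vector over genes (TRUE = keep)
#' @export
filter_low_expression <- function(x, min_cpm = 1, min_samples = NULL) {
  stopifnot(inherits(x, "cki_expression"))
  if (is.null(min_samples))
    min_samples <- min(sum(x$sample_type == "01"), sum(x$sample_type == "11"))
  cpm <- cpm_raw(x$counts)
  keep <- rowSums(cpm >= min_cpm) >= min_samples
  names(keep) <- x$gene_ids
  keep
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control with enforced monotonicity; the
#' input order is preserved.
#'
#' @param p numeric vector of p values in \[0, 1\]
#' @return vector of BH-adjusted q values, same order as `p`
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop_cki("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Tumor-vs-normal differential overexpression
#'
#' For every gene, computes the log2 fold change as the difference of group
#' means of log2-CPM (tumor minus normal), a two-sided Welch two-sample test
#' on the log2-CPM values, and BH-adjusted p values across all tested genes.
#' A gene is flagged overexpressed iff `log2fc > fc_threshold` and
#' `fdr < fdr_threshold`; under-expressed genes are never flagged. Requires
#' at least three samples per group, mirroring the cohort eligibility rule.
#'
#' @param x [expression_matrix()] object (or a log2-CPM matrix if `log2cpm`
#'   is TRUE)
#' @param group optional logical/character vector of per-sample groups; by
#'   default taken from the sample-type codes ("01" tumor vs "11" normal)
#' @param fc_threshold log2 fold-change cutoff (default 1)
#' @param fdr_threshold FDR cutoff (default 0.01)
#' @param pseudo offset passed to [cpm_normalize()]
#' @return data.frame of class `cki_dge`: gene, log2fc, p_value, fdr,
#'   overexpressed_flag
#' @export
differential_overexpression <- function(x, group = NULL, fc_threshold = 1,
                                        fdr_threshold = 0.01, pseudo = 1) {
  if (inherits(x, "cki_expression")) {
    lcpm <- cpm_normalize(x, pseudo = pseudo)
    if (is.null(group)) group <- x$sample_type == "01"
  } else {
    lcpm <- as.matrix(x)
    if (is.null(group)) stop_cki("group labels required for a plain matrix")
  }
  group <- as.logical(group)
  idx_t <- which(group); idx_n <- which(!group)
  if (length(idx_t) < 3 || length(idx_n) < 3)
    stop_cki("differential expression requires >= 3 tumor and >= 3 normal samples (got %d/%d)",
             length(idx_t), length(idx_n))
  w <- welch_rows(lcpm, idx_t, idx_n)
  log2fc <- w$mean1 - w$mean2
  fdr <- bh_adjust(w$p)
  res <- data.frame(gene = rownames(lcpm), log2fc = log2fc, p_value = w$p,
                    fdr = fdr,
                    overexpressed_flag = log2fc > fc_threshold & fdr < fdr_threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("cki_dge", "data.frame")
  res
}
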