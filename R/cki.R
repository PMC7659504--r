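#' Fit the Clinical Kinase Index for one cohort
#'
#' Runs the full evidence pipeline on a cohort bundle and assembles ranked
#' per-gene scorecards:
#' \enumerate{
#'   \item counts-per-million normalization and low-expression filtering
#'     (filtered genes receive no scorecard);
#'   \item tumor-vs-normal differential overexpression (Welch test on
#'     log2-CPM, BH-adjusted; flag iff log2FC and FDR pass their cutoffs);
#'     requires at least 3 tumor and 3 normal samples, otherwise the
#'     component is unavailable and the maximum score drops by 1;
#'   \item per-gene survival component: log-rank test between the upper and
#'     lower expression quartile arms, scoring only when the
#'     high-expression arm fares worse;
#'   \item per-gene clinical component: directional pairwise stage tests
#'     for each available staging parameter (T, N, M, grade,
#'     pathologic/clinical stage), each contributing at most 1;
#'   \item mutational hotspot component: positional clustering score
#'     standardized against the cross-gene background, flagged at
#'     `min_mutations` or more mutations.
#' }
#' The raw score is the sum of all components; the CKI percentage
#' normalizes by the cohort's maximum attainable score; ranks use
#' competition ranking on descending CKI.
#'
#' @param bundle [cohort_bundle()] object
#' @param config [cki_config()] object
#' @return object of class `cki` with elements `scorecards` (ranked
#'   data.frame), `dge`, `survival_detail`, `clinical_detail`, `hotspots`,
#'   `parameters_available`, `components_available`, `exclusions` (named
#'   counts), `config`, `cohort`
#' @seealso [simulate_cohort()] to generate a synthetic bundle,
#'   [benchmark_cohort()] to compare against a dependency screen
#' @examples
#' sim <- simulate_cohort(sim_config(n_genes = 40, n_tumor = 60,
#'                                   n_normal = 20, seed = 7))
#' fit <- cki(sim$bundle)
#' fit
#' head(as.data.frame(fit))
#' @export
cki <- function(bundle, config = cki_config()) {
  stopifnot(inherits(bundle, "cki_bundle"), inherits(config, "cki_config"))
  expr <- bundle$expression
  exclusions <- c()

  # -- expression filter ----------------------------------------------------
  keep <- filter_low_expression(expr, min_cpm = config$dge$min_cpm,
                                min_samples = config$dge$min_samples)
  exclusions["low_expression_genes"] <- sum(!keep)
  if (!any(keep)) stop_cki("no gene passes the expression filter")
  # library sizes use all genes; filtered genes are then dropped from testing
  lcpm <- cpm_normalize(expr$counts, pseudo = config$dge$pseudo)[keep, , drop = FALSE]
  genes <- rownames(lcpm)

  # -- differential overexpression ------------------------------------------
  tum <- expr$sample_type == "01"
  dge_ok <- sum(tum) >= 3 && sum(!tum) >= 3
  if (dge_ok) {
    dge <- differential_overexpression(lcpm, group = tum,
                                       fc_threshold = config$dge$fc_threshold,
                                       fdr_threshold = config$dge$fdr_threshold)
    dge_comp <- as.numeric(dge$overexpressed_flag)
  } else {
    warning(sprintf("cohort %s: fewer than 3 tumor or normal samples; overexpression component unavailable",
                    bundle$cohort), call. = FALSE)
    dge <- NULL
    dge_comp <- rep(NA_real_, length(genes))
  }

  # -- per-patient tumor expression -----------------------------------------
  tum_idx <- which(tum)
  pat <- expr$patient_id[tum_idx]
  first <- !duplicated(pat)
  expr_pat <- lcpm[, tum_idx[first], drop = FALSE]
  colnames(expr_pat) <- pat[first]

  # -- survival --------------------------------------------------------------
  records <- build_survival_records(bundle$clinical)
  exclusions["survival_patients"] <- attr(records, "n_excluded")
  surv_detail <- lapply(genes, function(g)
    survival_score(expr_pat[g, ], records, alpha = config$survival$alpha,
                   quartiles = config$survival$quartiles,
                   min_patients = config$survival$min_patients))
  names(surv_detail) <- genes
  surv_comp <- vapply(surv_detail, `[[`, 0, "score")

  # -- clinical staging -------------------------------------------------------
  assign <- stage_assignments(bundle$clinical,
                              parameters = config$clinical$parameters)
  exclusions["unmapped_stage_labels"] <- sum(attr(assign, "n_unmapped"))
  clin_detail <- lapply(genes, function(g)
    clinical_score(expr_pat[g, ], assign,
                   parameters = config$clinical$parameters,
                   alpha = config$clinical$alpha,
                   pairs = config$clinical$pairs,
                   rule = config$clinical$rule))
  names(clin_detail) <- genes
  clin_mat <- t(vapply(clin_detail, `[[`,
                       numeric(length(config$clinical$parameters)), "scores"))
  colnames(clin_mat) <- config$clinical$parameters
  params_avail <- max(vapply(clin_detail, `[[`, 0L, "parameters_available"))

  # -- mutational hotspots -----------------------------------------------------
  plen <- NULL
  if (!is.null(bundle$annotations) &&
      "protein_length" %in% names(bundle$annotations))
    plen <- stats::setNames(bundle$annotations$protein_length,
                            bundle$annotations$gene)
  hot <- mutation_hotspots(bundle$mutations, genes = genes,
                           protein_lengths = plen,
                           seed_q = config$hotspot$seed_q,
                           max_gap = config$hotspot$max_gap,
                           min_mutations = config$hotspot$min_mutations,
                           alpha = config$hotspot$alpha,
                           adjust = config$hotspot$adjust)
  hot_comp <- as.numeric(hot$hotspot_flag[match(genes, hot$gene)])

  # -- assemble ----------------------------------------------------------------
  cards <- assemble_scorecards(
    genes, dge_comp, surv_comp, hot_comp, clin_mat, cohort = bundle$cohort,
    components_available = c(dge = dge_ok, survival = TRUE, hotspot = TRUE))
  if (!is.null(bundle$annotations)) {
    idx <- match(cards$gene, bundle$annotations$gene)
    cards$tdl <- ifelse(is.na(idx), "unknown", bundle$annotations$tdl[idx])
    cards$understudied <- !is.na(idx) & bundle$annotations$understudied[idx]
    moa <- strsplit(ifelse(is.na(idx), "",
                           bundle$annotations$moa_target_cancers[idx]), ",")
    cards$moa_target <- mapply(function(set, coh) coh %in% trimws(set),
                               moa, cards$cohort)
  }
  cards <- rank_cohort(cards)

  structure(list(scorecards = cards, dge = dge, survival_detail = surv_detail,
                 clinical_detail = clin_detail, hotspots = hot,
                 parameters_available = params_avail,
                 components_available = c(dge = dge_ok, survival = TRUE,
                                          hotspot = TRUE),
                 exclusions = exclusions, config = config,
                 cohort = bundle$cohort),
            class = "cki")
}

#' @export
print.cki <- function(x, ...) {
  cat(sprintf("Clinical Kinase Index fit: cohort %s\n", x$cohort))
  cat(sprintf("  %d genes scored; maximum score %s (3 evidence components + %d clinical parameters)\n",
              nrow(x$scorecards), format(x$scorecards$max_score[1]),
              x$parameters_available))
  top <- utils::head(x$scorecards, 5)
  cat("  top genes:\n")
  for (i in seq_len(nrow(top)))
    cat(sprintf("    %2d. %-10s CKI %6.2f (raw %.2f / %g)\n", top$rank[i],
                top$gene[i], top$cki_percent[i], top$raw_score[i],
                top$max_score[i]))
  invisible(x)
}

#' @export
summary.cki <- function(object, ...) {
  cards <- object$scorecards
  comp_rates <- c(dge = mean(cards$dge), survival = mean(cards$survival),
                  hotspot = mean(cards$hotspot))
  clin_cols <- grep("^clinical_", names(cards), value = TRUE)
  clin_means <- vapply(clin_cols, function(cc) mean(cards[[cc]], na.rm = TRUE), 1)
  out <- list(cohort = object$cohort, n_genes = nrow(cards),
              max_score = cards$max_score[1],
              component_rates = comp_rates, clinical_means = clin_means,
              cki_quartiles = stats::quantile(cards$cki_percent,
                                              c(0, 0.25, 0.5, 0.75, 1)),
              exclusions = object$exclusions,
              top = utils::head(cards, 10))
  class(out) <- "summary.cki"
  out
}

#' @export
print.summary.cki <- function(x, ...) {
  cat(sprintf("CKI summary — cohort %s: %d genes, max score %g\n",
              x$cohort, x$n_genes, x$max_score))
  cat(sprintf("  component rates: overexpression %.2f, survival %.2f, hotspot %.2f\n",
              x$component_rates["dge"], x$component_rates["survival"],
              x$component_rates["hotspot"]))
  if (length(x$clinical_means)) {
    cat("  mean clinical sub-scores:",
        paste(sprintf("%s %.3f", sub("^clinical_", "", names(x$clinical_means)),
                      x$clinical_means), collapse = ", "), "\n")
  }
  q <- x$cki_quartiles
  cat(sprintf("  CKI %%: min %.1f / Q1 %.1f / median %.1f / Q3 %.1f / max %.1f\n",
              q[1], q[2], q[3], q[4], q[5]))
  if (length(x$exclusions))
    cat("  exclusions:",
        paste(sprintf("%s=%d", names(x$exclusions), x$exclusions),
              collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.cki <- function(x, ...) x$scorecards

#' Plot a CKI fit
#'
#' Histogram of the cohort's CKI percentages with the top-quartile cutoff,
#' plus per-component firing rates.
#'
#' @param x `cki` object
#' @param ... passed to [graphics::hist()]
#' @export
plot.cki <- function(x, ...) {
  cards <- x$scorecards
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::hist(cards$cki_percent, breaks = 20,
                 main = sprintf("CKI distribution (%s)", x$cohort),
                 xlab = "CKI (%)", col = "grey80", border = "white", ...)
  cut <- sort(cards$cki_percent, decreasing = TRUE)[ceiling(nrow(cards) / 4)]
  graphics::abline(v = cut, lty = 2)
  rates <- c(overexpr = mean(cards$dge), survival = mean(cards$survival),
             hotspot = mean(cards$hotspot))
  graphics::barplot(rates, ylim = c(0, 1), ylab = "fraction of genes",
                    main = "component rates", col = "steelblue")
  invisible(x)
}
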