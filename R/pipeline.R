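# deterministic hash of the resolved configuration, embedded in run outputs
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA),
             tmp)
  unname(tools::md5sum(tmp))
}

#' Score one or more cohorts end to end
#'
#' Fits [cki()] on each bundle and writes, per cohort,
#' `scorecards_<cohort>.tsv` (+ `.json` summary) into `out_dir`; with more
#' than one cohort a cross-cohort Spearman matrix
#' (`cross_cohort_spearman.tsv`) is added. A `run_summary.json` records the
#' seed, the resolved config hash, and every exclusion count. Outputs are
#' byte-identical across reruns with the same inputs, config and seed.
#'
#' @param bundles a [cohort_bundle()], a list of them, or a character
#'   vector of exported bundle directories (read with [read_bundle()])
#' @param out_dir output directory
#' @param config [cki_config()]
#' @param seed seed recorded in the outputs (the scoring itself is
#'   deterministic)
#' @return named list of `cki` fits, invisibly
#' @export
run_score <- function(bundles, out_dir, config = cki_config(), seed = NULL) {
  if (inherits(bundles, "cki_bundle")) bundles <- list(bundles)
  if (is.character(bundles))
    bundles <- lapply(bundles, function(d) read_bundle(d, cohort = basename(d)))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop_cki("cannot create output directory '%s'", out_dir)
  fits <- list()
  for (b in bundles) {
    fit <- cki(b, config = config)
    fits[[b$cohort]] <- fit
    write_scorecards(fit$scorecards,
                     file.path(out_dir, sprintf("scorecards_%s.tsv", b$cohort)),
                     seed = seed)
  }
  if (length(fits) > 1) {
    rho <- cross_cohort_spearman(lapply(fits, `[[`, "scorecards"))
    write_tsv(data.frame(cohort = rownames(rho), rho, check.names = FALSE),
              file.path(out_dir, "cross_cohort_spearman.tsv"))
  }
  summary <- list(
    cohorts = names(fits),
    n_genes = vapply(fits, function(f) nrow(f$scorecards), 1L),
    exclusions = lapply(fits, function(f) as.list(f$exclusions)),
    parameters_available = vapply(fits, `[[`, 1L, "parameters_available"),
    seed = seed,
    config_hash = config_hash(config))
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(fits)
}

#' Benchmark scored cohorts against a dependency screen
#'
#' Runs [benchmark_cohort()] for each fit and writes
#' `benchmark_<cohort>.tsv` (per-cell-line statistics) and a combined
#' `benchmark_report.json` (tissue-level statistics, unmatched-gene counts,
#' skip reasons) into `out_dir`.
#'
#' @param fits named list of `cki` fits (from [run_score()]) or a single
#'   fit
#' @param dependency [dependency_matrix()] object
#' @param tissue_map named cohort -> tissue character vector (NULL: use all
#'   cell lines for every cohort)
#' @param out_dir output directory
#' @param cutoff dependency cutoff (default -1)
#' @return named list of `cki_benchmark` objects, invisibly
#' @export
run_benchmark <- function(fits, dependency, tissue_map = NULL, out_dir,
                          cutoff = -1) {
  if (inherits(fits, "cki")) fits <- stats::setNames(list(fits), fits$cohort)
  if (!length(fits)) stop_cki("no fits supplied; run run_score() first")
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop_cki("cannot create output directory '%s'", out_dir)
  reports <- list()
  for (nm in names(fits)) {
    bm <- benchmark_cohort(fits[[nm]]$scorecards, dependency,
                           tissue_map = tissue_map, cohort = nm,
                           cutoff = cutoff)
    reports[[nm]] <- bm
    if (!is.null(bm$per_line))
      write_tsv(bm$per_line, file.path(out_dir, sprintf("benchmark_%s.tsv", nm)))
  }
  json <- lapply(reports, function(bm) {
    t <- bm$tissue
    if (!is.null(t)) t$roc_curve <- NULL
    list(cohort = bm$cohort, n_shared_genes = bm$n_shared_genes,
         n_unmatched_scorecards = bm$n_unmatched_scorecards,
         n_unmatched_dependency = bm$n_unmatched_dependency,
         tissue = t, skipped = as.list(bm$skipped))
  })
  jsonlite::write_json(json, file.path(out_dir, "benchmark_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(reports)
}
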