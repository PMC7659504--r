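#' Analysis configuration
#'
#' Central configuration for all scoring stages. Call with named lists to
#' override individual keys, e.g. `cki_config(dge = list(fdr_threshold =
#' 0.05))`; unnamed keys keep their defaults.
#'
#' @param dge differential-expression keys: `fc_threshold` (log2 fold-change
#'   cutoff, default 1), `fdr_threshold` (BH-adjusted p cutoff, default 0.01),
#'   `min_cpm` / `min_samples` (low-expression filter: keep a gene iff CPM >=
#'   `min_cpm` in at least `min_samples` samples; `min_samples = NULL` means
#'   the smaller group size), `pseudo` (offset inside log2, default 1)
#' @param survival keys: `alpha` (log-rank significance level, default 0.05),
#'   `quartiles` (lower/upper expression split points, default c(0.25, 0.75)),
#'   `min_patients` (minimum patients with expression + survival, default 8)
#' @param clinical keys: `alpha` (pairwise test level, default 0.05), `pairs`
#'   ("all" ordered level pairs or "consecutive" only), `rule` ("average":
#'   significant increasing pairs / tested pairs; "any": 1 if any pair fires),
#'   `parameters` (ordered subset of T, N, M, grade, pathologic_stage,
#'   clinical_stage)
#' @param hotspot keys: `seed_q` (binomial seed quantile, default 0.01),
#'   `max_gap` (residues between seeds merged into one cluster, default 5),
#'   `min_mutations` (minimum qualifying mutations for a flag, default 5),
#'   `alpha` (default 0.05), `adjust` ("none" or "BH" across genes)
#' @return list of class `cki_config`
#' @export
cki_config <- function(dge = list(), survival = list(), clinical = list(),
                       hotspot = list()) {
  defaults <- list(
    dge = list(fc_threshold = 1, fdr_threshold = 0.01, min_cpm = 1,
               min_samples = NULL, pseudo = 1),
    survival = list(alpha = 0.05, quartiles = c(0.25, 0.75), min_patients = 8),
    clinical = list(alpha = 0.05, pairs = "all", rule = "average",
                    parameters = c("T", "N", "M", "grade",
                                   "pathologic_stage", "clinical_stage")),
    hotspot = list(seed_q = 0.01, max_gap = 5, min_mutations = 5,
                   alpha = 0.05, adjust = "none")
  )
  merge1 <- function(base, over) { base[names(over)] <- over; base }
  cfg <- list(dge = merge1(defaults$dge, dge),
              survival = merge1(defaults$survival, survival),
              clinical = merge1(defaults$clinical, clinical),
              hotspot = merge1(defaults$hotspot, hotspot))
  stopifnot(cfg$dge$fc_threshold >= 0, cfg$dge$pseudo > 0,
            cfg$survival$alpha > 0, cfg$survival$alpha < 1,
            cfg$clinical$pairs %in% c("all", "consecutive"),
            cfg$clinical$rule %in% c("average", "any"),
            cfg$hotspot$adjust %in% c("none", "BH"))
  bad <- setdiff(cfg$clinical$parameters,
                 c("T", "N", "M", "grade", "pathologic_stage", "clinical_stage"))
  if (length(bad)) stop_cki("unknown clinical parameter(s): %s",
                            paste(bad, collapse = ", "))
  structure(cfg, class = "cki_config")
}

#' Load an analysis / simulation configuration from YAML
#'
#' The YAML file may contain a `cohort` block (`sim:` simulation keys, or
#' `dir:` a path to an exported bundle), a `seed`, and any of the
#' [cki_config()] namespaces (`dge:`, `survival:`, `clinical:`, `hotspot:`).
#'
#' @param path YAML file
#' @return list with elements `config` ([cki_config()]), `sim`
#'   ([sim_config()] or NULL), `dir` (bundle directory or NULL), `seed`
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- cki_config(dge = y$dge %||% list(), survival = y$survival %||% list(),
                    clinical = y$clinical %||% list(),
                    hotspot = y$hotspot %||% list())
  sim <- if (!is.null(y$sim)) do.call(sim_config, y$sim) else NULL
  list(config = cfg, sim = sim, dir = y$dir %||% NULL, seed = y$seed %||% 1L)
}
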