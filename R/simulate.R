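#' Simulation configuration
#'
#' Defines one synthetic cancer cohort. Defaults describe the reference
#' verification cohort: 100 genes, 200 tumor patients, 50 normals,
#' negative-binomial counts (mean 100, dispersion 0.2), and 20% of genes
#' carrying each planted effect (2 log2 units of overexpression, hazard
#' ratio 3 for high composite-risk expression, +0.5 log2 per tumor stage
#' level, 60% of mutations concentrated at one residue, dependency mean
#' -1.5).
#'
#' @param n_genes number of genes
#' @param n_tumor,n_normal tumor / normal sample counts (one sample per
#'   patient)
#' @param baseline_mean negative-binomial mean count per gene and sample
#' @param dispersion negative-binomial dispersion (> 0; variance =
#'   mu + dispersion * mu^2)
#' @param frac_dge,frac_surv,frac_clinical,frac_hotspot,frac_dependent
#'   fractions of genes with each planted effect, in \[0, 1\]
#' @param planted_log2fc tumor-over-normal log2 fold change planted in
#'   `frac_dge` genes
#' @param hazard_ratio_high hazard multiplier (>= 1) for patients in the
#'   upper quartile of the composite risk expression
#' @param censor_rate target fraction of censored patients under the
#'   baseline hazard, in \[0, 1\]
#' @param baseline_hazard exponential event rate per day
#' @param stage_levels number of tumor (T) stage levels
#' @param stage_shift additive log2-expression shift per T level planted in
#'   `frac_clinical` genes
#' @param gene_mut_rate expected qualifying mutations per gene (Poisson)
#' @param hotspot_concentration fraction of a planted gene's mutations
#'   placed at its hotspot residue
#' @param protein_length_range min/max protein length in residues
#' @param dep_mean_null,dep_mean_dependent dependency-score means (sd 0.3)
#'   for background and planted-dependent genes
#' @param n_cell_lines number of dependency-screen cell lines
#' @param planting `"independent"` (each effect drawn independently; a gene
#'   may carry several) or `"composite"` (all effects planted on one shared
#'   gene set; requires equal fractions)
#' @param cohort,tissue cohort code and the tissue its cell lines map to
#' @param library_sigma log-normal sd of per-sample library size factors
#' @param seed RNG seed (split into fixed per-component substreams)
#' @return list of class `cki_sim_config`
#' @export
sim_config <- function(n_genes = 100, n_tumor = 200, n_normal = 50,
                       baseline_mean = 100, dispersion = 0.2,
                       frac_dge = 0.2, frac_surv = 0.2, frac_clinical = 0.2,
                       frac_hotspot = 0.2, frac_dependent = 0.2,
                       planted_log2fc = 2, hazard_ratio_high = 3,
                       censor_rate = 0.2, baseline_hazard = 1 / 1000,
                       stage_levels = 4, stage_shift = 0.5,
                       gene_mut_rate = 20, hotspot_concentration = 0.6,
                       protein_length_range = c(300, 800),
                       dep_mean_null = 0, dep_mean_dependent = -1.5,
                       n_cell_lines = 5, planting = c("independent", "composite"),
                       cohort = "SIM", tissue = "sim_tissue",
                       library_sigma = 0.3, seed = 1) {
  planting <- match.arg(planting)
  fracs <- c(frac_dge, frac_surv, frac_clinical, frac_hotspot, frac_dependent)
  if (n_genes < 1) stop_cki("n_genes must be >= 1")
  if (any(fracs < 0 | fracs > 1)) stop_cki("planted fractions must lie in [0, 1]")
  if (dispersion <= 0) stop_cki("dispersion must be > 0")
  if (hazard_ratio_high < 1) stop_cki("hazard_ratio_high must be >= 1")
  if (censor_rate < 0 || censor_rate >= 1) stop_cki("censor_rate must be in [0, 1)")
  if (planting == "composite" && length(unique(fracs)) > 1)
    stop_cki("composite planting requires equal planted fractions")
  structure(as.list(environment()), class = "cki_sim_config")
}

# draw planted flags: exactly round(frac * n) genes per effect
plant_flags <- function(cfg) {
  set.seed(substream_seed(cfg$seed, "planting"))
  n <- cfg$n_genes
  counts <- vapply(c(cfg$frac_dge, cfg$frac_surv, cfg$frac_clinical,
                     cfg$frac_hotspot, cfg$frac_dependent),
                   function(f) as.integer(round(f * n)), integer(1))
  names(counts) <- c("dge", "surv", "clinical", "hotspot", "dependent")
  flags <- matrix(FALSE, n, 5, dimnames = list(NULL, names(counts)))
  if (cfg$planting == "composite") {
    pool <- sample.int(n, max(counts))
    for (k in names(counts)) flags[pool[seq_len(counts[k])], k] <- TRUE
  } else {
    for (k in names(counts)) flags[sample.int(n, counts[k]), k] <- TRUE
  }
  flags
}

#' Simulate a complete synthetic cohort
#'
#' Generates counts, clinical records, somatic mutations, a dependency
#' matrix and an annotation catalog with planted effects recorded in a
#' truth manifest, emulating the statistical structure the CKI score
#' assumes:
#' \itemize{
#'   \item counts are negative binomial around `baseline_mean` with
#'     log-normal library-size factors; planted overexpressed genes have
#'     their tumor mean multiplied by `2^planted_log2fc`;
#'   \item planted stage-trend genes additionally gain `stage_shift` log2
#'     units per T level above 1;
#'   \item survival times are exponential; patients in the upper quartile of
#'     a composite risk expression (the mean standardized log-expression of
#'     all planted survival genes) have their hazard multiplied by
#'     `hazard_ratio_high`; censoring is exponential, calibrated to
#'     `censor_rate` under the baseline hazard;
#'   \item per-gene mutation totals are Poisson(`gene_mut_rate`), placed
#'     uniformly over the protein, except planted hotspot genes which place
#'     each mutation at their hotspot residue with probability
#'     `hotspot_concentration`;
#'   \item dependency scores are Normal(`dep_mean_null`, 0.3), or
#'     Normal(`dep_mean_dependent`, 0.3) for planted-dependent genes.
#' }
#' Each component draws from its own seeded RNG substream, so enlarging one
#' component does not perturb the others. The same config and seed always
#' reproduce an identical cohort.
#'
#' @param config [sim_config()] object
#' @return list with `bundle` ([cohort_bundle()]) and `truth` (data.frame:
#'   gene, planted_dge, planted_surv, planted_clinical, planted_hotspot,
#'   planted_dependent, hotspot_residue)
#' @export
simulate_cohort <- function(config = sim_config()) {
  cfg <- config
  stopifnot(inherits(cfg, "cki_sim_config"))
  genes <- sprintf("KIN%04d", seq_len(cfg$n_genes))
  flags <- plant_flags(cfg)

  tumor_pat <- sprintf("PT%04d", seq_len(cfg$n_tumor))
  normal_pat <- sprintf("PN%04d", seq_len(cfg$n_normal))
  samples <- c(paste0(tumor_pat, "-01"), paste0(normal_pat, "-11"))
  sample_type <- rep(c("01", "11"), c(cfg$n_tumor, cfg$n_normal))
  patient_id <- c(tumor_pat, normal_pat)
  n_s <- length(samples)

  # -- staging (drawn before counts: stage trends feed expression means) ----
  set.seed(substream_seed(cfg$seed, "stages"))
  t_level <- sample.int(cfg$stage_levels, cfg$n_tumor, replace = TRUE)
  n_level <- sample(0:3, cfg$n_tumor, replace = TRUE)
  m_level <- sample(0:1, cfg$n_tumor, replace = TRUE, prob = c(0.8, 0.2))
  g_level <- sample(1:4, cfg$n_tumor, replace = TRUE)
  ps_level <- sample(1:4, cfg$n_tumor, replace = TRUE)
  cs_level <- sample(1:4, cfg$n_tumor, replace = TRUE)
  subfx <- function(n) sample(c("", "a", "b"), n, replace = TRUE)
  roman <- c("i", "ii", "iii", "iv")

  # -- counts ---------------------------------------------------------------
  set.seed(substream_seed(cfg$seed, "counts"))
  libf <- exp(stats::rnorm(n_s, 0, cfg$library_sigma))
  mu <- matrix(cfg$baseline_mean, cfg$n_genes, n_s)
  tum <- sample_type == "01"
  if (any(flags[, "dge"]))
    mu[flags[, "dge"], tum] <- mu[flags[, "dge"], tum] * 2^cfg$planted_log2fc
  if (any(flags[, "clinical"])) {
    shift <- 2^(cfg$stage_shift * (t_level - 1))  # per tumor patient
    mu[flags[, "clinical"], tum] <-
      sweep(mu[flags[, "clinical"], tum, drop = FALSE], 2, shift, `*`)
  }
  mu <- sweep(mu, 2, libf, `*`)
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion),
                   cfg$n_genes, n_s, dimnames = list(genes, samples))
  expr <- expression_matrix(counts, sample_type, patient_id)

  # -- survival -------------------------------------------------------------
  set.seed(substream_seed(cfg$seed, "survival"))
  surv_genes <- which(flags[, "surv"])
  if (length(surv_genes)) {
    lx <- log2(counts[surv_genes, tum, drop = FALSE] + 1)
    z <- (lx - rowMeans(lx)) / pmax(apply(lx, 1, stats::sd), 1e-9)
    risk <- colMeans(z)  # composite risk expression, one value per patient
    high <- risk >= stats::quantile(risk, 0.75, type = 7)
  } else {
    high <- rep(FALSE, cfg$n_tumor)
  }
  rate <- cfg$baseline_hazard * ifelse(high, cfg$hazard_ratio_high, 1)
  t_event <- stats::rexp(cfg$n_tumor, rate)
  rate_c <- cfg$baseline_hazard * cfg$censor_rate / (1 - cfg$censor_rate)
  t_cens <- if (rate_c > 0) stats::rexp(cfg$n_tumor, rate_c) else rep(Inf, cfg$n_tumor)
  obs <- pmax(1, ceiling(pmin(t_event, t_cens)))
  event <- t_event <= t_cens
  clinical <- clinical_table(data.frame(
    patient_id = c(tumor_pat, normal_pat),
    vital_status = c(ifelse(event, "dead", "alive"), rep(NA, cfg$n_normal)),
    days_to_death = c(ifelse(event, obs, NA), rep(NA, cfg$n_normal)),
    days_to_last_follow_up = c(ifelse(event, NA, obs), rep(NA, cfg$n_normal)),
    t_stage = c(paste0("t", t_level, subfx(cfg$n_tumor)), rep(NA, cfg$n_normal)),
    n_stage = c(paste0("n", n_level, subfx(cfg$n_tumor)), rep(NA, cfg$n_normal)),
    m_stage = c(paste0("m", m_level), rep(NA, cfg$n_normal)),
    grade = c(paste0("g", g_level), rep(NA, cfg$n_normal)),
    pathologic_stage = c(paste0("stage ", roman[ps_level], subfx(cfg$n_tumor)),
                         rep(NA, cfg$n_normal)),
    clinical_stage = c(paste0("stage ", roman[cs_level]), rep(NA, cfg$n_normal)),
    stringsAsFactors = FALSE))

  # -- mutations ------------------------------------------------------------
  set.seed(substream_seed(cfg$seed, "mutations"))
  plen <- sample(cfg$protein_length_range[1]:cfg$protein_length_range[2],
                 cfg$n_genes, replace = TRUE)
  hot_res <- ifelse(flags[, "hotspot"],
                    vapply(plen, function(L) sample.int(L, 1), 1L), NA_integer_)
  n_mut <- stats::rpois(cfg$n_genes, cfg$gene_mut_rate)
  rec <- vector("list", cfg$n_genes)
  classes <- c("missense", "nonsense", "insertion", "deletion", "silent")
  probs <- c(0.70, 0.10, 0.05, 0.05, 0.10)
  for (g in seq_len(cfg$n_genes)) {
    k <- n_mut[g]
    if (k == 0) next
    pos <- sample.int(plen[g], k, replace = TRUE)
    if (flags[g, "hotspot"]) {
      # exactly the configured fraction lands on the hotspot residue
      n_hot <- round(cfg$hotspot_concentration * k)
      if (n_hot > 0) pos[sample.int(k, n_hot)] <- hot_res[g]
    }
    rec[[g]] <- data.frame(
      gene = genes[g], protein_position = pos,
      variant_class = sample(classes, k, replace = TRUE, prob = probs),
      sample = sample(paste0(tumor_pat, "-01"), k, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  mutations <- mutation_table(do.call(rbind, c(rec, list(
    data.frame(gene = character(), protein_position = numeric(),
               variant_class = character(), sample = character())))))

  # -- dependency -----------------------------------------------------------
  set.seed(substream_seed(cfg$seed, "dependency"))
  lines <- sprintf("CL%02d", seq_len(cfg$n_cell_lines))
  dep_mu <- ifelse(flags[, "dependent"], cfg$dep_mean_dependent, cfg$dep_mean_null)
  dep <- matrix(stats::rnorm(cfg$n_genes * cfg$n_cell_lines, mean = dep_mu, sd = 0.3),
                cfg$n_genes, cfg$n_cell_lines, dimnames = list(genes, lines))
  dependency <- dependency_matrix(dep, data.frame(cell_line = lines,
                                                  tissue = cfg$tissue,
                                                  stringsAsFactors = FALSE))

  # -- annotations ----------------------------------------------------------
  set.seed(substream_seed(cfg$seed, "annotations"))
  tdl <- sample(c("Tclin", "Tchem", "Tbio", "Tdark"), cfg$n_genes,
                replace = TRUE, prob = c(0.08, 0.30, 0.40, 0.22))
  groups <- c("TK", "TKL", "STE", "CK1", "AGC", "CAMK", "CMGC", "Other", "Atypical")
  grp <- sample(groups, cfg$n_genes, replace = TRUE)
  annotations <- annotation_catalog(data.frame(
    gene = genes, tdl = tdl,
    understudied = stats::runif(cfg$n_genes) < 0.24,
    kinase_group = grp,
    kinase_family = paste0(grp, "-", sample(LETTERS[1:4], cfg$n_genes, TRUE)),
    # approved MOA targets are emulated as truly overexpressed drivers
    moa_target_cancers = ifelse(flags[, "dge"], cfg$cohort, ""),
    in_trial_cancers = ifelse(flags[, "dge"] | stats::runif(cfg$n_genes) < 0.1,
                              cfg$cohort, ""),
    protein_length = plen,
    stringsAsFactors = FALSE))

  truth <- data.frame(gene = genes,
                      planted_dge = flags[, "dge"],
                      planted_surv = flags[, "surv"],
                      planted_clinical = flags[, "clinical"],
                      planted_hotspot = flags[, "hotspot"],
                      planted_dependent = flags[, "dependent"],
                      hotspot_residue = hot_res,
                      stringsAsFactors = FALSE)
  list(bundle = cohort_bundle(cfg$cohort, expr, clinical, mutations,
                              annotations, dependency),
       truth = truth)
}

#' Export / re-import a simulated cohort as plain-text files
#'
#' Writes every file the readers in this package understand: `counts.tsv` +
#' `samples.tsv`, `clinical.tsv`, `mutations.maf` (standard MAF columns),
#' `annotations.tsv`, `dependency.tsv` + `cell_lines.tsv`, and
#' `truth_manifest.tsv`. `read_bundle()` reconstructs the in-memory bundle
#' from such a directory.
#'
#' @param bundle [cohort_bundle()] object
#' @param truth truth manifest data.frame (or NULL to skip)
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
export_bundle <- function(bundle, truth = NULL, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop_cki("cannot create output directory '%s'", dir)
  write_expression(bundle$expression, file.path(dir, "counts.tsv"))
  write_clinical(bundle$clinical, file.path(dir, "clinical.tsv"))
  write_maf(bundle$mutations, file.path(dir, "mutations.maf"), format = "maf")
  if (!is.null(bundle$annotations))
    write_annotations(bundle$annotations, file.path(dir, "annotations.tsv"))
  if (!is.null(bundle$dependency))
    write_dependency(bundle$dependency, file.path(dir, "dependency.tsv"))
  if (!is.null(truth)) write_tsv(truth, file.path(dir, "truth_manifest.tsv"))
  invisible(dir)
}

#' @rdname export_bundle
#' @param cohort cohort code to assign to the re-read bundle
#' @export
read_bundle <- function(dir, cohort = "SIM") {
  ann_path <- file.path(dir, "annotations.tsv")
  dep_path <- file.path(dir, "dependency.tsv")
  cohort_bundle(
    cohort,
    read_expression(file.path(dir, "counts.tsv")),
    read_clinical(file.path(dir, "clinical.tsv")),
    read_maf(file.path(dir, "mutations.maf")),
    annotations = if (file.exists(ann_path)) read_annotations(ann_path) else NULL,
    dependency = if (file.exists(dep_path)) read_dependency(dep_path) else NULL)
}

#' @rdname export_bundle
#' @export
read_truth_manifest <- function(dir) {
  read_tsv(file.path(dir, "truth_manifest.tsv"))
}
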