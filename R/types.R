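#' Construct a validated expression matrix
#'
#' The central expression container: a non-negative integer count matrix
#' (genes in rows, samples in columns) with per-sample metadata. Sample type
#' codes follow the tumor-bank convention: `"01"` primary tumor, `"11"`
#' solid-tissue normal.
#'
#' Duplicate samples for the same (patient, sample type) pair are collapsed
#' to the first occurrence with a warning; the number dropped is recorded in
#' the `"n_dropped_duplicates"` attribute.
#'
#' @param counts integer matrix, genes x samples, with unique rownames (gene
#'   symbols) and colnames (sample barcodes)
#' @param sample_type character vector, one code per sample ("01" or "11")
#' @param patient_id character vector, one patient key per sample
#' @return object of class `cki_expression`: list with `counts`, `gene_ids`,
#'   `sample_ids`, `sample_type`, `patient_id`
#' @export
expression_matrix <- function(counts, sample_type, patient_id) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_cki("counts must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop_cki("duplicate gene symbol(s): %s",
             paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                   collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop_cki("duplicate sample barcode(s)")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad))
    stop_cki("counts must be non-negative integers; offending cell: gene '%s', sample '%s' (value %s)",
             rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
             format(counts[bad[1, 1], bad[1, 2]]))
  if (length(sample_type) != ncol(counts) || length(patient_id) != ncol(counts))
    stop_cki("sample_type and patient_id must have one entry per sample")
  if (anyNA(sample_type) || !all(sample_type %in% c("01", "11")))
    stop_cki("every sample needs a sample_type code '01' (tumor) or '11' (normal)")

  key <- paste(patient_id, sample_type)
  dup <- duplicated(key)
  n_dup <- sum(dup)
  if (n_dup > 0) {
    warning(sprintf("collapsed %d duplicate patient barcode(s) to first occurrence",
                    n_dup), call. = FALSE)
    counts <- counts[, !dup, drop = FALSE]
    sample_type <- sample_type[!dup]
    patient_id <- patient_id[!dup]
  }
  structure(list(counts = counts,
                 gene_ids = rownames(counts),
                 sample_ids = colnames(counts),
                 sample_type = sample_type,
                 patient_id = patient_id),
            n_dropped_duplicates = n_dup,
            class = "cki_expression")
}

#' @export
print.cki_expression <- function(x, ...) {
  cat(sprintf("<cki_expression> %d genes x %d samples (%d tumor, %d normal)\n",
              length(x$gene_ids), length(x$sample_ids),
              sum(x$sample_type == "01"), sum(x$sample_type == "11")))
  invisible(x)
}

#' Construct a validated clinical table
#'
#' One row per patient: vital status, follow-up times in days, and raw
#' (uncollapsed) stage/grade labels as recorded in the clinic.
#'
#' @param df data.frame with columns `patient_id`, `vital_status` ("alive",
#'   "dead" or NA), `days_to_death`, `days_to_last_follow_up`, `t_stage`,
#'   `n_stage`, `m_stage`, `grade`, `pathologic_stage`, `clinical_stage`
#'   (label columns may be NA)
#' @return the data.frame, validated, with class `cki_clinical` prepended
#' @export
clinical_table <- function(df) {
  require_columns(df, c("patient_id", "vital_status", "days_to_death",
                        "days_to_last_follow_up", "t_stage", "n_stage",
                        "m_stage", "grade", "pathologic_stage",
                        "clinical_stage"), "clinical table")
  if (anyDuplicated(df$patient_id)) stop_cki("duplicate patient_id in clinical table")
  df$vital_status <- tolower(as.character(df$vital_status))
  df$vital_status[!df$vital_status %in% c("alive", "dead")] <- NA
  for (col in c("days_to_death", "days_to_last_follow_up")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
    if (any(df[[col]] < 0, na.rm = TRUE))
      stop_cki("negative values in %s", col)
  }
  class(df) <- c("cki_clinical", "data.frame")
  df
}

#' Construct a validated somatic mutation table
#'
#' @param df data.frame with columns `gene`, `protein_position` (1-based
#'   residue index, NA allowed), `variant_class` (one of missense, nonsense,
#'   insertion, deletion, silent, other), `sample`
#' @return data.frame with class `cki_mutations`; rows with missing position
#'   are retained but unusable for clustering
#' @export
mutation_table <- function(df) {
  require_columns(df, c("gene", "protein_position", "variant_class", "sample"),
                  "mutation table")
  df$protein_position <- suppressWarnings(as.numeric(df$protein_position))
  if (any(df$protein_position < 1, na.rm = TRUE))
    stop_cki("protein_position must be >= 1 (1-based residue index)")
  known <- c("missense", "nonsense", "insertion", "deletion", "silent", "other")
  df$variant_class <- as.character(df$variant_class)
  df$variant_class[!df$variant_class %in% known] <- "other"
  class(df) <- c("cki_mutations", "data.frame")
  df
}

#' Construct a validated gene annotation catalog
#'
#' Static per-gene annotations: target development level (TDL), understudied
#' flag, kinase group/family, the cohorts in which the gene is the
#' mechanism-of-action (MOA) target of an approved drug, and optionally
#' protein length (residues) used by the hotspot module.
#'
#' @param df data.frame with columns `gene`, `tdl` (Tclin/Tchem/Tbio/Tdark/
#'   unknown), `understudied` (logical), `kinase_group`, `kinase_family`,
#'   `moa_target_cancers`, `in_trial_cancers` (comma-separated cohort codes,
#'   empty string for none); optional `protein_length`
#' @return data.frame with class `cki_annotations`
#' @export
annotation_catalog <- function(df) {
  require_columns(df, c("gene", "tdl", "understudied", "kinase_group",
                        "kinase_family", "moa_target_cancers",
                        "in_trial_cancers"), "annotation catalog")
  if (anyDuplicated(df$gene)) stop_cki("duplicate gene in annotation catalog")
  df$tdl <- as.character(df$tdl)
  df$tdl[is.na(df$tdl) | !df$tdl %in% c("Tclin", "Tchem", "Tbio", "Tdark")] <- "unknown"
  df$understudied <- as.logical(df$understudied)
  for (col in c("moa_target_cancers", "in_trial_cancers")) {
    df[[col]] <- as.character(df[[col]])
    df[[col]][is.na(df[[col]])] <- ""
  }
  class(df) <- c("cki_annotations", "data.frame")
  df
}

#' Construct a dependency-screen matrix
#'
#' Gene x cell-line matrix of loss-of-function dependency scores (more
#' negative = more essential; scores below -1 are conventionally "dependent")
#' together with a cell-line-to-tissue mapping.
#'
#' @param scores numeric matrix, genes x cell lines, dimnames required
#' @param cell_lines data.frame with columns `cell_line`, `tissue` covering
#'   every column of `scores`
#' @return object of class `cki_dependency`
#' @export
dependency_matrix <- function(scores, cell_lines) {
  if (!is.matrix(scores)) scores <- as.matrix(scores)
  if (is.null(rownames(scores)) || is.null(colnames(scores)))
    stop_cki("dependency scores need gene rownames and cell-line colnames")
  require_columns(cell_lines, c("cell_line", "tissue"), "cell line metadata")
  unmapped <- setdiff(colnames(scores), cell_lines$cell_line)
  if (length(unmapped))
    warning(sprintf("%d cell line(s) without tissue mapping: %s",
                    length(unmapped), paste(unmapped, collapse = ", ")),
            call. = FALSE)
  structure(list(scores = scores, cell_lines = cell_lines,
                 unmapped = unmapped),
            class = "cki_dependency")
}

#' Bundle all inputs of one cancer cohort
#'
#' @param cohort cohort code, e.g. `"KIRP"`
#' @param expression [expression_matrix()] object
#' @param clinical [clinical_table()] object
#' @param mutations [mutation_table()] object
#' @param annotations [annotation_catalog()] object or NULL
#' @param dependency [dependency_matrix()] object or NULL
#' @return object of class `cki_bundle`
#' @export
cohort_bundle <- function(cohort, expression, clinical, mutations,
                          annotations = NULL, dependency = NULL) {
  stopifnot(inherits(expression, "cki_expression"),
            inherits(clinical, "cki_clinical"),
            inherits(mutations, "cki_mutations"))
  structure(list(cohort = cohort, expression = expression,
                 clinical = clinical, mutations = mutations,
                 annotations = annotations, dependency = dependency),
            class = "cki_bundle")
}

#' @export
print.cki_bundle <- function(x, ...) {
  cat(sprintf("<cki_bundle> cohort %s: %d genes, %d samples, %d patients, %d mutation records\n",
              x$cohort, length(x$expression$gene_ids),
              length(x$expression$sample_ids), nrow(x$clinical),
              nrow(x$mutations)))
  invisible(x)
}
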