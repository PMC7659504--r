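#' Read a count matrix with sample metadata
#'
#' Expects a tab-separated file whose first column (`gene`) holds gene
#' symbols and whose remaining columns are sample barcodes. Sample type and
#' patient assignment come from a sidecar TSV (`sample_id`, `sample_type`,
#' `patient_id`); when no sidecar is given they are inferred from barcodes of
#' the form `<patient>-<code>` (code "01" primary tumor, "11" normal).
#'
#' @param path counts TSV
#' @param samples_path sidecar sample-metadata TSV; defaults to
#'   `samples.tsv` next to `path` if that file exists, otherwise barcodes are
#'   parsed
#' @return [expression_matrix()] object
#' @export
read_expression <- function(path, samples_path = NULL) {
  df <- read_tsv(path, colClasses = "character")
  require_columns(df, "gene", "counts file")
  if (ncol(df) < 2) stop_cki("counts file has no sample columns")
  genes <- df$gene
  samples <- setdiff(names(df), "gene")
  counts <- matrix(NA_real_, nrow = length(genes), ncol = length(samples),
                   dimnames = list(genes, samples))
  for (s in samples) {
    v <- suppressWarnings(as.numeric(df[[s]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad))
      stop_cki("invalid count '%s' at gene '%s', sample '%s'",
               df[[s]][bad[1]], genes[bad[1]], s)
    counts[, s] <- v
  }
  if (is.null(samples_path)) {
    cand <- file.path(dirname(path), "samples.tsv")
    if (file.exists(cand)) samples_path <- cand
  }
  if (!is.null(samples_path)) {
    meta <- read_tsv(samples_path, colClasses = "character")
    require_columns(meta, c("sample_id", "sample_type", "patient_id"),
                    "sample metadata")
    idx <- match(samples, meta$sample_id)
    if (anyNA(idx))
      stop_cki("sample(s) missing from metadata: %s",
               paste(samples[is.na(idx)], collapse = ", "))
    sample_type <- meta$sample_type[idx]
    patient_id <- meta$patient_id[idx]
  } else {
    parts <- regmatches(samples, regexec("^(.*)-([0-9]{2})$", samples))
    if (any(lengths(parts) != 3))
      stop_cki("cannot infer sample type from barcode '%s'; provide samples_path",
               samples[which(lengths(parts) != 3)[1]])
    patient_id <- vapply(parts, `[`, "", 2)
    sample_type <- vapply(parts, `[`, "", 3)
  }
  expression_matrix(counts, sample_type, patient_id)
}

#' Write a count matrix (and sample sidecar)
#'
#' Inverse of [read_expression()]: writes `<path>` (gene column plus one
#' column per barcode) and `samples.tsv` in the same directory.
#'
#' @param x [expression_matrix()] object
#' @param path output TSV
#' @export
write_expression <- function(x, path) {
  df <- data.frame(gene = x$gene_ids, check.names = FALSE)
  cnt <- as.data.frame(x$counts, check.names = FALSE)
  df <- cbind(df, cnt)
  write_tsv(df, path)
  write_tsv(data.frame(sample_id = x$sample_ids, sample_type = x$sample_type,
                       patient_id = x$patient_id),
            file.path(dirname(path), "samples.tsv"))
  invisible(path)
}

#' Read a clinical table
#'
#' @param path TSV with the [clinical_table()] columns
#' @return [clinical_table()] object
#' @export
read_clinical <- function(path) {
  df <- read_tsv(path, colClasses = "character")
  clinical_table(df)
}

#' @rdname read_clinical
#' @param x clinical table
#' @export
write_clinical <- function(x, path) {
  write_tsv(as.data.frame(x), path)
  invisible(path)
}

# MAF variant classification -> internal class
normalize_variant_class <- function(vc) {
  map <- c(Missense_Mutation = "missense", Nonsense_Mutation = "nonsense",
           In_Frame_Ins = "insertion", Frame_Shift_Ins = "insertion",
           In_Frame_Del = "deletion", Frame_Shift_Del = "deletion",
           Silent = "silent",
           missense = "missense", nonsense = "nonsense",
           insertion = "insertion", deletion = "deletion", silent = "silent")
  out <- unname(map[vc])
  out[is.na(out)] <- "other"
  out
}

# Protein_position dialects: "600", "600/766" (position/protein length),
# "600-601/766" (range; the first residue is used). Non-numeric -> NA.
parse_protein_position <- function(x) {
  x <- as.character(x)
  m <- regmatches(x, regexec("^([0-9]+)", x))
  pos <- vapply(m, function(p) if (length(p)) as.numeric(p[2]) else NA_real_,
                numeric(1))
  pos
}

# protein length from the "pos/len" dialect, NA when absent
parse_protein_length <- function(x) {
  m <- regmatches(as.character(x), regexec("/([0-9]+)\\s*$", as.character(x)))
  vapply(m, function(p) if (length(p) == 2) as.numeric(p[2]) else NA_real_,
         numeric(1))
}

#' Read a somatic mutation table (MAF or minimal TSV)
#'
#' Accepts standard MAF column headers (`Hugo_Symbol`, `Protein_position`,
#' `Variant_Classification`, `Tumor_Sample_Barcode`) or the package's
#' minimal dialect (`gene`, `protein_position`, `variant_class`, `sample`).
#' `Protein_position` values written as `"600/766"` (residue / protein
#' length) keep residue 600; the protein length is retained in the
#' `"protein_lengths"` attribute when present. Records with missing position
#' are kept but are unusable for clustering. An empty file yields an empty
#' table, not an error.
#'
#' @param path MAF/TSV file
#' @return [mutation_table()] object
#' @export
read_maf <- function(path) {
  df <- read_tsv(path, colClasses = "character", comment.char = "#")
  if (nrow(df) == 0 && !any(c("Hugo_Symbol", "gene") %in% names(df)))
    return(mutation_table(data.frame(gene = character(), protein_position = numeric(),
                                     variant_class = character(), sample = character())))
  if ("Hugo_Symbol" %in% names(df)) {
    require_columns(df, c("Hugo_Symbol", "Protein_position",
                          "Variant_Classification", "Tumor_Sample_Barcode"),
                    "MAF file")
    out <- data.frame(gene = df$Hugo_Symbol,
                      protein_position = parse_protein_position(df$Protein_position),
                      variant_class = normalize_variant_class(df$Variant_Classification),
                      sample = df$Tumor_Sample_Barcode,
                      stringsAsFactors = FALSE)
    plen <- parse_protein_length(df$Protein_position)
  } else {
    require_columns(df, c("gene", "protein_position", "variant_class", "sample"),
                    "mutation file")
    out <- data.frame(gene = df$gene,
                      protein_position = parse_protein_position(df$protein_position),
                      variant_class = normalize_variant_class(df$variant_class),
                      sample = df$sample, stringsAsFactors = FALSE)
    plen <- parse_protein_length(df$protein_position)
  }
  tab <- mutation_table(out)
  ok <- !is.na(plen)
  if (any(ok)) {
    attr(tab, "protein_lengths") <-
      vapply(split(plen[ok], out$gene[ok]), max, numeric(1))
  }
  tab
}

#' @rdname read_maf
#' @param x mutation table
#' @param format `"maf"` (standard columns) or `"tsv"` (minimal dialect)
#' @export
write_maf <- function(x, path, format = c("maf", "tsv")) {
  format <- match.arg(format)
  if (format == "maf") {
    rev_map <- c(missense = "Missense_Mutation", nonsense = "Nonsense_Mutation",
                 insertion = "In_Frame_Ins", deletion = "In_Frame_Del",
                 silent = "Silent", other = "Translation_Start_Site")
    df <- data.frame(Hugo_Symbol = x$gene,
                     Protein_position = ifelse(is.na(x$protein_position), ".",
                                               format(x$protein_position,
                                                      scientific = FALSE, trim = TRUE)),
                     Variant_Classification = rev_map[x$variant_class],
                     Tumor_Sample_Barcode = x$sample)
  } else {
    df <- as.data.frame(x)
  }
  write_tsv(df, path)
  invisible(path)
}

#' Read / write a gene annotation catalog
#'
#' @param path annotations TSV with the [annotation_catalog()] columns
#' @return [annotation_catalog()] object
#' @export
read_annotations <- function(path) {
  df <- read_tsv(path)
  df$gene <- as.character(df$gene)
  annotation_catalog(df)
}

#' @rdname read_annotations
#' @param x annotation catalog
#' @export
write_annotations <- function(x, path) {
  write_tsv(as.data.frame(x), path)
  invisible(path)
}

#' Read / write a dependency matrix with cell-line metadata
#'
#' @param path genes x cell-lines TSV (first column `gene`)
#' @param cell_lines_path TSV with `cell_line`, `tissue`; defaults to
#'   `cell_lines.tsv` next to `path`
#' @return [dependency_matrix()] object
#' @export
read_dependency <- function(path, cell_lines_path = NULL) {
  df <- read_tsv(path)
  require_columns(df, "gene", "dependency matrix")
  m <- as.matrix(df[setdiff(names(df), "gene")])
  rownames(m) <- df$gene
  if (is.null(cell_lines_path))
    cell_lines_path <- file.path(dirname(path), "cell_lines.tsv")
  meta <- read_tsv(cell_lines_path, colClasses = "character")
  dependency_matrix(m, meta)
}

#' @rdname read_dependency
#' @param x dependency matrix object
#' @export
write_dependency <- function(x, path) {
  df <- data.frame(gene = rownames(x$scores), check.names = FALSE)
  df <- cbind(df, as.data.frame(x$scores, check.names = FALSE))
  write_tsv(df, path)
  write_tsv(x$cell_lines, file.path(dirname(path), "cell_lines.tsv"))
  invisible(path)
}

#' Write per-gene scorecards
#'
#' Writes a deterministic-ordered TSV (descending CKI, then gene symbol) and
#' a JSON summary sidecar (`<path>.json`) with cohort-level bookkeeping.
#' Output uses "." decimals, UTF-8 and LF line endings.
#'
#' @param cards scorecard data.frame as produced by [cki()] /
#'   [assemble_scorecards()]
#' @param path output TSV path
#' @param seed optional seed recorded in the JSON summary
#' @export
write_scorecards <- function(cards, path, seed = NULL) {
  cards <- cards[order(-cards$cki_percent, cards$gene), , drop = FALSE]
  num <- vapply(cards, is.numeric, TRUE)
  out <- cards
  out[num] <- lapply(out[num], function(v) round(v, 6))
  write_tsv(out, path)
  summary <- list(
    cohort = if (nrow(cards)) cards$cohort[1] else NA,
    n_genes = nrow(cards),
    max_score = if (nrow(cards)) max(cards$max_score) else NA,
    mean_cki = if (nrow(cards)) round(mean(cards$cki_percent), 4) else NA,
    top_genes = utils::head(cards$gene, 5),
    seed = seed
  )
  jsonlite::write_json(summary, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_scorecards
#' @export
read_scorecards <- function(path) {
  read_tsv(path)
}
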