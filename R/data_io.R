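#' Gene annotation table
#'
#' Builds and validates the per-gene annotation used to order genes along the
#' genome. Chromosomes must come from the ordered set 1..22, X, Y; positions
#' are 1-based start coordinates and are used for ordering only (strand is
#' irrelevant at gene-level resolution).
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param chromosome chromosome label per gene (1..22, X, Y).
#' @param start 1-based start coordinate per gene (>= 1).
#' @param biotype optional character vector (e.g. "protein_coding").
#' @return A `data.frame` of class `gene_annotation` with columns
#'   `gene_id`, `chromosome` (factor with ordered levels), `start`, and
#'   optionally `biotype`.
#' @export
gene_annotation <- function(gene_id, chromosome, start, biotype = NULL) {
  gene_id <- as.character(gene_id)
  chromosome <- sub("^chr", "", as.character(chromosome))
  if (anyDuplicated(gene_id))
    stop("duplicate gene ids: ", paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  bad <- setdiff(unique(chromosome), CHROMOSOME_LEVELS)
  if (length(bad))
    stop("unknown chromosome label(s): ", paste(bad, collapse = ", "))
  start <- as.numeric(start)
  if (anyNA(start) || any(start < 1))
    stop("gene start positions must be numeric and >= 1")
  ann <- data.frame(
    gene_id = gene_id,
    chromosome = factor(chromosome, levels = CHROMOSOME_LEVELS),
    start = start,
    stringsAsFactors = FALSE
  )
  if (!is.null(biotype)) ann$biotype <- as.character(biotype)
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Expression data container
#'
#' A genes x samples matrix tied to a [gene_annotation()] table. Two scales
#' are supported: raw `counts` (non-negative) and `log2cpm` (already
#' normalized log2 counts-per-million, as in the typical limma workflow).
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids).
#' @param annotation a [gene_annotation()]; every matrix row must be present.
#' @param scale `"counts"` or `"log2cpm"`.
#' @return A list of class `expression_data` with elements `values`,
#'   `annotation`, `scale`.
#' @export
expression_data <- function(values, annotation, scale = c("counts", "log2cpm")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids in expression matrix")
  if (scale == "counts" && any(values < 0)) stop("counts must be non-negative")
  if (!inherits(annotation, "gene_annotation"))
    annotation <- gene_annotation(annotation$gene_id, annotation$chromosome,
                                  annotation$start, annotation$biotype)
  missing_ann <- setdiff(rownames(values), annotation$gene_id)
  if (length(missing_ann))
    stop("genes absent from annotation: ", paste(head(missing_ann, 5), collapse = ", "),
         if (length(missing_ann) > 5) sprintf(" (and %d more)", length(missing_ann) - 5))
  structure(list(values = values, annotation = annotation, scale = scale),
            class = "expression_data")
}

#' @export
print.expression_data <- function(x, ...) {
  cat(sprintf("expression_data: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' Read an expression TSV with embedded gene annotation
#'
#' Expects a tab-separated file whose first three columns are `gene_id`,
#' `chromosome`, `start`, followed by one numeric column per sample.
#' Alternatively a bare genes x samples TSV (first column `gene_id`) plus a
#' separate annotation TSV via `annotation_path`.
#'
#' @param path expression TSV.
#' @param annotation_path optional separate annotation TSV with columns
#'   `gene_id`, `chromosome`, `start`.
#' @param scale `"counts"` or `"log2cpm"`.
#' @return An [expression_data()] object.
#' @export
read_expression <- function(path, annotation_path = NULL,
                            scale = c("counts", "log2cpm")) {
  scale <- match.arg(scale)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(df)) stop("expression TSV must have a gene_id column")
  if (is.null(annotation_path)) {
    needed <- c("gene_id", "chromosome", "start")
    if (!all(needed %in% names(df)))
      stop("expression TSV must carry gene_id, chromosome, start columns ",
           "(or pass annotation_path)")
    ann <- gene_annotation(df$gene_id, df$chromosome, df$start)
    val_cols <- setdiff(names(df), c(needed, "biotype"))
  } else {
    adf <- read.delim(annotation_path, check.names = FALSE, stringsAsFactors = FALSE)
    ann <- gene_annotation(adf$gene_id, adf$chromosome, adf$start,
                           if ("biotype" %in% names(adf)) adf$biotype)
    val_cols <- setdiff(names(df), "gene_id")
  }
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene ids in ", path)
  vals <- as.matrix(df[val_cols])
  if (!is.numeric(vals)) stop("non-numeric expression cells in ", path)
  rownames(vals) <- df$gene_id
  expression_data(vals, ann, scale)
}

#' Write expression data (with annotation columns) to TSV
#'
#' Inverse of [read_expression()]: gene_id, chromosome, start, then one
#' column per sample.
#'
#' @param x an [expression_data()] object.
#' @param path output file.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "expression_data"))
  ann <- x$annotation[match(rownames(x$values), x$annotation$gene_id), ]
  df <- data.frame(gene_id = rownames(x$values),
                   chromosome = as.character(ann$chromosome),
                   start = ann$start,
                   x$values, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a sample sheet
#'
#' Columns: `sample_id`, `patient_id`, `compartment`
#' (intracranial/extracranial), `tissue`.
#'
#' @param path TSV file, or a data.frame already in memory.
#' @return A validated `data.frame` of class `sample_sheet`.
#' @export
read_sample_sheet <- function(path) {
  df <- if (is.data.frame(path)) path
        else read.delim(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "patient_id", "compartment")
  if (!all(needed %in% names(df)))
    stop("sample sheet needs columns: ", paste(needed, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in sample sheet")
  ok <- df$compartment %in% c("intracranial", "extracranial")
  if (!all(ok))
    stop("compartment must be intracranial or extracranial (bad: ",
         paste(unique(df$compartment[!ok]), collapse = ", "), ")")
  if (!"tissue" %in% names(df)) df$tissue <- NA_character_
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Construct all patient-matched intra/extracranial pairs
#'
#' Every combination of one intracranial and one extracranial sample within a
#' patient becomes a pair, so a patient with one brain sample and three
#' extracranial samples contributes three pairs. Patients lacking samples in
#' one compartment are skipped with a warning.
#'
#' @param sheet a [read_sample_sheet()] result (or data.frame with the same
#'   columns).
#' @return A `data.frame` of class `pair_set` with columns `pair_id`,
#'   `patient_id`, `intracranial`, `extracranial`.
#' @export
build_pairs <- function(sheet) {
  sheet <- read_sample_sheet(sheet)
  out <- list()
  for (pt in unique(sheet$patient_id)) {
    sub <- sheet[sheet$patient_id == pt, ]
    intra <- sub$sample_id[sub$compartment == "intracranial"]
    extra <- sub$sample_id[sub$compartment == "extracranial"]
    if (!length(intra) || !length(extra)) {
      warning("patient ", pt, " lacks samples in one compartment; skipped")
      next
    }
    grid <- expand.grid(intracranial = intra, extracranial = extra,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid <- grid[order(grid$intracranial, grid$extracranial), , drop = FALSE]
    grid$patient_id <- pt
    grid$pair_id <- sprintf("P%s_%s-%s", pt, grid$intracranial, grid$extracranial)
    out[[pt]] <- grid[c("pair_id", "patient_id", "intracranial", "extracranial")]
  }
  pairs <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(pairs))
    pairs <- data.frame(pair_id = character(), patient_id = character(),
                        intracranial = character(), extracranial = character())
  if (anyDuplicated(pairs$pair_id)) stop("pair ids are not unique")
  class(pairs) <- c("pair_set", "data.frame")
  pairs
}

#' Chromosomal gene ordering
#'
#' Sorts genes by chromosome (1..22, X, Y) then ascending start position;
#' the sort is stable, so ties retain their input order.
#'
#' @param annotation a [gene_annotation()].
#' @return Character vector of gene ids in chromosomal order.
#' @export
order_genes <- function(annotation) {
  ord <- order(as.integer(annotation$chromosome), annotation$start)
  annotation$gene_id[ord]
}

#' Sample sheet of the melanoma metastasis study cohort
#'
#' The published cohort composition: 16 patients, one intracranial (brain)
#' metastasis sample each, and 21 extracranial metastasis samples (four
#' patients contributed multiple histologically distinct extracranial
#' regions). Useful as a realistic pairing fixture and as the default
#' patient/pair layout of the cohort simulator.
#'
#' @return A `sample_sheet` data.frame with 37 rows.
#' @export
study_sample_sheet <- function() {
  extra <- list(
    P03 = c(lung = 1), P04 = c(skin = 2), P08 = c(`soft tissue` = 3),
    P13 = c(`lymph node` = 1), P16 = c(lung = 1), P18 = c(lung = 2),
    P39 = c(lung = 1), P42 = c(`lymph node` = 2), P74 = c(`lymph node` = 1),
    P77 = c(`lymph node` = 1), P78 = c(`small intestine` = 1),
    P101 = c(liver = 1), P106 = c(`lymph node` = 1), P107 = c(lung = 1),
    P108 = c(`lymph node` = 1), P111 = c(`lymph node` = 1)
  )
  rows <- list()
  for (pt in names(extra)) {
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = paste0(pt, "_brain"), patient_id = pt,
      compartment = "intracranial", tissue = "brain",
      stringsAsFactors = FALSE)
    tis <- names(extra[[pt]])
    n <- extra[[pt]][[1]]
    code <- c(lung = "Lu", `lymph node` = "Lym", skin = "Sk", liver = "Li",
              `small intestine` = "SI", `soft tissue` = "ST")[[tis]]
    suffix <- if (n > 1) paste0(code, seq_len(n)) else code
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = paste0(pt, "_", suffix), patient_id = pt,
      compartment = "extracranial", tissue = tis, stringsAsFactors = FALSE)
  }
  read_sample_sheet(do.call(rbind, rows))
}
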