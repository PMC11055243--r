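#' Low-expression gene filter on CPM
#'
#' Keeps a gene when its counts-per-million exceed `cpm_threshold` in
#' strictly more than `sample_fraction` of the samples (CPM > 1 in > 25% of
#' samples by default). CPM is count / library size * 1e6, so the filter is
#' invariant under per-sample rescaling of counts.
#'
#' @param counts an [expression_data()] on the counts scale.
#' @param cpm_threshold CPM cutoff (strict).
#' @param sample_fraction required fraction of samples above the cutoff
#'   (strict).
#' @return Character vector of retained gene ids (input row order).
#' @export
cpm_filter <- function(counts, cpm_threshold = 1, sample_fraction = 0.25) {
  stopifnot(inherits(counts, "expression_data"))
  if (counts$scale != "counts") stop("cpm_filter needs raw counts")
  if (cpm_threshold <= 0 || sample_fraction <= 0)
    stop("thresholds must be positive")
  lib <- colSums(counts$values)
  if (any(lib == 0))
    stop("zero library size for sample(s): ",
         paste(colnames(counts$values)[lib == 0], collapse = ", "))
  cpm <- edgeR::cpm(counts$values)
  frac <- rowMeans(cpm > cpm_threshold)
  rownames(counts$values)[frac > sample_fraction]
}

#' Normalize counts to log2-CPM, optionally with cyclic loess
#'
#' log2(CPM) with a pseudo-count of 0.5 added to the counts (avoids -Inf;
#' only near-zero counts are affected, and those are removed by
#' [cpm_filter()] anyway). With `loess = TRUE` a pairwise cyclic loess
#' normalization is applied to the log2-CPM columns, removing
#' intensity-dependent offsets between samples on MA coordinates.
#'
#' @param counts an [expression_data()] on the counts scale.
#' @param loess apply cyclic loess normalization.
#' @param span loess span.
#' @param iterations full cycles over all sample pairs.
#' @return An [expression_data()] on the log2cpm scale.
#' @export
normalize_log2cpm <- function(counts, loess = TRUE, span = 0.7, iterations = 3) {
  stopifnot(inherits(counts, "expression_data"))
  if (counts$scale != "counts") stop("normalize_log2cpm needs raw counts")
  if (loess && ncol(counts$values) < 2)
    stop("cyclic loess needs at least 2 samples")
  lib <- colSums(counts$values)
  if (any(lib == 0))
    stop("zero library size for sample(s): ",
         paste(colnames(counts$values)[lib == 0], collapse = ", "))
  lcpm <- edgeR::cpm(counts$values, log = TRUE, prior.count = 0.5)
  if (loess)
    lcpm <- limma::normalizeCyclicLoess(lcpm, span = span,
                                        iterations = iterations,
                                        method = "pairs")
  dimnames(lcpm) <- dimnames(counts$values)
  expression_data(lcpm, counts$annotation, "log2cpm")
}

#' Per-pair chromosome-ordered log2-ratio profiles
#'
#' For each patient-matched pair the profile is the per-gene difference
#' intracranial minus extracranial log2-CPM, with genes sorted in
#' chromosomal order and the per-chromosome index ranges recorded so that
#' each chromosome can be treated as its own sequence downstream.
#'
#' @param expr an [expression_data()] on the log2cpm scale.
#' @param pairs a [build_pairs()] result.
#' @param genes optional subset of gene ids to use (e.g. the
#'   [cpm_filter()] output); default all genes in `expr`.
#' @return A list of `pair_profile` objects, each with elements `pair_id`,
#'   `patient_id`, `gene_ids`, `ratios`, `chromosome` (factor per gene) and
#'   `breaks` (named list of index ranges per chromosome).
#' @export
compute_pair_profiles <- function(expr, pairs, genes = NULL) {
  stopifnot(inherits(expr, "expression_data"))
  if (expr$scale != "log2cpm")
    stop("pair profiles are differences of log2-CPM values; normalize first")
  if (is.null(genes)) genes <- rownames(expr$values)
  ann <- expr$annotation[match(genes, expr$annotation$gene_id), ]
  ord_ids <- order_genes(gene_annotation(ann$gene_id, as.character(ann$chromosome), ann$start))
  ann <- ann[match(ord_ids, ann$gene_id), ]
  missing <- setdiff(c(pairs$intracranial, pairs$extracranial), colnames(expr$values))
  if (length(missing))
    stop("pair sample(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  vals <- expr$values[ord_ids, , drop = FALSE]
  chrom <- droplevels(ann$chromosome)
  rle_len <- rle(as.character(chrom))$lengths
  ends <- cumsum(rle_len)
  starts <- c(1L, head(ends, -1L) + 1L)
  breaks <- Map(function(s, e) s:e, starts, ends)
  names(breaks) <- rle(as.character(chrom))$values
  lapply(seq_len(nrow(pairs)), function(i) {
    structure(list(
      pair_id = pairs$pair_id[i],
      patient_id = pairs$patient_id[i],
      gene_ids = ord_ids,
      ratios = unname(vals[, pairs$intracranial[i]] - vals[, pairs$extracranial[i]]),
      chromosome = chrom,
      breaks = breaks
    ), class = "pair_profile")
  })
}

#' @export
print.pair_profile <- function(x, ...) {
  cat(sprintf("pair_profile %s: %d genes on %d chromosomes\n",
              x$pair_id, length(x$ratios), length(x$breaks)))
  invisible(x)
}

#' Split a pair profile into per-chromosome ratio sequences
#'
#' @param profile a `pair_profile`.
#' @return Named list of numeric vectors, one per chromosome.
#' @export
profile_sequences <- function(profile) {
  lapply(profile$breaks, function(idx) profile$ratios[idx])
}
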