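#' Read gene sets from a GMT file
#'
#' Tab-separated: set id, description, then one gene per remaining field.
#'
#' @param path GMT file.
#' @return Named list of character vectors (names = set ids) with a
#'   `description` attribute per element.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line (need id, description, >=1 gene)")
    id <- f[1]
    if (id %in% names(out)) stop("duplicate pathway id: ", id)
    genes <- unique(f[-(1:2)])
    attr(genes, "description") <- f[2]
    out[[id]] <- genes
  }
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(id) {
    desc <- attr(sets[[id]], "description")
    if (is.null(desc)) desc <- id
    paste(c(id, desc, sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with monotonicity enforcement; q >= p always.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Fisher-exact pathway enrichment of one decoding
#'
#' For each pathway and each differential direction, tests the 2x2 table
#' (in pathway vs not) x (decoded in that direction vs not) over the gene
#' universe with a two-sided Fisher exact test. Pathway gene sets are
#' intersected with the universe first; pathways with no overlap are
#' omitted. FDR adjustment is applied within the decoding across all
#' pathway-direction tests.
#'
#' @param decoding a `state_decoding`.
#' @param pathways named list of gene-id vectors (see [read_gmt()]).
#' @param universe gene universe; defaults to the decoding's genes.
#' @param alternative "two.sided" (default) or "greater".
#' @return data.frame with columns `pair_id`, `pathway_id`, `direction`,
#'   `k`, `K`, `n`, `N`, `odds_ratio`, `p`, `q`.
#' @export
fisher_enrichment <- function(decoding, pathways,
                              universe = decoding$gene_ids,
                              alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  universe <- unique(universe)
  if (!length(universe)) stop("empty gene universe")
  N <- length(universe)
  st <- setNames(decoding$states, decoding$gene_ids)[universe]
  rows <- list()
  for (dir in c("-", "+")) {
    hits <- names(st)[st == dir]
    n <- length(hits)
    for (pid in names(pathways)) {
      pw <- intersect(pathways[[pid]], universe)
      K <- length(pw)
      if (K == 0) next
      k <- length(intersect(pw, hits))
      tab <- matrix(c(k, n - k, K - k, N - K - n + k), 2, 2)
      ft <- fisher.test(tab, alternative = alternative)
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = decoding$pair_id, pathway_id = pid, direction = dir,
        k = k, K = K, n = n, N = N,
        odds_ratio = unname(ft$estimate), p = ft$p.value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$q <- bh_adjust(out$p)
  out
}

#' Pathway enrichment across all pair decodings
#'
#' Runs [fisher_enrichment()] per pair (FDR within pair) and summarizes,
#' per pathway, in how many pairs it reached significance in either
#' direction.
#'
#' @param decodings list of `state_decoding`s.
#' @param pathways named list of gene sets.
#' @param universe gene universe.
#' @param alpha FDR threshold for calling a pathway significant in a pair.
#' @return List with `table` (all per-pair rows) and `n_significant_pairs`
#'   (named integer vector per pathway).
#' @export
enrich_cohort <- function(decodings, pathways, universe = NULL, alpha = 0.05) {
  tabs <- lapply(decodings, function(d)
    fisher_enrichment(d, pathways,
                      universe = if (is.null(universe)) d$gene_ids else universe))
  tab <- do.call(rbind, tabs)
  sig <- tab[tab$q < alpha, c("pair_id", "pathway_id")]
  sig <- unique(sig)
  counts <- table(factor(sig$pathway_id, levels = names(pathways)))
  list(table = tab,
       n_significant_pairs = setNames(as.integer(counts), names(counts)))
}
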