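#' Majority vote over one patient's pair decodings
#'
#' Counts "+" and "-" calls per gene across the patient's pairs. A strict
#' majority wins; equal nonzero counts give "excluded" (the gene carries no
#' vote for this patient); no differential call at all gives "=".
#'
#' @param decodings list of `state_decoding`s from the same patient, on an
#'   identical gene universe.
#' @return Character vector per gene in `{-, =, +, excluded}`, named by
#'   gene id.
#' @export
majority_vote <- function(decodings) {
  if (!length(decodings)) stop("no decodings supplied")
  genes <- decodings[[1]]$gene_ids
  for (d in decodings)
    if (!identical(d$gene_ids, genes)) stop("gene universes differ across decodings")
  mat <- vapply(decodings, function(d) d$states, character(length(genes)))
  if (is.null(dim(mat))) mat <- matrix(mat, ncol = length(decodings))
  n_up <- rowSums(mat == "+"); n_dn <- rowSums(mat == "-")
  out <- ifelse(n_up > n_dn, "+",
         ifelse(n_dn > n_up, "-",
         ifelse(n_up > 0, "excluded", "=")))
  names(out) <- genes
  out
}

#' Cross-patient consensus table
#'
#' Applies [majority_vote()] within each patient (patients with a single
#' pair keep that pair's states) and tallies, per gene, the number of
#' patients with consensus "-" (`n_down`) and "+" (`n_up`). The tie
#' fraction reported is the share of gene-by-patient votes that were
#' excluded among patients contributing multiple pairs.
#'
#' @param decodings list of `state_decoding`s (all pairs, all patients).
#' @return A list of class `consensus_table`: `states` (genes x patients
#'   character matrix), `n_down`, `n_up` (named integer vectors),
#'   `tie_fraction`, `patients`.
#' @export
patient_consensus <- function(decodings) {
  pts <- vapply(decodings, function(d) d$patient_id, character(1))
  genes <- decodings[[1]]$gene_ids
  by_pt <- split(decodings, pts)
  states <- vapply(by_pt, majority_vote, character(length(genes)))
  rownames(states) <- genes
  multi <- vapply(by_pt, length, integer(1)) > 1
  tie_fraction <- if (any(multi)) mean(states[, multi, drop = FALSE] == "excluded") else 0
  structure(list(
    states = states,
    n_down = setNames(rowSums(states == "-"), genes),
    n_up = setNames(rowSums(states == "+"), genes),
    tie_fraction = tie_fraction,
    patients = colnames(states)), class = "consensus_table")
}

#' @export
print.consensus_table <- function(x, ...) {
  cat(sprintf("consensus_table: %d genes x %d patients (tie fraction %.3f%%)\n",
              nrow(x$states), length(x$patients), 100 * x$tie_fraction))
  invisible(x)
}

#' Cross-patient gene rankings
#'
#' Two rankings: by decreasing number of patients with decreased expression
#' and by decreasing number with increased expression. Genes excluded by a
#' vote tie in any patient are not further considered and are dropped from
#' both rankings. Count ties are broken alphabetically by gene id, so the
#' ordering is deterministic.
#'
#' @param consensus a [patient_consensus()] result.
#' @return List with data.frames `down` and `up` (columns `gene_id`,
#'   `n_patients`).
#' @export
rank_genes <- function(consensus) {
  tied <- rownames(consensus$states)[rowSums(consensus$states == "excluded") > 0]
  keep <- setdiff(rownames(consensus$states), tied)
  mk <- function(counts) {
    counts <- counts[keep]
    ord <- order(-counts, names(counts))
    data.frame(gene_id = names(counts)[ord],
               n_patients = unname(counts[ord]),
               stringsAsFactors = FALSE)
  }
  list(down = mk(consensus$n_down), up = mk(consensus$n_up))
}

#' Candidate gene sets at a patient-recurrence threshold
#'
#' @param rankings a [rank_genes()] result.
#' @param min_patients minimal number of patients with the same direction.
#' @return List with character vectors `down` and `up`.
#' @export
candidate_set <- function(rankings, min_patients) {
  if (min_patients < 1) stop("min_patients must be >= 1")
  list(down = rankings$down$gene_id[rankings$down$n_patients >= min_patients],
       up = rankings$up$gene_id[rankings$up$n_patients >= min_patients])
}

#' Mann-Whitney U test (exact enumeration or normal approximation)
#'
#' Two-sided rank-sum comparison. `method = "exact"` enumerates all
#' group-label assignments (feasible for small groups; handles ties because
#' the statistic is computed on mid-ranks of the pooled sample);
#' `method = "normal"` uses the Gaussian approximation with the standard
#' tie correction of the rank variance. `"auto"` enumerates when both
#' groups have at most 8 members.
#'
#' @param x,y numeric samples.
#' @param method "auto", "exact" or "normal".
#' @param correct continuity correction for the normal approximation.
#' @return List with `U` (statistic of the first sample) and `p`.
#' @export
mann_whitney_u <- function(x, y, method = c("auto", "exact", "normal"),
                           correct = TRUE) {
  method <- match.arg(method)
  m <- length(x); n <- length(y)
  if (!m || !n) stop("both groups must be non-empty")
  if (method == "auto") method <- if (m <= 8 && n <= 8) "exact" else "normal"
  r <- rank(c(x, y))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  if (method == "exact") {
    combs <- utils::combn(m + n, m)
    stat <- apply(combs, 2, function(idx) sum(r[idx])) - m * (m + 1) / 2
    mu <- m * n / 2
    p <- mean(abs(stat - mu) >= abs(U - mu) - 1e-12)
  } else {
    mu <- m * n / 2
    ties <- table(r)
    sigma2 <- m * n / 12 * ((m + n + 1) - sum(ties^3 - ties) / ((m + n) * (m + n - 1)))
    if (sigma2 == 0) return(list(U = U, p = 1))
    cc <- if (correct) 0.5 else 0
    z <- max(0, abs(U - mu) - cc) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-z)
  }
  list(U = U, p = min(1, p))
}

#' Pairwise overlap of decoded states across all pairs
#'
#' For every unordered pair of pair-decodings, the overlap is the percentage
#' of genes assigned an identical state (over all three states and the
#' whole gene universe). Comparisons are labeled same_patient or
#' different_patient and the two groups are compared by a two-sided
#' Mann-Whitney U test.
#'
#' @param decodings list of `state_decoding`s (>= 2).
#' @param method passed to [mann_whitney_u()].
#' @return A list of class `overlap_result`: `comparisons` (data.frame with
#'   `pair_a`, `pair_b`, `overlap`, `group`), `median_same`,
#'   `median_different`, `U`, `p`.
#' @export
pairwise_overlap <- function(decodings, method = "auto") {
  if (length(decodings) < 2) stop("need at least two decodings")
  genes <- decodings[[1]]$gene_ids
  for (d in decodings)
    if (!identical(d$gene_ids, genes)) stop("gene universes differ across decodings")
  ids <- vapply(decodings, function(d) d$pair_id, character(1))
  pts <- vapply(decodings, function(d) d$patient_id, character(1))
  cmb <- utils::combn(length(decodings), 2)
  comparisons <- data.frame(
    pair_a = ids[cmb[1, ]], pair_b = ids[cmb[2, ]],
    overlap = apply(cmb, 2, function(ij)
      100 * mean(decodings[[ij[1]]]$states == decodings[[ij[2]]]$states)),
    group = ifelse(pts[cmb[1, ]] == pts[cmb[2, ]],
                   "same_patient", "different_patient"),
    stringsAsFactors = FALSE)
  same <- comparisons$overlap[comparisons$group == "same_patient"]
  diff <- comparisons$overlap[comparisons$group == "different_patient"]
  test <- if (length(same) >= 2 && length(diff) >= 2) {
    mann_whitney_u(same, diff, method = method)
  } else {
    warning("fewer than 2 comparisons in one group; Mann-Whitney test skipped")
    list(U = NA_real_, p = NA_real_)
  }
  structure(list(comparisons = comparisons,
                 median_same = if (length(same)) median(same) else NA_real_,
                 median_different = if (length(diff)) median(diff) else NA_real_,
                 U = test$U, p = test$p), class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(paste0("overlap_result: median same-patient %.1f%% vs ",
                     "different-patient %.1f%% (Mann-Whitney p = %.3g)\n"),
              x$median_same, x$median_different, x$p))
  invisible(x)
}

#' Compare a candidate gene set with an external gene list
#'
#' Overlap fraction relative to the own set, plus a two-sided Fisher exact
#' test of membership association over a common gene universe.
#'
#' @param own,external character vectors of gene ids, subsets of `universe`.
#' @param universe character vector of all genes considered.
#' @return List with `overlap_fraction`, `n_overlap`, `p`, `odds_ratio`.
#' @export
compare_candidate_sets <- function(own, external, universe) {
  if (!length(universe)) stop("empty gene universe")
  own <- unique(own); external <- unique(external); universe <- unique(universe)
  if (length(setdiff(own, universe)) || length(setdiff(external, universe)))
    stop("candidate sets must be subsets of the universe")
  k <- length(intersect(own, external))
  tab <- matrix(c(k, length(own) - k,
                  length(external) - k,
                  length(universe) - length(own) - length(external) + k), 2, 2)
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(overlap_fraction = if (length(own)) k / length(own) else NA_real_,
       n_overlap = k, p = ft$p.value, odds_ratio = unname(ft$estimate))
}
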