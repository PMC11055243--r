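#' Train the HMM on all pair profiles and decode each of them
#'
#' Convenience wrapper for the core loop of the analysis: one parameter set
#' is fitted to all profiles' chromosome sequences by MAP Baum-Welch, then
#' every profile is decoded by state posteriors.
#'
#' @param profiles list of `pair_profile`s.
#' @param init initial [hmm_parameters()].
#' @param priors [hmm_priors()].
#' @param tol,max_iter passed to [baum_welch_map()].
#' @return List with `fit` (an `hmm_fit`) and `decodings` (list of
#'   `state_decoding`s, one per profile).
#' @export
fit_and_decode <- function(profiles, init = default_hmm_parameters(),
                           priors = hmm_priors(init), tol = 1e-6,
                           max_iter = 500) {
  fit <- baum_welch_map(init, priors, profiles, tol = tol, max_iter = max_iter)
  decodings <- lapply(profiles, decode_states, params = fit$params)
  list(fit = fit, decodings = decodings)
}

#' Per-pair differential gene counts
#'
#' @param decodings list of `state_decoding`s.
#' @return data.frame with `pair_id`, `n_down`, `n_up`.
#' @export
differential_counts <- function(decodings) {
  data.frame(
    pair_id = vapply(decodings, function(d) d$pair_id, character(1)),
    n_down = vapply(decodings, function(d) sum(d$states == "-"), integer(1)),
    n_up = vapply(decodings, function(d) sum(d$states == "+"), integer(1)),
    stringsAsFactors = FALSE)
}

#' Write decoded states of all pairs to a TSV
#'
#' One row per gene, one column per pair with symbols "-", "=", "+".
#'
#' @param decodings list of `state_decoding`s on the same gene universe.
#' @param path output file.
#' @export
write_states <- function(decodings, path) {
  genes <- decodings[[1]]$gene_ids
  df <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (d in decodings) df[[d$pair_id]] <- d$states
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
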