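# Shared fixtures and independent oracles, all built in code.

# tiny annotated expression set: n genes over the given chromosomes
toy_expression <- function(n_genes = 9, samples = c("s1", "s2"),
                           chromosomes = c("1", "2", "3"),
                           scale = "log2cpm", seed = 11) {
  set.seed(seed)
  ann <- gene_annotation(
    gene_id = sprintf("g%03d", seq_len(n_genes)),
    chromosome = rep(chromosomes, length.out = n_genes),
    start = rep(seq_len(ceiling(n_genes / length(chromosomes))) * 100,
                each = length(chromosomes))[seq_len(n_genes)]
  )
  vals <- matrix(round(rnorm(n_genes * length(samples), 5, 2), 3),
                 n_genes, length(samples),
                 dimnames = list(ann$gene_id, samples))
  if (scale == "counts") vals <- abs(round(vals * 10))
  expression_data(vals, ann, scale)
}

toy_sheet <- function(patients) {
  # patients: named integer vector of extracranial sample counts
  rows <- lapply(names(patients), function(pt) {
    rbind(
      data.frame(sample_id = paste0(pt, "_i"), patient_id = pt,
                 compartment = "intracranial", tissue = "brain",
                 stringsAsFactors = FALSE),
      data.frame(sample_id = sprintf("%s_e%d", pt, seq_len(patients[[pt]])),
                 patient_id = pt, compartment = "extracranial",
                 tissue = "lung", stringsAsFactors = FALSE))
  })
  read_sample_sheet(do.call(rbind, rows))
}

# a pair_profile built directly from a ratio vector
make_profile <- function(ratios, chrom_lengths = NULL, pair_id = "p1",
                         patient_id = "pt1") {
  if (is.null(chrom_lengths))
    chrom_lengths <- setNames(length(ratios), "1")
  ends <- cumsum(chrom_lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  breaks <- Map(function(a, b) a:b, starts, ends)
  names(breaks) <- names(chrom_lengths)
  structure(list(pair_id = pair_id, patient_id = patient_id,
                 gene_ids = sprintf("g%05d", seq_along(ratios)),
                 ratios = as.numeric(ratios),
                 chromosome = factor(rep(names(chrom_lengths), chrom_lengths),
                                     levels = names(chrom_lengths)),
                 breaks = breaks),
            class = "pair_profile")
}

# a state_decoding built directly from a state vector
make_decoding <- function(states, pair_id = "p1", patient_id = "pt1",
                          gene_ids = NULL) {
  if (is.null(gene_ids)) gene_ids <- sprintf("g%05d", seq_along(states))
  structure(list(pair_id = pair_id, patient_id = patient_id,
                 gene_ids = gene_ids, states = states,
                 gamma = NULL, loglik = NA_real_),
            class = "state_decoding")
}

# Exhaustive path-sum oracle for a 3-state Gaussian HMM: likelihood and
# per-position posteriors by summing over all 3^T state paths.
enum_hmm_oracle <- function(params, x) {
  T <- length(x)
  paths <- as.matrix(expand.grid(rep(list(1:3), T)))
  lik <- apply(paths, 1, function(s) {
    w <- params$start[s[1]] * prod(dnorm(x[1], params$means[s[1]], params$sds[s[1]]))
    if (T > 1) for (t in 2:T)
      w <- w * params$trans[s[t - 1], s[t]] *
        dnorm(x[t], params$means[s[t]], params$sds[s[t]])
    w
  })
  total <- sum(lik)
  gamma <- sapply(1:3, function(i)
    vapply(1:T, function(t) sum(lik[paths[, t] == i]) / total, numeric(1)))
  if (T == 1) gamma <- matrix(gamma, 1, 3)
  list(loglik = log(total), gamma = gamma)
}

# Two-sided Fisher p by hypergeometric point-probability enumeration for the
# 2x2 table with margins (K, N - K) x (n, N - n) and observed overlap k.
hyper_fisher_oracle <- function(k, K, n, N) {
  support <- max(0, n + K - N):min(n, K)
  pr <- dhyper(support, K, N - K, n)
  sum(pr[pr <= pr[support == k] * (1 + 1e-7)])
}

# Hand computation of the two-group log-rank statistic: observed minus
# expected deaths in group 1 with the hypergeometric variance at each
# distinct event time.
logrank_oracle <- function(time1, event1, time2, event2) {
  df <- data.frame(time = c(time1, time2), event = c(event1, event2),
                   g1 = rep(c(1, 0), c(length(time1), length(time2))))
  o_minus_e <- 0; v <- 0
  for (tt in sort(unique(df$time[df$event == 1]))) {
    at_risk <- df$time >= tt
    n <- sum(at_risk); n1 <- sum(at_risk & df$g1 == 1)
    d <- sum(df$time == tt & df$event == 1)
    d1 <- sum(df$time == tt & df$event == 1 & df$g1 == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- o_minus_e^2 / v
  list(statistic = stat, p = pchisq(stat, 1, lower.tail = FALSE))
}
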