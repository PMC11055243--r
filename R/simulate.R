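#' Generative HMM truth with prescribed state frequencies
#'
#' Transition rows are `self * I + (1 - self) * start`, a lazy chain whose
#' stationary distribution is exactly `start`; simulated profiles then carry
#' the prescribed long-run fractions of decreased/unchanged/increased genes
#' (0.1 / 0.8 / 0.1 by default) in diagonal-dominant runs.
#'
#' @param self self-transition weight in \[0, 1).
#' @param start stationary state frequencies.
#' @param means,sds emission parameters.
#' @return An [hmm_parameters()] object.
#' @export
generator_hmm_parameters <- function(self = 0.9, start = c(0.1, 0.8, 0.1),
                                     means = c(-3, 0, 3), sds = c(0.5, 1, 0.5)) {
  trans <- self * diag(3) + (1 - self) * matrix(start, 3, 3, byrow = TRUE)
  hmm_parameters(start, trans, means, sds)
}

#' Default simulation configuration
#'
#' Desk-scale synthetic cohort mirroring the matched-pair study design:
#' 16 patients with the published pair multiplicities (21 pairs in total),
#' 3,000 genes over 5 pseudo-chromosomes of 600 genes, true HMM equal to
#' the default initial parameterization with self-transition 0.9
#' (diagonal-dominant, the positional persistence the model assumes),
#' within-patient state agreement rho = 0.9, and extracranial baseline
#' expression N(6, 2^2) log2-CPM. Ten pathways of 50 genes are drawn at
#' random; the first is planted with enrichment odds 5 toward "-" and the
#' second with odds 5 toward "+".
#'
#' @param n_genes total gene count (split evenly over `n_chromosomes`).
#' @param n_chromosomes number of pseudo-chromosomes.
#' @param patients named integer vector: pairs per patient.
#' @param params true [hmm_parameters()].
#' @param rho within-patient state agreement in \[0, 1\].
#' @param n_pathways,pathway_size random pathway collection dimensions.
#' @param planted list of `list(pathway, direction, odds)` entries.
#' @param baseline_mean,baseline_sd extracranial log2-CPM baseline.
#' @param seed RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 3000, n_chromosomes = 5,
                       patients = c(P03 = 1, P04 = 2, P08 = 3, P13 = 1,
                                    P16 = 1, P18 = 2, P39 = 1, P42 = 2,
                                    P74 = 1, P77 = 1, P78 = 1, P101 = 1,
                                    P106 = 1, P107 = 1, P108 = 1, P111 = 1),
                       params = NULL, rho = 0.9,
                       n_pathways = 10, pathway_size = 50,
                       planted = list(list(pathway = "pw01", direction = "-", odds = 5),
                                      list(pathway = "pw02", direction = "+", odds = 5)),
                       baseline_mean = 6, baseline_sd = 2, seed = 1) {
  if (is.null(params)) params <- generator_hmm_parameters(self = 0.9)
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]")
  if (n_genes %% n_chromosomes != 0)
    stop("n_genes must be divisible by n_chromosomes")
  chrom_lengths <- setNames(rep(n_genes %/% n_chromosomes, n_chromosomes),
                            as.character(seq_len(n_chromosomes)))
  structure(list(n_genes = n_genes, chrom_lengths = chrom_lengths,
                 patients = patients, params = params, rho = rho,
                 n_pathways = n_pathways, pathway_size = pathway_size,
                 planted = planted, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, seed = seed),
            class = "sim_config")
}

# Gene annotation for simulated cohorts: evenly spaced genes along
# pseudo-chromosomes, already in chromosomal order.
.sim_annotation <- function(chrom_lengths) {
  gene_annotation(
    gene_id = sprintf("g%05d", seq_len(sum(chrom_lengths))),
    chromosome = rep(names(chrom_lengths), chrom_lengths),
    start = unlist(lapply(chrom_lengths, function(n) seq_len(n) * 1000), use.names = FALSE)
  )
}

# One latent state path: Markov chain per chromosome, states coded 1:3.
.sim_states <- function(params, chrom_lengths) {
  unlist(lapply(chrom_lengths, function(len) {
    s <- integer(len)
    s[1] <- sample.int(3, 1, prob = params$start)
    for (t in seq_len(len - 1))
      s[t + 1] <- sample.int(3, 1, prob = params$trans[s[t], ])
    s
  }), use.names = FALSE)
}

#' Simulate one log2-ratio pair profile from the HMM
#'
#' Per chromosome: initial state from the start distribution, Markov
#' transitions, Gaussian emissions.
#'
#' @param params true [hmm_parameters()].
#' @param chrom_lengths named integer vector (chromosome label -> gene
#'   count).
#' @param seed RNG seed (NULL leaves the RNG state alone).
#' @param pair_id,patient_id labels for the returned profile.
#' @return List with `profile` (a `pair_profile`) and `states` (true state
#'   labels per gene).
#' @export
simulate_hmm_profile <- function(params, chrom_lengths, seed = NULL,
                                 pair_id = "sim", patient_id = "sim") {
  stopifnot(inherits(params, "hmm_parameters"))
  if (!is.null(seed)) set.seed(seed)
  ann <- .sim_annotation(chrom_lengths)
  s <- .sim_states(params, chrom_lengths)
  x <- rnorm(length(s), params$means[s], params$sds[s])
  ends <- cumsum(chrom_lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  breaks <- Map(function(a, b) a:b, starts, ends)
  names(breaks) <- names(chrom_lengths)
  profile <- structure(list(
    pair_id = pair_id, patient_id = patient_id,
    gene_ids = ann$gene_id, ratios = x,
    chromosome = factor(rep(names(chrom_lengths), chrom_lengths),
                        levels = names(chrom_lengths)),
    breaks = breaks), class = "pair_profile")
  list(profile = profile, states = STATE_LABELS[s])
}

#' Simulate a full matched-pair cohort
#'
#' Each patient carries a shared latent state vector drawn from the true
#' HMM; every pair of that patient copies it, resampling each gene's state
#' independently with probability 1 - rho from the start distribution, so
#' rho tunes the same-patient state agreement. Pathway effects are planted
#' by biasing the latent state of member genes toward the planted direction
#' with the probability that yields the configured enrichment odds ratio.
#' Extracranial baseline expression is drawn per gene and patient; the
#' intracranial column is shared within a patient and each pair's
#' extracranial column is baseline such that intra - extra reproduces the
#' pair's simulated ratios exactly.
#'
#' @param config a [sim_config()].
#' @return List with `expr` ([expression_data()], log2cpm), `sheet`
#'   (sample sheet), `pairs` ([build_pairs()] result), `annotation`,
#'   `pathways` (named list of gene sets), `true_states` (genes x pairs
#'   character matrix), `latent_states` (genes x patients), `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  params <- config$params
  ann <- .sim_annotation(config$chrom_lengths)
  genes <- ann$gene_id
  n <- length(genes)

  # random pathway collection; planted sets are biased below
  pathways <- lapply(seq_len(config$n_pathways), function(i)
    sample(genes, config$pathway_size))
  names(pathways) <- sprintf("pw%02d", seq_len(config$n_pathways))

  force_prob <- function(odds, p0) {
    q <- odds * p0 / (1 - p0 + odds * p0)  # target in-pathway state frequency
    (q - p0) / (1 - p0)
  }

  sheets <- list(); ratios <- list(); true_states <- list()
  latent <- matrix(NA_character_, n, length(config$patients),
                   dimnames = list(genes, names(config$patients)))
  for (pt in names(config$patients)) {
    z <- .sim_states(params, config$chrom_lengths)
    chrom_end <- rep(cumsum(config$chrom_lengths), config$chrom_lengths)
    for (pl in config$planted) {
      dir_idx <- match(pl$direction, STATE_LABELS)
      p0 <- params$start[dir_idx]
      pf <- force_prob(pl$odds, p0)
      members <- which(genes %in% pathways[[pl$pathway]])
      # plant segmental runs (the chain's own run-length law) seeded at
      # pathway member genes, so the effect carries the positional
      # persistence a posterior decoder relies on
      seeds <- members[runif(length(members)) < pf]
      for (s in seeds) {
        len <- 1L + rgeom(1, 1 - params$trans[dir_idx, dir_idx])
        z[s:min(s + len - 1L, chrom_end[s])] <- dir_idx
      }
    }
    latent[, pt] <- STATE_LABELS[z]
    n_pairs <- config$patients[[pt]]
    intra_id <- paste0(pt, "_intra")
    sheets[[length(sheets) + 1L]] <- data.frame(
      sample_id = intra_id, patient_id = pt,
      compartment = "intracranial", tissue = "brain", stringsAsFactors = FALSE)
    for (j in seq_len(n_pairs)) {
      zj <- z
      flip <- which(runif(n) < 1 - config$rho)
      if (length(flip))
        zj[flip] <- sample.int(3, length(flip), replace = TRUE,
                               prob = params$start)
      extra_id <- sprintf("%s_extra%d", pt, j)
      sheets[[length(sheets) + 1L]] <- data.frame(
        sample_id = extra_id, patient_id = pt,
        compartment = "extracranial", tissue = "simulated",
        stringsAsFactors = FALSE)
      pair_id <- sprintf("P%s_%s-%s", pt, intra_id, extra_id)
      ratios[[pair_id]] <- list(extra = extra_id, intra = intra_id,
                                x = rnorm(n, params$means[zj], params$sds[zj]))
      true_states[[pair_id]] <- STATE_LABELS[zj]
    }
  }
  sheet <- read_sample_sheet(do.call(rbind, sheets))
  pairs <- build_pairs(sheet)

  vals <- matrix(NA_real_, n, nrow(sheet),
                 dimnames = list(genes, sheet$sample_id))
  for (pt in names(config$patients)) {
    intra_id <- paste0(pt, "_intra")
    vals[, intra_id] <- rnorm(n, config$baseline_mean, config$baseline_sd)
  }
  for (pid in names(ratios))
    vals[, ratios[[pid]]$extra] <- vals[, ratios[[pid]]$intra] - ratios[[pid]]$x

  st_mat <- do.call(cbind, true_states[pairs$pair_id])
  dimnames(st_mat) <- list(genes, pairs$pair_id)

  list(expr = expression_data(vals, ann, "log2cpm"),
       sheet = sheet, pairs = pairs, annotation = ann,
       pathways = pathways, true_states = st_mat,
       latent_states = latent, config = config)
}

#' Simulate a survival cohort with expression-dependent hazard
#'
#' Event times are exponential with rate `baseline_hazard *
#' exp(sum(beta * expression))`; censoring times are independent
#' exponentials with rate `censor_rate`; the observed time is the minimum
#' and the event indicator marks death before censoring.
#'
#' @param genes character vector of gene ids to simulate.
#' @param beta named numeric log-hazard coefficients (genes absent from
#'   `beta` get 0).
#' @param n_patients cohort size.
#' @param baseline_hazard events per day at expression 0.
#' @param censor_rate censoring hazard.
#' @param expr_mean,expr_sd per-gene expression distribution.
#' @param seed RNG seed.
#' @return List with `surv` (data.frame `patient_id`, `time`, `event`) and
#'   `expr` (genes x patients matrix).
#' @export
simulate_survival <- function(genes, beta = numeric(0), n_patients = 300,
                              baseline_hazard = 1 / 1000, censor_rate = 1 / 2000,
                              expr_mean = 0, expr_sd = 1, seed = 1) {
  if (any(!is.finite(beta))) stop("coefficients must be finite")
  set.seed(seed)
  ids <- sprintf("pt%04d", seq_len(n_patients))
  expr <- matrix(rnorm(length(genes) * n_patients, expr_mean, expr_sd),
                 length(genes), n_patients, dimnames = list(genes, ids))
  b <- setNames(numeric(length(genes)), genes)
  b[names(beta)] <- beta
  rate <- baseline_hazard * exp(as.vector(crossprod(expr, b)))
  t_event <- rexp(n_patients, rate)
  t_cens <- rexp(n_patients, censor_rate)
  list(surv = data.frame(patient_id = ids,
                         time = pmin(t_event, t_cens),
                         event = as.integer(t_event <= t_cens),
                         stringsAsFactors = FALSE),
       expr = expr)
}
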