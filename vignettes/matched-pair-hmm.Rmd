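---
title: "Personalized matched-pair differential expression with a three-state Gaussian HMM"
author: "matchedHMM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized matched-pair differential expression with a three-state Gaussian HMM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matchedHMM)
```

## The problem

Bulk transcriptomes of tumor samples are highly patient-specific: two
metastases from the same patient resemble each other far more than they
resemble metastases from other patients growing in the same organ. A
cohort-level two-group comparison of, say, intracranial versus extracranial
melanoma metastases therefore mixes patient effects into the compartment
effect. `matchedHMM` instead analyzes each *patient-matched pair* — one
intracranial and one extracranial sample from the same patient — on its own,
and only afterwards integrates the per-pair calls across the cohort.

The personalized unit of analysis is the pair's **log2-ratio profile**

$$x_t \;=\; \log_2\!\mathrm{CPM}^{\text{intra}}_t \;-\;
           \log_2\!\mathrm{CPM}^{\text{extra}}_t ,$$

one value per gene $t$, with genes sorted in chromosomal order (chromosomes
1..22, X, Y, then ascending start coordinate). Expression changes of
neighboring genes are positively correlated — largely because copy-number
segments and regional regulation shift whole chromosomal stretches — which
the package verifies directly via a gene-count-weighted, chromosome-wise
autocorrelation with a gene-permutation null (`weighted_acf()`,
`acf_permutation_null()`).

## The model

Each chromosome of each pair profile is modeled as an independent chain of a
first-order hidden Markov model with three states,

* `-` : decreased expression in the intracranial sample,
* `=` : unchanged expression,
* `+` : increased expression,

and state-specific Gaussian emission densities
$x_t \mid s_t = i \sim \mathcal N(\mu_i, \sigma_i^2)$. The initial
parameterization is $\mu = (-3, 0, 3)$, $\sigma = (0.5, 1, 0.5)$ and start
probabilities $\pi = (0.1, 0.8, 0.1)$ — wide, well-separated differential
states flanking a dominant unchanged state. The transition matrix is not
part of the published initialization; `default_hmm_parameters()` starts it
diagonal-dominant (self-transition 0.8, each row's remaining mass split
across the other two states proportionally to their start probabilities),
encoding the positional persistence the autocorrelation motivates. Any
diagonal-dominant initialization reaches the same mode in practice.

### Bayesian (MAP) Baum-Welch

One parameter set is trained on *all* pairs' chromosome sequences jointly
(`baum_welch_map()`). The E-step is the scaled forward-backward recursion
(`forward_backward()`, implemented in C++ and checked against exhaustive
$3^T$ path enumeration in the test suite). Start and transition updates are
the classical Baum-Welch ratios; the emission updates are
maximum-a-posteriori under a conjugate normal-inverse-chi-square-style
prior with centers $(m_i, s_i)$ (defaulting to the initial values) and
pseudo-counts $\kappa_i$ (`scale_means`) on the mean and $\nu_i$
(`shape_sds`) on the variance:

$$\mu_i \leftarrow \frac{\sum_t \gamma_t(i)\, x_t + \kappa_i m_i}
                        {\sum_t \gamma_t(i) + \kappa_i},
  \qquad
  \sigma_i^2 \leftarrow \frac{\sum_t \gamma_t(i) (x_t - \mu_i)^2
                              + \kappa_i (\mu_i - m_i)^2 + \nu_i s_i^2}
                             {\sum_t \gamma_t(i) + \nu_i}.$$

The $\kappa_i(\mu_i - m_i)^2$ term makes the pair of updates the *joint*
mode of the penalized objective (data log-likelihood plus log prior), which
is what guarantees the penalized log-likelihood is non-decreasing at every
EM iteration — a property the test suite asserts at $10^{-8}$ relative
tolerance. A variance update that omits this term is a valid generalized-EM
variant but loses the exact ascent guarantee; since the term vanishes as
$\mu_i \to m_i$ (which strong $\kappa_i$ enforce), the two forms are
numerically close in the regime the pipeline uses. Both contractual limits
hold exactly: $\kappa, \nu \to \infty$ pins the emissions to the prior
centers, and $\kappa = \nu = 0$ reproduces classical maximum-likelihood
Baum-Welch (cross-checked against an independent ML implementation).

The default hyperparameters are `scale_means = (2500, 1000, 2500)` and
`shape_sds = (5000, 10, 5000)`: the differential states are strongly
anchored at $\pm 3 \pm 0.5$ so they keep representing *clear* changes,
while the unchanged state's spread is left nearly free to absorb the bulk
of the ratio distribution. `hmm_grid_search()` reproduces the selection
procedure behind these values: every candidate setting is trained and
decoded, settings are ranked lexicographically by (fewest sign-inconsistent
genes, most differential genes), where a gene is sign-inconsistent when its
observed ratio is negative but decoded `+` or positive but decoded `-`
(ratios exactly 0 are never counted — their sign is undefined).

### Decoding

Genes are assigned by **state-posterior decoding** (`decode_states()`): the
state with maximal marginal posterior $\gamma_t(i)$, computed per
chromosome. Posterior ties are resolved toward `=`, trading a few missed
calls for fewer false differential calls. Viterbi decoding is deliberately
not offered; the downstream statistics consume marginal calls, not a single
best path.

## Downstream stages

* **Consensus** (`patient_consensus()`): patients contributing several
  pairs are collapsed by a per-gene majority vote over `+`/`-` calls;
  equal nonzero counts exclude the gene for that patient (the printed tie
  fraction is the share of such votes among multi-pair patients), and genes
  tied in any patient are dropped from both rankings. `rank_genes()` orders
  genes by the number of patients with consensus `-` (and separately `+`),
  ties broken alphabetically for determinism; `candidate_set()` thresholds
  at a chosen patient count.
* **Pair overlap** (`pairwise_overlap()`): for every two pair-decodings,
  the percentage of genes with an identical state over *all three states
  and the whole gene universe*; restricted-to-differential agreement would
  sit far below the ~80% magnitudes this statistic is meant to capture.
  Same-patient versus different-patient groups are compared with a
  two-sided Mann-Whitney U test — exact enumeration when both groups have
  at most 8 members, otherwise the normal approximation with tie and
  continuity corrections. The approximation's absolute agreement with the
  exact p is about 0.01–0.09 at such group sizes (worst over the statistic's
  support; best at 8 vs 8), which is inherent to the approximation, not to
  this implementation.
* **Enrichment** (`fisher_enrichment()`): per pair and per direction, a
  two-sided Fisher exact test of pathway membership against
  differential-in-direction over the analyzed gene universe (all genes
  surviving the CPM filter, not the whole genome), with Benjamini-Hochberg
  adjustment *within each pair* across all pathway-direction tests. The
  adjustment scope and sidedness are configurable because neither is
  uniquely standard; per-pair two-sided is the default.
* **Survival screen** (`survival_screen()`): per candidate gene, patients
  at or below the first quartile of that gene's expression versus patients
  at or above the third quartile (linear-interpolation type-7 quantiles;
  boundary ties included on the inclusive side; quartiles computed over the
  patients entering the screen), compared by a two-group log-rank test with
  the hypergeometric variance at tied event times, then BH adjustment
  across screened genes with significance at $q < 0.1$.

## Preprocessing choices

Counts are filtered by CPM strictly greater than 1 in strictly more than
25% of samples (`cpm_filter()`; the survival cohort uses an inclusive
"at least 50% of patients" variant, `survival_prefilter()`).
Normalization is log2-CPM with a pseudo-count of 0.5 — the pseudo-count
only matters for near-zero counts, which the filter removes — followed by
pairwise cyclic loess on MA coordinates (span 0.7, 3 cycles), delegated to
`limma::normalizeCyclicLoess()`. Pre-normalized log2-CPM matrices can
bypass normalization entirely (`scale = "log2cpm"`), which is how an
externally normalized expression table enters the pipeline.

Sex-chromosome genes are kept (X and Y are valid chromosome labels);
within-patient ratios cancel genotype, so no per-sex handling is imposed.
Mitochondrial contigs and scaffolds are rejected at load time.

## The synthetic-cohort generator

`simulate_cohort()` produces a full cohort with the statistical structure
the analysis assumes, so every stage runs without external data:

* **Design**: 16 patients with pair multiplicities (1, 2, 3, 1, 1, 2, 1, 2,
  1, 1, 1, 1, 1, 1, 1, 1) — 21 pairs, 37 samples, four multi-pair patients,
  matching the published cohort layout.
* **Truth**: 3,000 genes on 5 pseudo-chromosomes of 600;
  `generator_hmm_parameters()` uses the initial emission parameterization
  with transition rows $0.9\,I + 0.1\,\pi$, a lazy chain whose stationary
  law is exactly $\pi = (0.1, 0.8, 0.1)$ — the long-run state frequencies
  the start probabilities assert, realized in diagonal-dominant segmental
  runs. (The *training* initialization's transition rule would imply >50%
  differential genes if used generatively, which is why generator truth and
  training init differ.)
* **Within-patient agreement**: each patient draws one latent state vector;
  every pair copies it, resampling each gene's state from $\pi$ with
  probability $1 - \rho$ ($\rho = 0.9$). One knob reproduces the
  same-patient versus different-patient overlap contrast.
* **Planted pathways**: member genes seed forced segmental runs (the
  chain's own geometric run-length law) toward a chosen direction, with the
  seeding probability derived from a target enrichment odds ratio (default:
  one pathway at odds 5 toward `-`, one toward `+`). Planting isolated
  single-gene states would be invisible to a posterior decoder that
  correctly smooths over singletons; segmental planting is both decodable
  and biologically the mechanism the model assumes.
* **Expression**: per-patient intracranial baseline
  $\mathcal N(6, 2^2)$ log2-CPM; each pair's extracranial column is
  baseline minus the simulated ratios, so profile construction recovers the
  ratios exactly.
* **Survival** (`simulate_survival()`): exponential event times with hazard
  $\lambda \exp(\beta^\top \text{expr})$ and independent exponential
  censoring.

What the generator does **not** emulate: count-level sequencing noise
(negative-binomial libraries), gene-length effects, batch structure,
correlated baseline expression between patients, and cross-patient sharing
of differential genes beyond chance. Passing tests therefore demonstrate
correctness of the algorithms under the model's own assumptions, not
robustness to real-data violations of them.

## Numerical choices and degenerate inputs

* Forward-backward uses per-position scaling; the log-likelihood is the sum
  of log scaling constants. An observation in the far tail of *every* state
  raises an explicit underflow error rather than returning garbage.
* Convergence: relative change of the penalized log-likelihood below
  $10^{-6}$ (default), capped at 500 iterations with a warning.
* State labels are anchored by the ordered-means invariant
  $\mu_- < \mu_= < \mu_+$, asserted at construction and after every
  update; label switching is an error, never silently reordered.
* A state receiving zero responsibility with zero prior pseudo-counts is an
  error; with prior mass it falls back toward the prior.
* Length-1 sequences contribute no transition statistics; the affected
  rows keep their previous values while $\pi$ is still estimated.
* Permutation p-values use the add-one rule $(1 + \#\{null \ge obs\}) /
  (n_{perm} + 1)$ and a caller-supplied seed.

## Problem sizes used by the checks

The test suite and the acceptance script run at desk scale, chosen so the
full suite completes in well under five minutes on one core: path-sum
oracles at $T \le 6$; parameter recovery on 20 sequences of 700 genes;
the default 21-pair, 3,000-gene synthetic cohort for the end-to-end
consensus, overlap, enrichment and survival stages; 100–200 permutations
or replicates for calibration properties. Dataset-scale checks against the
original study's supplementary expression tables activate automatically
when those tables are placed under `inst/extdata/study/` (see
`tests/testthat/test-acceptance.R` for the expected file names); they are
journal supplements and cannot be redistributed here.

## Known limitations

* The exact conjugate-prior density of the originally referenced HMM
  implementation is not published; the two testable limits above are the
  contract this implementation satisfies, and hyperparameter values are
  transferable only in that sense.
* The three-state Gaussian emission model is a deliberate simplification;
  heavy-tailed ratio noise inflates the differential states' tails and is
  partly absorbed by the wide `=` state.
* Pathway enrichment treats genes as exchangeable; positional correlation
  (the very thing the HMM models) means Fisher p-values within a pair are
  anti-conservative for pathways whose genes cluster on the genome.
* The survival screen is a univariate quartile-contrast screen, not a
  proportional-hazards model; it is intended for candidate triage, not
  effect estimation.
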