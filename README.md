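# matchedHMM

Personalized differential-expression analysis of **patient-matched tumor
sample pairs** — built for cohorts where each patient contributes one
intracranial and one or more extracranial metastasis samples, and where
patient identity dominates any cohort-level group contrast.

Tumor transcriptomes are so patient-specific that comparing *groups* of
intracranial vs extracranial metastases largely measures patient effects.
`matchedHMM` instead forms, for every patient-matched pair, the per-gene
log2-ratio profile

```
x_t = log2CPM(intracranial)_t − log2CPM(extracranial)_t
```

with genes in chromosomal order (1..22, X, Y, ascending start), and decodes
each profile with a **three-state Gaussian hidden Markov model**: states
`-` (decreased), `=` (unchanged) and `+` (increased expression in the
intracranial sample), with emissions N(μ_i, σ_i²), initialized at
μ = (−3, 0, 3), σ = (0.5, 1, 0.5), π = (0.1, 0.8, 0.1). The HMM exploits
the positional correlation of expression changes along chromosomes (copy
-number-driven segmental runs), which the package can verify via a
weighted, chromosome-wise autocorrelation against a permutation null.

Training is **Bayesian (MAP) Baum-Welch** over all pairs' chromosome
sequences jointly: classical start/transition updates, conjugate MAP
emission updates with pseudo-counts `scale_means` (κ, on the means;
default 2500/1000/2500) and `shape_sds` (ν, on the variances; default
5000/10/5000) anchoring the differential states while leaving the unchanged
state nearly free. Genes are then assigned by state-posterior decoding
(argmax of γ_t, ties toward `=`). Downstream stages:

* per-patient **majority-vote consensus**, cross-patient gene **rankings**
  and recurrence-thresholded **candidate sets**;
* **pair-overlap** statistics (same-patient vs different-patient state
  agreement, Mann-Whitney U test);
* per-pair, per-direction **Fisher-exact pathway enrichment** with
  Benjamini-Hochberg FDR (GMT input);
* a quartile Kaplan-Meier **survival screen** (Q1 vs Q4 expression groups,
  log-rank test, BH across genes, q < 0.1);
* a **synthetic-cohort generator** reproducing the matched-pair design
  (16 patients, 21 pairs), the segmental HMM truth, tunable within-patient
  agreement, planted pathway effects and expression-dependent survival —
  so the whole pipeline runs and is tested without any external data.

## Worked example

```r
library(matchedHMM)

cohort   <- simulate_cohort(sim_config(seed = 7))
profiles <- compute_pair_profiles(cohort$expr, cohort$pairs)
run      <- fit_and_decode(profiles)      # MAP Baum-Welch + posterior decoding
run$fit
#> hmm_fit: 10 EM iterations (converged), penalized loglik -97125.0780
#> 3-state Gaussian HMM
#>   start: 0.0973 0.7520 0.1507
#>   means: -2.9986 0.0001 2.9937  sds: 0.5063 1.0394 0.5055
#>   transitions:
#>        -      =      +
#> - 0.8110 0.1587 0.0303
#> = 0.0301 0.9417 0.0282
#> + 0.0308 0.1469 0.8223

head(differential_counts(run$decodings), 3)
#>                     pair_id n_down n_up
#> 1 PP03_P03_intra-P03_extra1    429  562
#> 2 PP04_P04_intra-P04_extra1    479  436
#> 3 PP04_P04_intra-P04_extra2    483  427

cons <- patient_consensus(run$decodings)
cons
#> consensus_table: 3000 genes x 16 patients (tie fraction 0.308%)

pairwise_overlap(run$decodings, method = "normal")
#> overlap_result: median same-patient 93.2% vs different-patient 58.3%
#> (Mann-Whitney p = 3.07e-05)

enr <- enrich_cohort(run$decodings, cohort$pathways)
enr$n_significant_pairs[1:3]
#> pw01 pw02 pw03
#>   17   17    0
```

The fitted emissions sit on the generative truth (±3 / 0 with the planted
spreads); each pair calls a few hundred genes per direction; pairs from the
same patient agree on ~93% of gene states versus ~58% for pairs from
different patients (the generator draws cross-patient states
independently); and exactly the two pathways planted with enrichment odds 5
are flagged in 17 of 21 pairs each, the unplanted ones in none.

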