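#' Quartile expression groups for one gene
#'
#' Low group: patients with expression <= the first quartile; high group:
#' patients with expression >= the third quartile (linear-interpolation
#' quantiles, R type 7). Ties at a boundary are included on the inclusive
#' side; patients strictly between the quartiles are excluded.
#'
#' @param expr named numeric vector (names = patient ids).
#' @return List with character vectors `low` and `high`.
#' @export
quartile_groups <- function(expr) {
  if (length(expr) < 8) stop("need at least 8 patients for a quartile split")
  if (is.null(names(expr))) stop("expression vector must be named by patient id")
  if (max(expr) == min(expr)) stop("constant expression; quartile split undefined")
  q <- quantile(expr, c(0.25, 0.75), type = 7, names = FALSE)
  list(low = names(expr)[expr <= q[1]], high = names(expr)[expr >= q[2]])
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank chi-square with the hypergeometric variance
#' formula at tied event times (via [survival::survdiff()]); the p-value is
#' the chi-square upper tail. With zero events the test is undefined and
#' p = 1 is returned with a warning.
#'
#' @param low,high character vectors of patient ids.
#' @param surv data.frame with columns `patient_id`, `time`, `event`.
#' @return List with `statistic`, `p`, `n_low`, `n_high`, `n_events`.
#' @export
logrank_test <- function(low, high, surv) {
  if (!all(c("patient_id", "time", "event") %in% names(surv)))
    stop("survival table needs patient_id, time, event columns")
  if (any(surv$time < 0)) stop("negative survival times")
  if (anyDuplicated(surv$patient_id)) stop("duplicate patients in survival table")
  if (!length(low) || !length(high)) stop("both groups must be non-empty")
  if (length(intersect(low, high))) stop("groups must be disjoint")
  df <- surv[match(c(low, high), surv$patient_id), ]
  if (anyNA(df$time))
    stop("patients missing from survival table: ",
         paste(setdiff(c(low, high), surv$patient_id), collapse = ", "))
  df$group <- rep(c("low", "high"), c(length(low), length(high)))
  n_events <- sum(df$event)
  if (n_events == 0) {
    warning("no events in either group; log-rank undefined, p = 1")
    return(list(statistic = 0, p = 1, n_low = length(low),
                n_high = length(high), n_events = 0L))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  list(statistic = unname(sd$chisq),
       p = pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       n_low = length(low), n_high = length(high), n_events = n_events)
}

#' Expression pre-filter for a survival cohort
#'
#' Keeps genes with CPM above `cpm_threshold` in at least `min_fraction` of
#' the patients (inclusive threshold, as appropriate for a cohort-level
#' pre-filter).
#'
#' @param counts an [expression_data()] on the counts scale.
#' @param cpm_threshold CPM cutoff (strict per sample).
#' @param min_fraction required fraction of patients (inclusive).
#' @return Character vector of retained gene ids.
#' @export
survival_prefilter <- function(counts, cpm_threshold = 1, min_fraction = 0.5) {
  stopifnot(inherits(counts, "expression_data"))
  if (counts$scale != "counts") stop("survival_prefilter needs raw counts")
  cpm <- edgeR::cpm(counts$values)
  rownames(counts$values)[rowMeans(cpm > cpm_threshold) >= min_fraction]
}

#' Quartile Kaplan-Meier survival screen over candidate genes
#'
#' For each gene: quartile split of its expression across patients, log-rank
#' test between the low and high groups, then Benjamini-Hochberg adjustment
#' across all screened genes. Genes absent from the expression matrix are
#' skipped with a warning.
#'
#' @param expr genes x patients numeric matrix (log2-CPM), or an
#'   [expression_data()].
#' @param genes character vector of candidate gene ids.
#' @param surv data.frame with `patient_id`, `time`, `event`.
#' @param alpha_q FDR threshold for the `significant` flag.
#' @return data.frame with one row per screened gene: `gene_id`, `n_low`,
#'   `n_high`, `statistic`, `p`, `q`, `significant`.
#' @export
survival_screen <- function(expr, genes, surv, alpha_q = 0.1) {
  if (inherits(expr, "expression_data")) expr <- expr$values
  missing <- setdiff(genes, rownames(expr))
  if (length(missing)) {
    warning("gene(s) absent from expression matrix, skipped: ",
            paste(missing, collapse = ", "))
    genes <- setdiff(genes, missing)
  }
  common <- intersect(colnames(expr), surv$patient_id)
  if (length(common) < 8) stop("fewer than 8 patients with both expression and survival")
  rows <- lapply(genes, function(g) {
    grp <- quartile_groups(setNames(expr[g, common], common))
    lr <- logrank_test(grp$low, grp$high, surv)
    data.frame(gene_id = g, n_low = lr$n_low, n_high = lr$n_high,
               statistic = lr$statistic, p = lr$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < alpha_q
  out
}

#' Kaplan-Meier survival curve of one group
#'
#' Product-limit estimate, exported for plotting the screened groups.
#'
#' @param patients character vector of patient ids.
#' @param surv data.frame with `patient_id`, `time`, `event`.
#' @return data.frame with `time`, `n_risk`, `n_event`, `survival`.
#' @export
km_curve <- function(patients, surv) {
  df <- surv[match(patients, surv$patient_id), ]
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = df)
  data.frame(time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, survival = fit$surv)
}
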