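#' Histology vocabulary
#'
#' Histopathology outcomes are grouped into three classes: `benign`
#' (hyperplasia, thyroiditis, adenoma), `borderline` (NIFTP and WT-UMP,
#' the pre-malignant entities managed surgically), and `malignant`
#' (papillary carcinoma variants, follicular, Hurthle-cell and anaplastic
#' carcinoma). `"unresected"` marks nodules without histologic
#' verification.
#'
#' @param histology Character vector of histology subtype labels.
#' @return `histology_class()` returns `"benign"`, `"borderline"`,
#'   `"malignant"` or `"unresected"` per element.
#' @export
#' @examples
#' histology_class(c("NIFTP", "PTC_classic", "hyperplasia"))
histology_class <- function(histology) {
  cls <- rep(NA_character_, length(histology))
  cls[histology %in% .histology_levels$benign] <- "benign"
  cls[histology %in% .histology_levels$borderline] <- "borderline"
  cls[histology %in% .histology_levels$malignant] <- "malignant"
  cls[histology == "unresected"] <- "unresected"
  if (anyNA(cls))
    stop("unknown histology label(s): ",
         paste(unique(histology[is.na(cls)]), collapse = ", "), call. = FALSE)
  cls
}

.histology_levels <- list(
  benign = c("hyperplasia", "thyroiditis", "adenoma"),
  borderline = c("NIFTP", "WT_UMP"),
  malignant = c("PTC_classic", "PTC_classic_follicular", "PTC_follicular",
                "PTC_solid", "PTC_oncocytic", "follicular_carcinoma",
                "hurthle_carcinoma", "anaplastic_carcinoma")
)

#' @rdname histology_class
#' @export
histology_levels <- function() .histology_levels

# truth under a borderline policy: TRUE = disease-positive
.truth <- function(histology, policy) {
  cls <- histology_class(histology)
  if (any(cls == "unresected"))
    stop("unresected nodules have no histologic truth; subset to resected",
         call. = FALSE)
  if (policy == "as_malignant") cls %in% c("malignant", "borderline")
  else cls == "malignant"
}

#' Build a 2x2 confusion table from resected nodules
#'
#' Compares a classifier call against histopathologic truth. Histologic
#' borderline lesions (NIFTP, WT-UMP) are counted as disease-positive
#' under the default `as_malignant` policy — they are pre-malignant
#' entities managed surgically — or as disease-negative under
#' `as_benign`; the policy is an explicit parameter on every
#' truth-dependent computation because the two readings change every
#' downstream metric.
#'
#' @param records A nodule data frame; all rows must be resected with a
#'   known histology and a non-missing call in `call_field`.
#' @param call_field Name of the call column (`"rna_call"` or
#'   `"gc_call"`).
#' @param policy Borderline policy, `"as_malignant"` (default) or
#'   `"as_benign"`.
#' @return An object of class `"confusion_table"`: a list with integer
#'   fields `tp`, `fp`, `tn`, `fn` and the `policy` used.
#' @export
#' @examples
#' ct <- confusion_table(resected_cohort(), "rna_call")
#' ct
#' binary_metrics(ct)
confusion_table <- function(records, call_field = "gc_call",
                            policy = c("as_malignant", "as_benign")) {
  policy <- match.arg(policy)
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L)
    return(new_confusion_table(0L, 0L, 0L, 0L, policy))
  if (!call_field %in% names(records))
    stop("no column '", call_field, "' in records", call. = FALSE)
  if ("resected" %in% names(records) && !all(as.logical(records$resected)))
    stop("confusion_table() requires resected nodules only", call. = FALSE)
  call <- as.character(records[[call_field]])
  if (anyNA(call) || !all(call %in% c("positive", "negative")))
    stop("column '", call_field,
         "' must be 'positive'/'negative' with no missing values",
         call. = FALSE)
  truth <- .truth(records$histology, policy)
  pos <- call == "positive"
  new_confusion_table(sum(truth & pos), sum(!truth & pos),
                      sum(!truth & !pos), sum(truth & !pos), policy)
}

#' @rdname confusion_table
#' @param tp,fp,tn,fn Non-negative integer counts (for constructing a
#'   table directly from published counts).
#' @export
new_confusion_table <- function(tp, fp, tn, fn,
                                policy = c("as_malignant", "as_benign")) {
  policy <- match.arg(policy)
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers", call. = FALSE)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 tn = as.integer(tn), fn = as.integer(fn), policy = policy),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("2x2 confusion table (borderline %s), n = %d\n",
              x$policy, x$tp + x$fp + x$tn + x$fn))
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(call = c("positive", "negative"),
                              truth = c("disease", "no disease")))
  print(m)
  invisible(x)
}

#' Wilson score confidence interval for a proportion
#'
#' The Wilson interval inverts the normal approximation to the score test;
#' unlike the Wald interval it never escapes `[0, 1]`, is asymmetric near
#' the boundaries, and has close-to-nominal coverage at small n. It is
#' the default dialect for every proportion this package reports.
#' Vectorized over `k` and `n`.
#'
#' @param k Number of successes, `0 <= k <= n`.
#' @param n Number of trials, `> 0`.
#' @param level Confidence level (default 0.95).
#' @return A two-column matrix with columns `low`, `high`.
#' @export
#' @examples
#' wilson_ci(6, 15)
wilson_ci <- function(k, n, level = 0.95) {
  .check_kn(k, n, level)
  z <- stats::qnorm((1 + level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  low <- pmax(0, centre - half)
  high <- pmin(1, centre + half)
  # the bounds at k = 0 and k = n are exactly 0 and 1; do not let floating
  # point push them off the boundary
  low[k == 0] <- 0
  high[k == n] <- 1
  cbind(low = low, high = high)
}

#' Continuity-corrected Wald confidence interval
#'
#' The Wald interval with a 1/(2n) continuity correction,
#' `p +- (z * sqrt(p(1-p)/n) + 1/(2n))`, clipped to `[0, 1]`. Offered as
#' an alternative reporting dialect alongside [wilson_ci()]; some
#' published interval bounds for these metrics follow this dialect.
#' Vectorized over `k` and `n`.
#'
#' @inheritParams wilson_ci
#' @return A two-column matrix with columns `low`, `high`.
#' @export
#' @examples
#' wald_cc_ci(6, 15)  # 0.119 - 0.681
wald_cc_ci <- function(k, n, level = 0.95) {
  .check_kn(k, n, level)
  z <- stats::qnorm((1 + level) / 2)
  p <- k / n
  half <- z * sqrt(p * (1 - p) / n) + 1 / (2 * n)
  cbind(low = pmax(0, p - half), high = pmin(1, p + half))
}

.check_kn <- function(k, n, level) {
  if (any(n <= 0)) stop("'n' must be positive", call. = FALSE)
  if (any(k < 0) || any(k > n)) stop("need 0 <= k <= n", call. = FALSE)
  stopifnot(length(level) == 1L, level > 0, level < 1)
}

# one MetricEstimate row
.metric_row <- function(metric, k, n, ci_method, level, policy = NA_character_) {
  if (n == 0L)
    stop("metric '", metric, "' is undefined: zero denominator",
         call. = FALSE)
  ci <- switch(ci_method,
    wilson = wilson_ci(k, n, level),
    wald_cc = wald_cc_ci(k, n, level),
    none = cbind(low = NA_real_, high = NA_real_)
  )
  data.frame(metric = metric, numerator = as.integer(k),
             denominator = as.integer(n), point = k / n,
             ci_low = ci[1, "low"], ci_high = ci[1, "high"],
             ci_method = ci_method, level = level, policy = policy,
             stringsAsFactors = FALSE)
}

#' Diagnostic-performance metrics from a confusion table
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive and
#' negative predictive value, and accuracy, each with a confidence
#' interval in the requested dialect. A metric whose denominator is zero
#' raises an error naming the metric rather than returning `NaN`, so a
#' degenerate stratum cannot silently corrupt downstream comparisons.
#'
#' @param ct A [confusion_table()].
#' @param ci_method `"wilson"` (default), `"wald_cc"`, or `"none"`.
#' @param level Confidence level.
#' @param metrics Which metrics to compute.
#' @return A data frame, one row per metric, with columns `metric`,
#'   `numerator`, `denominator`, `point`, `ci_low`, `ci_high`,
#'   `ci_method`, `level`, `policy`.
#' @export
#' @examples
#' binary_metrics(new_confusion_table(40, 9, 6, 3))
binary_metrics <- function(ct, ci_method = c("wilson", "wald_cc", "none"),
                           level = 0.95,
                           metrics = c("sensitivity", "specificity",
                                       "ppv", "npv", "accuracy")) {
  stopifnot(inherits(ct, "confusion_table"))
  ci_method <- match.arg(ci_method)
  metrics <- match.arg(metrics, several.ok = TRUE)
  total <- ct$tp + ct$fp + ct$tn + ct$fn
  num <- c(sensitivity = ct$tp, specificity = ct$tn, ppv = ct$tp,
           npv = ct$tn, accuracy = ct$tp + ct$tn)
  den <- c(sensitivity = ct$tp + ct$fn, specificity = ct$tn + ct$fp,
           ppv = ct$tp + ct$fp, npv = ct$tn + ct$fn, accuracy = total)
  out <- do.call(rbind, lapply(metrics, function(m)
    .metric_row(m, num[[m]], den[[m]], ci_method, level, ct$policy)))
  rownames(out) <- NULL
  out
}

#' Risk of malignancy among resected nodules
#'
#' The ROM is the prevalence of disease-positive histology among resected
#' nodules: (borderline + malignant)/resected under the `as_malignant`
#' policy, malignant/resected under `as_benign`.
#'
#' @param records Resected nodules with known histology.
#' @inheritParams confusion_table
#' @inheritParams binary_metrics
#' @return A one-row metric data frame as in [binary_metrics()].
#' @export
#' @examples
#' rom(resected_cohort())  # 43/58 = 74.1%
rom <- function(records, policy = c("as_malignant", "as_benign"),
                ci_method = c("wilson", "wald_cc", "none"), level = 0.95) {
  policy <- match.arg(policy)
  ci_method <- match.arg(ci_method)
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L)
    stop("metric 'rom' is undefined: zero denominator", call. = FALSE)
  truth <- .truth(records$histology, policy)
  .metric_row("rom", sum(truth), length(truth), ci_method, level, policy)
}

#' Resection rates by molecular call
#'
#' Computes the fraction of nodules surgically resected within the
#' call-positive and call-negative strata of the full (resected +
#' unresected) cohort, and compares the two strata with a chi-squared
#' test. When clinical management ignores the molecular result the two
#' rates differ only by sampling noise.
#'
#' @param records Full cohort with a logical/0-1 `resected` column and a
#'   call column.
#' @param call_field Name of the call column.
#' @param correction Chi-squared continuity correction, see [chi2_2x2()].
#' @inheritParams binary_metrics
#' @return A list with `rates` (metric data frame, rows `positive` and
#'   `negative`) and `comparison` (a [chi2_2x2()] result).
#' @export
#' @examples
#' resection_rates(indeterminate_cohort(), "rna_call")
resection_rates <- function(records, call_field = "gc_call",
                            ci_method = c("wilson", "wald_cc", "none"),
                            level = 0.95, correction = c("none", "yates")) {
  ci_method <- match.arg(ci_method)
  correction <- match.arg(correction)
  stopifnot(is.data.frame(records))
  if (!call_field %in% names(records))
    stop("no column '", call_field, "' in records", call. = FALSE)
  call <- as.character(records[[call_field]])
  if (anyNA(call) || !all(call %in% c("positive", "negative")))
    stop("every record needs a 'positive'/'negative' call in '",
         call_field, "'", call. = FALSE)
  res <- as.logical(records$resected)
  strata <- lapply(c(positive = "positive", negative = "negative"),
                   function(s) {
    n <- sum(call == s)
    if (n == 0L)
      stop("resection rate undefined: no ", s, " calls", call. = FALSE)
    k <- sum(res[call == s])
    .metric_row("resection_rate", k, n, ci_method, level)
  })
  rates <- do.call(rbind, strata)
  rates <- cbind(stratum = c("positive", "negative"), rates)
  rownames(rates) <- NULL
  cmp <- chi2_2x2(rates$numerator[1], rates$denominator[1] - rates$numerator[1],
                  rates$numerator[2], rates$denominator[2] - rates$numerator[2],
                  correction = correction)
  list(rates = rates, comparison = cmp)
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Compares two proportions laid out as rows `(a, b)` and `(c, d)` of a
#' 2x2 contingency table, with the Pearson statistic (df = 1) or its
#' Yates continuity-corrected variant. The default is uncorrected, the
#' convention used for the cross-study performance comparisons this
#' package reproduces; pass `correction = "yates"` for small counts.
#'
#' @param a,b,c,d Non-negative integer cell counts, rows `(a, b)` /
#'   `(c, d)`.
#' @param correction `"none"` (default) or `"yates"`.
#' @return An object of class `"comparison_result"`: list with `table`,
#'   `chi2_stat`, `df`, `p_value`, `correction`.
#' @export
#' @examples
#' chi2_2x2(38, 7, 31, 18)  # chi2 ~ 5.39, p ~ 0.020
chi2_2x2 <- function(a, b, c, d, correction = c("none", "yates")) {
  correction <- match.arg(correction)
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  m <- matrix(as.integer(counts), 2, 2, byrow = TRUE)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected == 0))
    stop("chi-squared undefined: a margin of the 2x2 table is zero",
         call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(m, correct = correction == "yates"))
  structure(list(table = m, chi2_stat = unname(ht$statistic),
                 df = unname(ht$parameter), p_value = unname(ht$p.value),
                 correction = correction),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("chi-squared 2x2 (%s correction): X2 = %.4g, df = %d, p = %.4g\n",
              x$correction, x$chi2_stat, x$df, x$p_value))
  invisible(x)
}

#' Compare an observed proportion with a published one
#'
#' Convenience wrapper over [chi2_2x2()] taking two `(successes, total)`
#' pairs — e.g. this cohort's PPV numerator/denominator against a
#' published classifier's — and testing equality of the two proportions.
#'
#' @param k1,n1 Successes and total in the first group.
#' @param k2,n2 Successes and total in the second group.
#' @inheritParams chi2_2x2
#' @return A [chi2_2x2()] comparison result.
#' @export
#' @examples
#' compare_proportions(38, 45, 31, 49)  # PPV 84.4% vs 63.3%
compare_proportions <- function(k1, n1, k2, n2,
                                correction = c("none", "yates")) {
  chi2_2x2(k1, n1 - k1, k2, n2 - k2, correction = correction)
}

#' Mann-Whitney AUC
#'
#' The area under the ROC curve computed as the Mann-Whitney statistic:
#' the fraction of (disease-positive, disease-negative) pairs in which the
#' positive case scores higher, counting ties as one half. Implemented
#' via midranks, equivalent to full pair enumeration.
#'
#' @param scores Numeric scores.
#' @param labels Truth labels: logical, or coercible to logical via
#'   comparison with `positive_label`.
#' @param positive_label Value of `labels` marking disease-positive cases.
#' @return The AUC in `[0, 1]`.
#' @export
#' @examples
#' auc_mann_whitney(c(0.8, 0.3, 0.5, 0.2), c(TRUE, TRUE, FALSE, FALSE))
auc_mann_whitney <- function(scores, labels, positive_label = TRUE) {
  stopifnot(is.numeric(scores), length(scores) == length(labels))
  if (anyNA(scores) || anyNA(labels))
    stop("'scores' and 'labels' must not contain NA", call. = FALSE)
  pos <- if (is.logical(labels)) labels else labels == positive_label
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("AUC needs at least one positive and one negative label",
         call. = FALSE)
  r <- rank(scores)  # midranks handle ties as 0.5 wins
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Risk-tier summaries of an alteration profile
#'
#' Two headline fractions describing how molecular alterations stratify
#' histologic outcome in a resected cohort:
#'
#' 1. `high_risk_fraction` — the fraction of histologically malignant
#'    nodules carrying at least one high-risk alteration (BRAF V600E,
#'    TERT, or a gene fusion); each nodule is counted once however many
#'    high-risk events it carries.
#' 2. `ras_only_risk` — among nodules whose detected alterations are
#'    RAS-family mutations only (`ras_genes`, default NRAS/HRAS/KRAS),
#'    the fraction with malignant or borderline (NIFTP/WT-UMP)
#'    histology. BRAF K601E, although RAS-like in behaviour, is excluded
#'    from the denominator by default and reported separately in the
#'    literature; widen `ras_genes` to change that.
#'
#' @param records Resected nodules with `histology` and `alterations`
#'   columns.
#' @param tier_map Tier rules, see [assign_tier()].
#' @param ras_genes Gene symbols defining the "RAS alone" stratum.
#' @inheritParams binary_metrics
#' @return A metric data frame with rows `high_risk_fraction` and (when
#'   the stratum is non-empty) `ras_only_risk`.
#' @export
#' @examples
#' alteration_summaries(resected_cohort())
alteration_summaries <- function(records, tier_map = default_tier_map(),
                                 ras_genes = c("NRAS", "HRAS", "KRAS"),
                                 ci_method = c("wilson", "wald_cc", "none"),
                                 level = 0.95) {
  ci_method <- match.arg(ci_method)
  stopifnot(is.data.frame(records), "alterations" %in% names(records))
  cls <- histology_class(records$histology)
  alts <- lapply(as.character(records$alterations), parse_alterations)
  tiers <- lapply(alts, function(al)
    vapply(al, assign_tier, character(1), tier_map = tier_map))
  genes <- lapply(alts, function(al)
    vapply(al, function(a) a$gene, character(1)))

  has_high_risk <- vapply(tiers, function(t) any(t == "high_risk"), logical(1))
  malignant <- cls == "malignant"
  if (!any(malignant))
    stop("metric 'high_risk_fraction' is undefined: no malignant nodules",
         call. = FALSE)
  out <- .metric_row("high_risk_fraction", sum(has_high_risk & malignant),
                     sum(malignant), ci_method, level)

  ras_only <- vapply(genes, function(g)
    length(g) > 0L && all(g %in% ras_genes), logical(1))
  if (any(ras_only)) {
    at_risk <- cls %in% c("malignant", "borderline")
    out <- rbind(out, .metric_row("ras_only_risk", sum(ras_only & at_risk),
                                  sum(ras_only), ci_method, level))
  }
  rownames(out) <- NULL
  out
}
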