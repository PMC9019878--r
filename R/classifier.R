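#' Score a set of alterations
#'
#' Assigns each alteration its percentage value from the weight table
#' (after the common-variant filter has been applied, if desired). Order
#' is preserved; every alteration resolves to exactly one value.
#'
#' @param alterations A list of [alteration()] objects.
#' @param weights A [weight_table()].
#' @return A data frame with columns `alteration` (compact text form) and
#'   `value` (percent).
#' @export
#' @examples
#' score_alterations(parse_alterations("BRAF:V600E;NRAS"))
score_alterations <- function(alterations, weights = default_weight_table()) {
  if (length(alterations) == 0L)
    return(data.frame(alteration = character(0), value = numeric(0)))
  data.frame(
    alteration = vapply(alterations, format_alteration, character(1)),
    value = vapply(alterations, lookup_weight, numeric(1), weights = weights),
    stringsAsFactors = FALSE
  )
}

#' Combine per-alteration values into a genomic-classifier score
#'
#' The genomic-classifier (GC) score aggregates the individual percentage
#' values of all detected alterations. Two combination rules are offered:
#'
#' * `"saturating_sum"` (default): the plain sum of the values, capped at
#'   100 so the score remains a percentage.
#' * `"noisy_or"`: `100 * (1 - prod(1 - v/100))`, the complement-product
#'   combination of independent evidence; it approaches 100 smoothly
#'   instead of clipping.
#'
#' Both rules agree on a single alteration and are permutation-invariant
#' and monotone under adding evidence. An empty value set scores 0.
#'
#' @param values Numeric vector of per-alteration percentages in
#'   `[0, 100]`.
#' @param rule Combination rule.
#' @return The score, a percentage in `[0, 100]`.
#' @export
#' @examples
#' gc_score(c(60, 50))                    # 100 (capped)
#' gc_score(c(60, 50), rule = "noisy_or") # 80
gc_score <- function(values, rule = c("saturating_sum", "noisy_or")) {
  rule <- match.arg(rule)
  if (length(values) == 0L) return(0)
  if (!is.numeric(values) || anyNA(values) ||
      any(values < 0) || any(values > 100))
    stop("per-alteration values must be percentages in [0, 100]",
         call. = FALSE)
  switch(rule,
    saturating_sum = min(100, sum(values)),
    noisy_or = 100 * (1 - prod(1 - values / 100))
  )
}

#' Dichotomize a classifier score
#'
#' A score strictly above the threshold is called `"positive"`; a score at
#' or below it is `"negative"` (the threshold itself is negative). The
#' conventional operating points are 70% for the genomic classifier and
#' 10% for the expression classifier.
#'
#' @param score Numeric score(s) in `[0, 100]`; vectorized.
#' @param threshold Positivity threshold in `[0, 100]`.
#' @return Character vector of `"positive"` / `"negative"`.
#' @export
#' @examples
#' classify(c(70, 70.01), threshold = 70)
classify <- function(score, threshold = 70) {
  stopifnot(is.numeric(score), is.numeric(threshold),
            length(threshold) == 1L, threshold >= 0, threshold <= 100)
  if (any(!is.na(score) & (score < 0 | score > 100)))
    stop("'score' must be in [0, 100]", call. = FALSE)
  ifelse(is.na(score), NA_character_,
         ifelse(score > threshold, "positive", "negative"))
}

#' Score and call every nodule in a table
#'
#' Applies the full interpretation layer to a nodule table: parses the
#' `alterations` column, filters common variants, looks up per-alteration
#' weights, combines them into a genomic-classifier score, and
#' dichotomizes both classifiers at their thresholds. The expression
#' (RNA) classifier score is taken from the `rna_score` column when
#' present (the upstream expression model is not part of this package);
#' existing `gc_score` columns are recomputed only when the table has an
#' `alterations` column.
#'
#' @param nodules A nodule data frame (see [read_nodule_table()]).
#' @param weights A [weight_table()].
#' @param gc_threshold,rna_threshold Positivity thresholds (percent).
#' @param rule Combination rule, see [gc_score()].
#' @param freq_threshold Common-variant frequency cutoff, see
#'   [filter_common_variants()].
#' @return The table with `gc_score`, `gc_call` and (when an `rna_score`
#'   column exists) `rna_call` columns filled in.
#' @export
score_nodules <- function(nodules, weights = default_weight_table(),
                          gc_threshold = 70, rna_threshold = 10,
                          rule = c("saturating_sum", "noisy_or"),
                          freq_threshold = 0.001) {
  rule <- match.arg(rule)
  stopifnot(is.data.frame(nodules))
  if ("alterations" %in% names(nodules)) {
    nodules$gc_score <- vapply(seq_len(nrow(nodules)), function(i) {
      alts <- parse_alterations(as.character(nodules$alterations[i]))
      alts <- filter_common_variants(alts, freq_threshold)
      gc_score(score_alterations(alts, weights)$value, rule = rule)
    }, numeric(1))
  }
  if ("gc_score" %in% names(nodules))
    nodules$gc_call <- classify(nodules$gc_score, gc_threshold)
  if ("rna_score" %in% names(nodules))
    nodules$rna_call <- classify(nodules$rna_score, rna_threshold)
  nodules
}
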