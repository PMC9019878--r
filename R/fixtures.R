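#' Published resected indeterminate-nodule cohort
#'
#' `resected_cohort()` returns a per-nodule table of 58 surgically
#' resected, cytologically indeterminate (Bethesda III/IV) thyroid
#' nodules from a published high-ROM cohort: 15 benign, 10 borderline
#' (3 NIFTP, 7 WT-UMP) and 33 malignant nodules, with each nodule's
#' expression-classifier (RNA) call, genomic-classifier (GC, DNA-RNA)
#' call and detected molecular alterations. The per-nodule rows are
#' reconstructed from the published histology-by-call-by-alteration group
#' totals, which they reproduce exactly; `nodule_id`, `patient_id`,
#' `bethesda` and `size_cm` are synthetic placeholders (the publication
#' reports only cohort-level margins for those), so any analysis
#' stratified on them is illustrative only. Assignment of alterations to
#' individual nodules within a histology group is likewise arbitrary
#' (one alteration per nodule as listed, except the anaplastic carcinoma
#' carrying both TERT and BRAF V600E); all shipped summaries depend only
#' on the group totals.
#'
#' `indeterminate_cohort()` extends it to the full 140-nodule molecular
#' testing cohort by adding 82 unresected records whose per-classifier
#' call margins match the published resection-rate analysis exactly
#' (RNA: 114 positive / 26 negative overall, 49 and 9 resected; GC: 106
#' positive / 34 negative, 46 and 12 resected). The joint RNA-by-GC call
#' assignment for unresected nodules is not published and is filled in
#' with the maximal-overlap assignment (60 positive on both, 5 RNA-only,
#' 17 negative on both); every published margin is preserved. Unresected
#' records carry `histology = "unresected"` and no alterations (all 26
#' published DNA mutations and fusions occur in resected nodules).
#'
#' @return A nodule data frame, see [read_nodule_table()] for columns.
#' @export
#' @examples
#' rom(resected_cohort())                       # 43/58
#' resection_rates(indeterminate_cohort(), "rna_call")$rates
resected_cohort <- function() {
  path <- system.file("extdata", "resected_nodules.tsv",
                      package = "thyrostrat", mustWork = TRUE)
  read_nodule_table(path)
}

#' @rdname resected_cohort
#' @export
indeterminate_cohort <- function() {
  res <- resected_cohort()
  joint <- rbind(
    data.frame(rna_call = "positive", gc_call = "positive", n = 60),
    data.frame(rna_call = "positive", gc_call = "negative", n = 5),
    data.frame(rna_call = "negative", gc_call = "negative", n = 17)
  )
  idx <- rep(seq_len(nrow(joint)), joint$n)
  n_un <- length(idx)
  unres <- data.frame(
    nodule_id = sprintf("U%04d", seq_len(n_un)),
    patient_id = sprintf("PU%04d", seq_len(n_un)),
    bethesda = rep(c("III", "III", "IV"), length.out = n_un),
    size_cm = rep(c(0.8, 1.2, 1.6, 0.9), length.out = n_un),
    histology = "unresected",
    resected = FALSE,
    alterations = NA_character_,
    rna_call = joint$rna_call[idx],
    gc_call = joint$gc_call[idx],
    stringsAsFactors = FALSE
  )
  rbind(res[names(unres)], unres)
}
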