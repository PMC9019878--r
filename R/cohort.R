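#' Configuration for a synthetic indeterminate-nodule cohort
#'
#' Describes the generative model behind [generate_cohort()]: cohort size,
#' Bethesda-category mix, the benign/borderline/malignant class mix with
#' histologic subtypes, class-conditional alteration frequencies,
#' class-conditional Beta score distributions for the expression (RNA)
#' and genomic (GC) classifiers, and per-call resection probabilities.
#'
#' The defaults emulate the structure of a published resected cohort of
#' 58 cytologically indeterminate nodules from a high-ROM setting:
#' 15 benign / 10 borderline / 33 malignant, a 62/38 Bethesda III/IV
#' split, alteration frequencies read off the published
#' histology-by-alteration listing, classifier operating points
#' sens 93.0% / spec 40.0% (RNA, threshold 10%) and
#' sens 88.4% / spec 53.3% (GC, threshold 70%), and resection
#' probabilities 0.43 (call-positive) vs 0.35 (call-negative) — the
#' "management ignores the molecular result" regime. Score distributions
#' are Beta laws calibrated with [calibrate_score_distributions()] so the
#' simulated cohort hits the configured operating points exactly in
#' expectation; borderline nodules are scored from the disease-positive
#' distribution by default (most published borderline nodules test
#' positive), configurable via `borderline_from`.
#'
#' Histologic truth is revealed only for resected nodules (`histology =
#' "unresected"` otherwise), reproducing the verification bias of real
#' diagnostic-accuracy cohorts; set `reveal_unresected = TRUE` to expose
#' the latent outcome for every nodule.
#'
#' @param n_nodules Number of nodules to simulate.
#' @param seed Integer seed fixing the cohort bit-for-bit.
#' @param bethesda_probs Named probabilities for categories `III`, `IV`.
#' @param class_probs Named probabilities for `benign`, `borderline`,
#'   `malignant`.
#' @param subtype_probs List of named probability vectors per class.
#' @param alteration_freqs List (per class) of named per-alteration
#'   Bernoulli frequencies; names are in the [parse_alteration()] grammar.
#'   `NULL` omits the alterations column.
#' @param rna,gc Operating points: lists with `target_sens`,
#'   `target_spec`, `threshold` (percent).
#' @param resection_probs Named resection probabilities for GC
#'   `positive` / `negative` calls.
#' @param borderline_from `"positive"` (default: borderline nodules score
#'   like disease-positive ones) or a list `list(rna = c(shape1, shape2),
#'   gc = c(shape1, shape2))` of explicit Beta parameters.
#' @param reveal_unresected Reveal latent histology for unresected
#'   nodules.
#' @param size_lognorm `c(meanlog, sdlog)` for nodule size in cm (default
#'   matches a median 1.0 cm, IQR 0.7-1.5 cohort).
#' @return A list of class `"cohort_config"`.
#' @export
#' @examples
#' cfg <- cohort_config(n_nodules = 100, seed = 1)
#' cohort <- generate_cohort(cfg)
#' table(histology_class(cohort$histology))
cohort_config <- function(n_nodules = 140,
                          seed = 1L,
                          bethesda_probs = c(III = 87 / 140, IV = 53 / 140),
                          class_probs = c(benign = 15 / 58,
                                          borderline = 10 / 58,
                                          malignant = 33 / 58),
                          subtype_probs = default_subtype_probs(),
                          alteration_freqs = default_alteration_freqs(),
                          rna = list(target_sens = 0.930, target_spec = 0.400,
                                     threshold = 10),
                          gc = list(target_sens = 0.884, target_spec = 0.533,
                                    threshold = 70),
                          resection_probs = c(positive = 0.43,
                                              negative = 0.35),
                          borderline_from = "positive",
                          reveal_unresected = FALSE,
                          size_lognorm = c(meanlog = 0, sdlog = 0.57)) {
  stopifnot(n_nodules >= 0, n_nodules == round(n_nodules))
  .check_probs(bethesda_probs, c("III", "IV"))
  .check_probs(class_probs, c("benign", "borderline", "malignant"))
  for (cls in names(class_probs)) {
    .check_probs(subtype_probs[[cls]], .histology_levels[[cls]],
                 subset_ok = TRUE)
  }
  if (!is.null(alteration_freqs)) {
    stopifnot(all(names(class_probs) %in% names(alteration_freqs)))
    for (f in alteration_freqs)
      if (length(f) && (any(f < 0) || any(f > 1)))
        stop("alteration frequencies must be in [0, 1]", call. = FALSE)
  }
  stopifnot(all(c("positive", "negative") %in% names(resection_probs)),
            all(resection_probs >= 0), all(resection_probs <= 1))
  structure(
    list(n_nodules = as.integer(n_nodules), seed = as.integer(seed),
         bethesda_probs = bethesda_probs, class_probs = class_probs,
         subtype_probs = subtype_probs,
         alteration_freqs = alteration_freqs,
         rna = rna, gc = gc, resection_probs = resection_probs,
         borderline_from = borderline_from,
         reveal_unresected = isTRUE(reveal_unresected),
         size_lognorm = size_lognorm),
    class = "cohort_config"
  )
}

.check_probs <- function(p, expected_names, subset_ok = FALSE) {
  lbl <- paste(expected_names, collapse = "/")
  if (is.null(names(p)) ||
      (!subset_ok && !setequal(names(p), expected_names)) ||
      (subset_ok && !all(names(p) %in% expected_names)))
    stop("probability vector must be named over {", lbl, "}", call. = FALSE)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("probabilities over {", lbl, "} must be non-negative and sum to 1",
         call. = FALSE)
}

#' @rdname cohort_config
#' @export
default_subtype_probs <- function() {
  list(
    benign = c(hyperplasia = 12 / 15, thyroiditis = 2 / 15, adenoma = 1 / 15),
    borderline = c(NIFTP = 3 / 10, WT_UMP = 7 / 10),
    malignant = c(PTC_classic = 9 / 33, PTC_classic_follicular = 3 / 33,
                  PTC_follicular = 15 / 33, PTC_solid = 1 / 33,
                  PTC_oncocytic = 1 / 33, follicular_carcinoma = 1 / 33,
                  hurthle_carcinoma = 2 / 33, anaplastic_carcinoma = 1 / 33)
  )
}

#' @rdname cohort_config
#' @export
default_alteration_freqs <- function() {
  list(
    benign = c("NRAS" = 1 / 15, "HRAS" = 1 / 15),
    borderline = c("BRAF:K601E" = 2 / 10, "NRAS" = 3 / 10),
    malignant = c("BRAF:V600E" = 5 / 33, "TERT" = 2 / 33, "KRAS" = 2 / 33,
                  "NRAS" = 3 / 33, "ETV6-NTRK3:fusion" = 4 / 33,
                  "CCDC6-RET:fusion" = 1 / 33, "NCOA4-RET:fusion" = 1 / 33,
                  "STRN-ALK:fusion" = 1 / 33)
  )
}

#' Calibrate Beta score distributions to an operating point
#'
#' Finds class-conditional Beta distributions for a classifier score
#' (expressed as a fraction of the 0-100 scale) such that the
#' disease-positive class exceeds the positivity threshold with
#' probability `target_sens` and the disease-negative class stays at or
#' below it with probability `target_spec`. One shape parameter is held
#' fixed (`fixed_shape`, default 2, giving unimodal, realistically
#' dispersed scores) and the other is solved numerically; the achieved
#' tail probabilities match the targets to within 1e-6.
#'
#' Targets of exactly 0 or 1 are infeasible for any Beta law (no Beta
#' places probability 1 strictly beyond an interior threshold) and raise
#' a calibration error.
#'
#' @param target_sens,target_spec Target operating point, in `(0, 1)`.
#' @param threshold Positivity threshold in percent (score > threshold is
#'   positive).
#' @param fixed_shape The Beta shape held fixed while the other is
#'   solved.
#' @return A list with elements `positive` and `negative`, each
#'   `c(shape1, shape2)`, plus `threshold`.
#' @export
#' @examples
#' cal <- calibrate_score_distributions(0.884, 0.533, threshold = 70)
#' 1 - pbeta(0.70, cal$positive[1], cal$positive[2])  # 0.884
calibrate_score_distributions <- function(target_sens, target_spec,
                                          threshold = 70, fixed_shape = 2) {
  for (t in c(target_sens, target_spec))
    if (!is.numeric(t) || length(t) != 1L || is.na(t) || t <= 0 || t >= 1)
      stop("calibration targets must lie strictly inside (0, 1)",
           call. = FALSE)
  stopifnot(threshold > 0, threshold < 100, fixed_shape > 0)
  thr <- threshold / 100
  # P(X > thr) increases monotonically in shape1 at fixed shape2
  a_pos <- stats::uniroot(
    function(a) 1 - stats::pbeta(thr, a, fixed_shape) - target_sens,
    interval = c(1e-9, 1e3), extendInt = "upX", tol = 1e-12
  )$root
  # P(X <= thr) increases monotonically in shape2 at fixed shape1
  b_neg <- stats::uniroot(
    function(b) stats::pbeta(thr, fixed_shape, b) - target_spec,
    interval = c(1e-9, 1e3), extendInt = "upX", tol = 1e-12
  )$root
  list(positive = c(shape1 = a_pos, shape2 = fixed_shape),
       negative = c(shape1 = fixed_shape, shape2 = b_neg),
       threshold = threshold)
}

#' Generate a synthetic indeterminate-nodule cohort
#'
#' Draws `n_nodules` nodule records from the generative model in a
#' [cohort_config()]: latent histologic class and subtype, Bethesda
#' category, size, molecular alterations (independent Bernoulli per
#' alteration given class), classifier scores (class-conditional Beta),
#' calls at the configured thresholds, and resection given the GC call.
#' The seed in the config fixes the output bit-for-bit; the function
#' seeds the global RNG stream.
#'
#' @param config A [cohort_config()].
#' @return A nodule data frame with columns `nodule_id`, `patient_id`,
#'   `bethesda`, `size_cm`, `histology`, `resected`, `alterations` (when
#'   configured), `rna_score`, `gc_score`, `rna_call`, `gc_call`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_nodules = 50, seed = 7))
#' head(cohort)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_nodules
  set.seed(config$seed)
  cls_names <- names(config$class_probs)
  cls <- sample(cls_names, n, replace = TRUE, prob = config$class_probs)
  subtype <- character(n)
  for (cl in cls_names) {
    idx <- which(cls == cl)
    if (length(idx))
      subtype[idx] <- sample(names(config$subtype_probs[[cl]]), length(idx),
                             replace = TRUE, prob = config$subtype_probs[[cl]])
  }
  bethesda <- sample(names(config$bethesda_probs), n, replace = TRUE,
                     prob = config$bethesda_probs)
  size_cm <- stats::rlnorm(n, config$size_lognorm[[1]],
                           config$size_lognorm[[2]])

  rna_cal <- calibrate_score_distributions(config$rna$target_sens,
                                           config$rna$target_spec,
                                           config$rna$threshold)
  gc_cal <- calibrate_score_distributions(config$gc$target_sens,
                                          config$gc$target_spec,
                                          config$gc$threshold)
  rna_score <- .draw_scores(cls, rna_cal, config$borderline_from, "rna")
  gc_score <- .draw_scores(cls, gc_cal, config$borderline_from, "gc")
  rna_call <- classify(rna_score, config$rna$threshold)
  gc_call <- classify(gc_score, config$gc$threshold)

  p_res <- unname(config$resection_probs[
    ifelse(gc_call == "positive", "positive", "negative")])
  resected <- stats::rbinom(n, 1L, p_res) == 1L

  out <- data.frame(
    nodule_id = sprintf("N%04d", seq_len(n)),
    patient_id = sprintf("P%04d", seq_len(n)),
    bethesda = bethesda, size_cm = round(size_cm, 2),
    histology = if (config$reveal_unresected) subtype
                else ifelse(resected, subtype, "unresected"),
    resected = resected,
    stringsAsFactors = FALSE
  )
  if (!is.null(config$alteration_freqs))
    out$alterations <- .draw_alterations(cls, config$alteration_freqs)
  out$rna_score <- round(rna_score, 4)
  out$gc_score <- round(gc_score, 4)
  out$rna_call <- rna_call
  out$gc_call <- gc_call
  out
}

# class-conditional Beta scores on the 0-100 scale
.draw_scores <- function(cls, cal, borderline_from, which_clf) {
  n <- length(cls)
  score <- numeric(n)
  for (cl in unique(cls)) {
    idx <- which(cls == cl)
    par <- if (cl == "benign") cal$negative
           else if (cl == "malignant") cal$positive
           else if (identical(borderline_from, "positive")) cal$positive
           else borderline_from[[which_clf]]
    score[idx] <- 100 * stats::rbeta(length(idx), par[[1]], par[[2]])
  }
  score
}

# independent Bernoulli per alteration given class; ";"-joined strings
.draw_alterations <- function(cls, freqs) {
  n <- length(cls)
  out <- character(n)
  for (cl in unique(cls)) {
    idx <- which(cls == cl)
    f <- freqs[[cl]]
    if (!length(f)) { out[idx] <- ""; next }
    cols <- lapply(names(f), function(alt)
      ifelse(stats::rbinom(length(idx), 1L, f[[alt]]) == 1L, alt, ""))
    joined <- do.call(paste, c(cols, sep = ";"))
    joined <- gsub(";{2,}", ";", joined)
    out[idx] <- gsub("^;|;$", "", joined)
  }
  out
}

#' Write a cohort with its generation metadata
#'
#' Writes the nodule TSV via [write_nodule_table()] plus a sidecar
#' `<path>.json` recording the generating configuration, seed and package
#' version, so any cohort file can be regenerated exactly.
#'
#' @param records A nodule data frame.
#' @param path Output TSV path.
#' @param config The generating [cohort_config()], echoed in the
#'   metadata.
#' @return `path`, invisibly.
#' @export
write_cohort_bundle <- function(records, path, config = NULL) {
  write_nodule_table(records, path)
  meta <- list(
    n_records = nrow(records),
    package = "thyrostrat",
    version = as.character(utils::packageVersion("thyrostrat")),
    config = if (!is.null(config)) unclass(config)
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
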