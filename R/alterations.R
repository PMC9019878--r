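#' Molecular alteration objects
#'
#' An alteration is one molecular event detected in a nodule: a point
#' mutation (SNV), a small insertion/deletion, a gene fusion, or a
#' gene-expression flag. Alterations are the unit of evidence consumed by
#' the genomic-classifier scoring engine and by the risk-tier summaries.
#'
#' @param gene Gene symbol, e.g. `"BRAF"`. For fusions, the composite
#'   two-partner symbol, e.g. `"ETV6-NTRK3"`.
#' @param kind One of `"snv"`, `"indel"`, `"fusion"`, `"expression"`.
#' @param detail Free-text detail: a protein change (`"V600E"`), the fusion
#'   partners (`"ETV6-NTRK3"`), or `""`.
#' @param population_frequency Population allele frequency in `[0, 1]`, or
#'   `NA` when unknown (the common default for fusions and panel-specific
#'   events).
#' @return An object of class `"alteration"`: a list with fields `gene`,
#'   `kind`, `detail`, `population_frequency`.
#' @seealso [parse_alteration()], [filter_common_variants()], [assign_tier()]
#' @export
#' @examples
#' alteration("BRAF", "snv", "V600E")
#' alteration("ETV6-NTRK3", "fusion", "ETV6-NTRK3")
alteration <- function(gene, kind = "snv", detail = "",
                       population_frequency = NA_real_) {
  kind <- match.arg(kind, c("snv", "indel", "fusion", "expression"))
  if (!is.character(gene) || length(gene) != 1L || !nzchar(gene))
    stop("'gene' must be a non-empty string", call. = FALSE)
  if (kind == "fusion" && !grepl("-", if (nzchar(detail)) detail else gene))
    stop("a fusion must name two partners, e.g. \"ETV6-NTRK3\"", call. = FALSE)
  if (!is.na(population_frequency) &&
      (population_frequency < 0 || population_frequency > 1))
    stop("'population_frequency' must be in [0, 1] or NA", call. = FALSE)
  if (kind == "fusion" && !nzchar(detail)) detail <- gene
  structure(
    list(gene = gene, kind = kind, detail = as.character(detail),
         population_frequency = as.numeric(population_frequency)),
    class = "alteration"
  )
}

#' @export
print.alteration <- function(x, ...) {
  cat("<alteration> ", format_alteration(x), sep = "")
  if (!is.na(x$population_frequency))
    cat(sprintf("  [pop. freq %.4g]", x$population_frequency))
  cat("\n")
  invisible(x)
}

#' @export
format.alteration <- function(x, ...) format_alteration(x)

.alteration_kinds <- c("snv", "indel", "fusion", "expression")

#' Parse an alteration from its compact text form
#'
#' The text grammar is `GENE[:DETAIL][:KIND]`, with `KIND` one of
#' `snv`, `indel`, `fusion`, `expression`. A gene token containing a
#' hyphen (two fusion partners, e.g. `"ETV6-NTRK3"`) implies
#' `kind = "fusion"`; otherwise the kind defaults to `"snv"` unless given
#' explicitly. `parse_alterations()` parses a semicolon-joined list as it
#' appears in the `alterations` column of a nodule table (an empty string
#' or `NA` is an empty list).
#'
#' Hyphenated HGNC symbols such as `NKX2-1` are indistinguishable from a
#' fusion pair under this grammar; spell the kind explicitly
#' (`"NKX2-1::snv"` is not supported — use the TSV/VCF path for such genes).
#'
#' @param text A single string, e.g. `"BRAF:V600E"`, `"ETV6-NTRK3:fusion"`,
#'   `"NRAS"`.
#' @return An [alteration()] object (`parse_alteration`) or a list of them
#'   (`parse_alterations`).
#' @export
#' @examples
#' parse_alteration("BRAF:V600E")
#' parse_alteration("ETV6-NTRK3:fusion")
#' parse_alterations("NRAS;BRAF:V600E")
parse_alteration <- function(text) {
  if (!is.character(text) || length(text) != 1L)
    stop("'text' must be a single string", call. = FALSE)
  text <- trimws(text)
  if (!nzchar(text))
    stop("cannot parse alteration from empty string", call. = FALSE)
  tokens <- strsplit(text, ":", fixed = TRUE)[[1]]
  if (any(!nzchar(tokens)))
    stop(sprintf("malformed alteration '%s': empty token", text), call. = FALSE)
  if (length(tokens) > 3L)
    stop(sprintf("malformed alteration '%s': too many ':' fields", text),
         call. = FALSE)
  kind <- NA_character_
  if (length(tokens) > 1L && tokens[length(tokens)] %in% .alteration_kinds) {
    kind <- tokens[length(tokens)]
    tokens <- tokens[-length(tokens)]
  } else if (length(tokens) == 3L) {
    stop(sprintf("malformed alteration '%s': unknown kind '%s'",
                 text, tokens[3L]), call. = FALSE)
  }
  gene <- tokens[1L]
  detail <- if (length(tokens) >= 2L) tokens[2L] else ""
  if (!grepl("^[A-Za-z0-9_.-]+$", gene))
    stop(sprintf("malformed alteration '%s': bad gene token '%s'", text, gene),
         call. = FALSE)
  if (is.na(kind)) kind <- if (grepl("-", gene)) "fusion" else "snv"
  alteration(gene, kind, detail)
}

#' @rdname parse_alteration
#' @export
parse_alterations <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text)))
    return(list())
  parts <- strsplit(text, ";", fixed = TRUE)[[1]]
  lapply(trimws(parts), parse_alteration)
}

#' Format an alteration back to its compact text form
#'
#' Canonical form: `GENE` for an SNV with no detail, `GENE:DETAIL` for an
#' SNV with a detail, `PARTNERS:fusion` for fusions, and explicit
#' `:indel` / `:expression` suffixes otherwise. `parse_alteration()` of a
#' formatted alteration reproduces the original value.
#'
#' @param x An [alteration()] object, or a list of them for
#'   `format_alterations()` (joined with `";"`).
#' @return A string.
#' @export
format_alteration <- function(x) {
  stopifnot(inherits(x, "alteration"))
  if (x$kind == "fusion")
    return(paste0(if (nzchar(x$detail)) x$detail else x$gene, ":fusion"))
  base <- if (nzchar(x$detail)) paste0(x$gene, ":", x$detail) else x$gene
  if (x$kind == "snv") base else paste0(base, ":", x$kind)
}

#' @rdname format_alteration
#' @export
format_alterations <- function(x) {
  paste(vapply(x, format_alteration, character(1)), collapse = ";")
}

#' Drop common population variants
#'
#' Variants whose population frequency in reference databases exceeds the
#' threshold are treated as common polymorphisms with no diagnostic weight
#' and removed before scoring. Alterations with unknown frequency are
#' retained: only variants *known* to be common are filtered. The default
#' threshold is 0.1% (0.001), the conventional common-SNP cutoff.
#'
#' @param alterations A list of [alteration()] objects.
#' @param threshold Frequency cutoff in `[0, 1]`; alterations with known
#'   frequency strictly above it are removed.
#' @return The filtered list, input order preserved.
#' @export
#' @examples
#' a <- alteration("BRAF", "snv", "V600E", population_frequency = 1e-5)
#' b <- alteration("GENE1", "snv", "P100L", population_frequency = 0.005)
#' filter_common_variants(list(a, b))
filter_common_variants <- function(alterations, threshold = 0.001) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 1)
  if (length(alterations) == 0L) return(list())
  keep <- vapply(alterations, function(a) {
    f <- a$population_frequency
    is.na(f) || f <= threshold
  }, logical(1))
  alterations[keep]
}

#' Risk tiers for molecular alterations
#'
#' In indeterminate thyroid nodules, BRAF V600E, TERT promoter mutations
#' and oncogenic gene fusions are near-deterministic markers of malignancy
#' (`high_risk`); RAS-family mutations and BRAF K601E mark
#' follicular-patterned neoplasia with substantial but not specific
#' malignant potential (`ras_like`); everything else is `other`.
#'
#' `default_tier_map()` returns the tier rules as a data frame with columns
#' `gene`, `kind`, `detail`, `tier`; `""` is a wildcard. Rules are matched
#' most-specific-first: exact `(gene, detail)`, then `(gene, kind)`, then
#' `gene` alone, then `kind` alone; unmatched alterations are `other`.
#'
#' @param a An [alteration()] object.
#' @param tier_map A rule table as returned by [default_tier_map()].
#' @return `assign_tier()` returns one of `"high_risk"`, `"ras_like"`,
#'   `"other"`.
#' @export
#' @examples
#' assign_tier(parse_alteration("BRAF:V600E"))   # high_risk
#' assign_tier(parse_alteration("BRAF:K601E"))   # ras_like
#' assign_tier(parse_alteration("CCDC6-RET:fusion"))
assign_tier <- function(a, tier_map = default_tier_map()) {
  stopifnot(inherits(a, "alteration"))
  hit <- .match_rule(a, tier_map)
  if (is.na(hit)) "other" else tier_map$tier[hit]
}

#' @rdname assign_tier
#' @export
default_tier_map <- function() {
  data.frame(
    gene   = c("BRAF", "TERT", "", "NRAS", "HRAS", "KRAS", "BRAF"),
    kind   = c("snv",  "",     "fusion", "", "", "", "snv"),
    detail = c("V600E", "",    "", "", "", "", "K601E"),
    tier   = c("high_risk", "high_risk", "high_risk",
               "ras_like", "ras_like", "ras_like", "ras_like"),
    stringsAsFactors = FALSE
  )
}

# Most-specific-match-first rule lookup shared by tier and weight tables.
# Precedence: (gene, detail) > (gene, kind) > gene > kind; returns the row
# index of the best match or NA. "" in a rule field is a wildcard.
.match_rule <- function(a, rules) {
  g <- nzchar(rules$gene)
  k <- nzchar(rules$kind)
  d <- nzchar(rules$detail)
  gene_ok <- !g | rules$gene == a$gene
  kind_ok <- !k | rules$kind == a$kind
  detail_ok <- !d | rules$detail == a$detail
  ok <- gene_ok & kind_ok & detail_ok
  if (!any(ok)) return(NA_integer_)
  specificity <- ifelse(g & d, 4L, ifelse(g & k, 3L, ifelse(g, 2L, 1L)))
  specificity[!ok] <- 0L
  which.max(specificity)
}
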