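#' Per-alteration weight tables
#'
#' The genomic classifier assigns each detected alteration a percentage
#' value reflecting the strength of its association with malignancy, then
#' combines the values into a single score. The weight table maps
#' alterations to those values. It is a data frame with columns `gene`,
#' `kind`, `detail` (each possibly `""` as a wildcard) and `weight`
#' (percent, in `[0, 100]`), plus a `default_weight` attribute for
#' alterations matched by no rule. Lookup is total and deterministic:
#' most-specific-match-first with precedence exact `(gene, detail)` >
#' `(gene, kind)` > `gene` > `kind` > default.
#'
#' The published assay does not disclose its per-alteration values, so the
#' defaults here are the package's own calibration, chosen to reproduce
#' the qualitative call pattern observed in resected indeterminate
#' cohorts: high-risk alterations (BRAF V600E, TERT, any fusion) are
#' individually decisive at the 70% positivity threshold, RAS-like
#' mutations alone are not, and an expression-classifier-positive flag
#' adds strong supporting evidence.
#'
#' @param gene,kind,detail Rule fields; `""` matches anything.
#' @param weight Percent values in `[0, 100]`.
#' @param default_weight Value for alterations matched by no rule.
#' @return A data frame of class `"weight_table"`.
#' @seealso [lookup_weight()], [score_alterations()], [read_weight_table()]
#' @export
#' @examples
#' default_weight_table()
weight_table <- function(gene, kind, detail, weight, default_weight = 20) {
  stopifnot(length(gene) == length(kind), length(kind) == length(detail),
            length(detail) == length(weight))
  weight <- as.numeric(weight)
  if (any(weight < 0 | weight > 100) ||
      default_weight < 0 || default_weight > 100)
    stop("weights must be percentages in [0, 100]", call. = FALSE)
  out <- data.frame(gene = as.character(gene), kind = as.character(kind),
                    detail = as.character(detail), weight = weight,
                    stringsAsFactors = FALSE)
  bad <- nzchar(out$kind) & !out$kind %in% .alteration_kinds
  if (any(bad))
    stop("unknown kind in weight table: ",
         paste(unique(out$kind[bad]), collapse = ", "), call. = FALSE)
  attr(out, "default_weight") <- as.numeric(default_weight)
  class(out) <- c("weight_table", "data.frame")
  out
}

#' @rdname weight_table
#' @export
default_weight_table <- function() {
  weight_table(
    gene   = c("BRAF",  "BRAF",  "TERT", "",       "NRAS", "HRAS", "KRAS", ""),
    kind   = c("snv",   "snv",   "",     "fusion", "",     "",     "",     "expression"),
    detail = c("V600E", "K601E", "",     "",       "",     "",     "",     ""),
    weight = c(95,      55,      90,     90,       60,     60,     60,     75),
    default_weight = 20
  )
}

#' Look up the weight of one alteration
#'
#' @param a An [alteration()] object.
#' @param weights A [weight_table()].
#' @return The weight (percent) as a single number; the table's default
#'   weight when no rule matches.
#' @export
lookup_weight <- function(a, weights = default_weight_table()) {
  stopifnot(inherits(weights, "weight_table"))
  hit <- .match_rule(a, weights)
  if (is.na(hit)) attr(weights, "default_weight") else weights$weight[hit]
}

#' Read / write a weight table as TSV
#'
#' Tab-separated, UTF-8, columns `gene`, `kind`, `detail`, `weight`;
#' `'#'` starts a comment line. An optional pseudo-row with `gene`,
#' `kind` and `detail` all empty (or `"*"`) sets the default weight;
#' `"*"` anywhere is read as the `""` wildcard.
#'
#' @param path File path.
#' @param weights A [weight_table()] (for the writer).
#' @return `read_weight_table()` returns a [weight_table()];
#'   `write_weight_table()` returns `path` invisibly.
#' @export
read_weight_table <- function(path) {
  if (!file.exists(path))
    stop("weight table not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL,
                          fileEncoding = "UTF-8")
  need <- c("gene", "kind", "detail", "weight")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("weight table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (col in c("gene", "kind", "detail"))
    df[[col]] <- ifelse(df[[col]] == "*", "", trimws(df[[col]]))
  w <- suppressWarnings(as.numeric(df$weight))
  if (anyNA(w))
    stop("non-numeric weight in ", path, " at row ",
         which(is.na(w))[1], call. = FALSE)
  is_default <- !nzchar(df$gene) & !nzchar(df$kind) & !nzchar(df$detail)
  default_weight <- if (any(is_default)) w[which(is_default)[1]] else 20
  weight_table(df$gene[!is_default], df$kind[!is_default],
               df$detail[!is_default], w[!is_default],
               default_weight = default_weight)
}

#' @rdname read_weight_table
#' @export
write_weight_table <- function(weights, path) {
  stopifnot(inherits(weights, "weight_table"))
  df <- as.data.frame(weights)
  df <- rbind(df, data.frame(gene = "", kind = "", detail = "",
                             weight = attr(weights, "default_weight")))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
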