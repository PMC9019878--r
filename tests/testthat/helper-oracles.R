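# Independent brute-force oracles used to check the fast implementations.

# Pearson / Yates chi-squared by direct sum over the four cells
oracle_chi2 <- function(a, b, c, d, yates = FALSE) {
  m <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  dev <- abs(m - e)
  if (yates) dev <- pmax(0, dev - 0.5)
  sum(dev^2 / e)
}

# AUC by explicit enumeration of all positive-negative pairs
oracle_auc <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  wins <- 0
  for (x in sp) for (y in sn)
    wins <- wins + (x > y) + 0.5 * (x == y)
  wins / (length(sp) * length(sn))
}

# Wilson interval via the score-test inversion in prop.test
oracle_wilson <- function(k, n, level = 0.95) {
  as.numeric(suppressWarnings(
    stats::prop.test(k, n, conf.level = level, correct = FALSE))$conf.int)
}

# common-variant filter as a one-line comprehension over the stated rule
oracle_filter <- function(alts, threshold) {
  Filter(function(a) is.na(a$population_frequency) ||
           a$population_frequency <= threshold, alts)
}

random_alteration <- function() {
  kind <- sample(c("snv", "indel", "fusion", "expression"), 1)
  gene <- if (kind == "fusion")
    paste(sample(LETTERS, 4), collapse = "")
  else paste(sample(LETTERS, 3), collapse = "")
  if (kind == "fusion") gene <- paste0(gene, "-", paste(sample(LETTERS, 3),
                                                        collapse = ""))
  freq <- if (runif(1) < 0.4) NA_real_ else runif(1, 0, 0.02)
  alteration(gene, kind,
             detail = if (kind == "snv") "V600E" else "",
             population_frequency = freq)
}
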