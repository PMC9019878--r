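test_that("the compact text grammar parses the published alteration spectrum", {
  a <- parse_alteration("BRAF:V600E")
  expect_s3_class(a, "alteration")
  expect_equal(a$gene, "BRAF")
  expect_equal(a$kind, "snv")
  expect_equal(a$detail, "V600E")

  f <- parse_alteration("ETV6-NTRK3:fusion")
  expect_equal(f$kind, "fusion")
  expect_equal(f$detail, "ETV6-NTRK3")

  # two hyphenated partners imply a fusion even without the suffix
  expect_equal(parse_alteration("CCDC6-RET")$kind, "fusion")
  # bare gene symbol is an SNV with no detail
  expect_equal(parse_alteration("NRAS")$kind, "snv")
  # explicit kinds
  expect_equal(parse_alteration("TP53:R273H:indel")$kind, "indel")
  expect_equal(parse_alteration("GENE1:expression")$kind, "expression")
})

test_that("malformed alteration strings fail with the offending token named", {
  expect_error(parse_alteration(""), "empty")
  expect_error(parse_alteration("BRAF::V600E"), "empty token")
  expect_error(parse_alteration("BRAF:V600E:badkind"), "badkind")
  expect_error(parse_alteration("BR AF"), "BR AF")
  expect_error(parse_alteration("A:B:C:D"), "too many")
})

test_that("every published alteration string round-trips parse -> format -> parse", {
  published <- c("NRAS", "HRAS", "KRAS", "BRAF:V600E", "BRAF:K601E", "TERT",
                 "ETV6-NTRK3:fusion", "CCDC6-RET:fusion", "NCOA4-RET:fusion",
                 "STRN-ALK:fusion")
  for (s in published) {
    a1 <- parse_alteration(s)
    a2 <- parse_alteration(format_alteration(a1))
    expect_equal(a1, a2, info = s)
  }
  # semicolon-joined lists round-trip too (multi-hit anaplastic nodule)
  alts <- parse_alterations("TERT;BRAF:V600E")
  expect_length(alts, 2)
  expect_equal(parse_alterations(format_alterations(alts)), alts)
  expect_equal(parse_alterations(""), list())
  expect_equal(parse_alterations(NA_character_), list())
})

test_that("common-variant filter keeps unknown and rare, drops common", {
  rare <- alteration("BRAF", "snv", "V600E", population_frequency = 1e-4)
  common <- alteration("GENE1", "snv", "P10L", population_frequency = 5e-3)
  unknown <- alteration("TERT", "snv")
  out <- filter_common_variants(list(common, rare, unknown))
  expect_equal(out, list(rare, unknown))  # order preserved
  expect_equal(filter_common_variants(list()), list())
  # boundary: exactly at the threshold is retained (rule is strictly >)
  at <- alteration("X1", "snv", "A1B", population_frequency = 0.001)
  expect_equal(filter_common_variants(list(at)), list(at))
})

test_that("filter matches a brute-force comprehension and is idempotent", {
  set.seed(42)
  for (rep in 1:5) {
    alts <- replicate(100, random_alteration(), simplify = FALSE)
    thr <- runif(1, 0, 0.01)
    got <- filter_common_variants(alts, thr)
    expect_equal(got, oracle_filter(alts, thr))
    expect_lte(length(got), length(alts))
    expect_equal(filter_common_variants(got, thr), got)
  }
})

test_that("risk tiers follow the high-risk / RAS-like / other partition", {
  expect_equal(assign_tier(parse_alteration("BRAF:V600E")), "high_risk")
  expect_equal(assign_tier(parse_alteration("TERT")), "high_risk")
  expect_equal(assign_tier(parse_alteration("ETV6-NTRK3:fusion")), "high_risk")
  expect_equal(assign_tier(parse_alteration("STRN-ALK:fusion")), "high_risk")
  expect_equal(assign_tier(parse_alteration("NRAS")), "ras_like")
  expect_equal(assign_tier(parse_alteration("HRAS")), "ras_like")
  expect_equal(assign_tier(parse_alteration("KRAS")), "ras_like")
  expect_equal(assign_tier(parse_alteration("BRAF:K601E")), "ras_like")
  expect_equal(assign_tier(parse_alteration("EIF1AX")), "other")
  # purity: repeated calls agree
  a <- parse_alteration("BRAF:V600E")
  expect_equal(assign_tier(a), assign_tier(a))
})

test_that("weight lookup is total with most-specific-match precedence", {
  w <- default_weight_table()
  expect_equal(lookup_weight(parse_alteration("BRAF:V600E"), w), 95)
  expect_equal(lookup_weight(parse_alteration("BRAF:K601E"), w), 55)
  expect_equal(lookup_weight(parse_alteration("TERT"), w), 90)
  expect_equal(lookup_weight(parse_alteration("ETV6-NTRK3:fusion"), w), 90)
  expect_equal(lookup_weight(parse_alteration("NRAS"), w), 60)
  expect_equal(lookup_weight(parse_alteration("GENE1:expression"), w), 75)
  # unmatched alteration falls through to the default weight
  expect_equal(lookup_weight(parse_alteration("EIF1AX"), w), 20)
  # gene+detail beats gene+kind beats gene: a BRAF SNV that is neither
  # V600E nor K601E gets the default, not the V600E weight
  expect_equal(lookup_weight(parse_alteration("BRAF:G469A"), w), 20)
})

test_that("weight tables reject out-of-range weights and round-trip TSV", {
  expect_error(weight_table("A", "snv", "", 120), "\\[0, 100\\]")
  expect_error(weight_table("A", "badkind", "", 50), "kind")
  w <- default_weight_table()
  tf <- tempfile(fileext = ".tsv")
  write_weight_table(w, tf)
  w2 <- read_weight_table(tf)
  expect_equal(as.data.frame(w2), as.data.frame(w))
  expect_equal(attr(w2, "default_weight"), attr(w, "default_weight"))
  expect_error(read_weight_table(tempfile()), "not found")
})
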