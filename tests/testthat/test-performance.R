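test_that("confusion tables partition the resected cohort under both borderline policies", {
  rc <- resected_cohort()
  ct_m <- confusion_table(rc, "rna_call", "as_malignant")
  expect_equal(c(ct_m$tp, ct_m$fp, ct_m$tn, ct_m$fn), c(40L, 9L, 6L, 3L))
  # moving borderline lesions to the benign side reshuffles the cells
  ct_b <- confusion_table(rc, "rna_call", "as_benign")
  expect_equal(c(ct_b$tp, ct_b$fp, ct_b$tn, ct_b$fn), c(32L, 17L, 8L, 1L))
  # both partitions cover all 58 nodules
  expect_equal(ct_m$tp + ct_m$fp + ct_m$tn + ct_m$fn, 58L)
  expect_equal(ct_b$tp + ct_b$fp + ct_b$tn + ct_b$fn, 58L)

  empty <- confusion_table(rc[0, ], "rna_call")
  expect_equal(c(empty$tp, empty$fp, empty$tn, empty$fn), rep(0L, 4))

  un <- rc
  un$resected[1] <- FALSE
  un$histology[1] <- "unresected"
  expect_error(confusion_table(un, "rna_call"), "resected")
})

test_that("binary metrics are the stated ratios and refuse zero denominators", {
  m <- binary_metrics(new_confusion_table(40, 9, 6, 3))
  get <- function(x) m$point[m$metric == x]
  expect_equal(get("sensitivity"), 40 / 43)
  expect_equal(get("specificity"), 6 / 15)
  expect_equal(get("ppv"), 40 / 49)
  expect_equal(get("npv"), 6 / 9)
  expect_equal(get("accuracy"), 46 / 58)
  expect_true(all(m$ci_low <= m$point & m$point <= m$ci_high))
  expect_error(binary_metrics(new_confusion_table(0, 0, 5, 5)),
               "ppv.*zero denominator")
})

test_that("Wilson interval matches the score-test inversion and its properties", {
  # frozen value computed independently from the closed form
  ci <- wilson_ci(6, 15)
  expect_equal(unname(ci[1, ]), c(0.1982450, 0.6425317), tolerance = 1e-6)
  # against prop.test's score-test inversion on a grid
  for (n in c(5, 20, 50)) for (k in c(0, 1, floor(n / 2), n)) {
    expect_equal(unname(wilson_ci(k, n)[1, ]), oracle_wilson(k, n),
                 tolerance = 1e-12, info = paste(k, n))
  }
  expect_equal(wilson_ci(0, 20)[1, "low"], c(low = 0))
  expect_equal(wilson_ci(20, 20)[1, "high"], c(high = 1))
  # symmetry k <-> n-k mirrors the interval around 1/2
  ci1 <- wilson_ci(10, 20); ci2 <- wilson_ci(10, 20)
  expect_equal(unname(ci1[1, "low"]), unname(1 - ci2[1, "high"]))
  # interval always contains k/n; width shrinks with n at fixed k/n
  set.seed(3)
  for (rep in 1:50) {
    n <- sample(2:500, 1); k <- sample(0:n, 1)
    ci <- wilson_ci(k, n)
    expect_true(ci[1, "low"] <= k / n && k / n <= ci[1, "high"])
  }
  widths <- vapply(c(10, 40, 160, 640), function(n)
    diff(wilson_ci(0.3 * n, n)[1, ]), numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_error(wilson_ci(3, 0), "positive")
})

test_that("continuity-corrected Wald interval reproduces its dialect and clips", {
  ci <- wald_cc_ci(6, 15)
  expect_equal(unname(round(ci[1, ], 3)), c(0.119, 0.681))
  expect_equal(unname(wald_cc_ci(0, 10)[1, "low"]), 0)
  expect_equal(unname(wald_cc_ci(15, 15)[1, "high"]), 1)
  # direct formula check
  p <- 6 / 15; z <- qnorm(0.975)
  half <- z * sqrt(p * (1 - p) / 15) + 1 / 30
  expect_equal(unname(ci[1, ]), c(p - half, p + half))
})

test_that("ROM honours the borderline policy", {
  rc <- resected_cohort()
  expect_equal(rom(rc)$point, 43 / 58)
  expect_equal(rom(rc, "as_benign")$point, 33 / 58)
  expect_gte(rom(rc)$point, rom(rc, "as_benign")$point)
  toy <- data.frame(histology = rep("hyperplasia", 4), resected = TRUE)
  expect_equal(rom(toy)$point, 0)
  expect_error(rom(toy[0, ]), "zero denominator")
})

test_that("resection rates reproduce the published strata and flag degenerate ones", {
  full <- indeterminate_cohort()
  rr_rna <- resection_rates(full, "rna_call")
  expect_equal(rr_rna$rates$numerator, c(49L, 9L))
  expect_equal(rr_rna$rates$denominator, c(114L, 26L))
  expect_equal(round(rr_rna$rates$point, 3), c(0.430, 0.346))
  expect_gt(rr_rna$comparison$p_value, 0.05)  # management ignores the call
  rr_gc <- resection_rates(full, "gc_call")
  expect_equal(round(rr_gc$rates$point, 3), c(0.434, 0.353))
  expect_equal(rr_gc$rates$denominator, c(106L, 34L))
  one_sided <- full[full$rna_call == "positive", ]
  expect_error(resection_rates(one_sided, "rna_call"), "no negative calls")
})

test_that("chi-squared matches the brute-force Pearson/Yates oracle and edge cases", {
  r <- chi2_2x2(38, 7, 31, 18)
  expect_equal(r$chi2_stat, oracle_chi2(38, 7, 31, 18))
  expect_equal(round(r$chi2_stat, 2), 5.39)
  expect_equal(round(r$p_value, 3), 0.02)
  expect_equal(round(chi2_2x2(40, 9, 46, 77)$chi2_stat, 2), 27.43)
  flat <- chi2_2x2(1, 1, 1, 1)
  expect_equal(flat$chi2_stat, 0)
  expect_equal(flat$p_value, 1)
  expect_error(chi2_2x2(0, 0, 3, 4), "margin")
  expect_error(chi2_2x2(-1, 2, 3, 4), "non-negative")
  y <- chi2_2x2(12, 5, 4, 14, correction = "yates")
  expect_equal(y$chi2_stat, oracle_chi2(12, 5, 4, 14, yates = TRUE))
  # proportion wrapper lays out the same table
  expect_equal(compare_proportions(38, 45, 31, 49)$chi2_stat,
               chi2_2x2(38, 7, 31, 18)$chi2_stat)
})

test_that("AUC equals pair enumeration, including ties and degenerate inputs", {
  expect_equal(auc_mann_whitney(c(0.9, 0.8, 0.7, 0.4),
                                c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auc_mann_whitney(c(0.8, 0.3, 0.5, 0.2),
                                c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_equal(auc_mann_whitney(rep(1, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  expect_error(auc_mann_whitney(1:3, c(TRUE, TRUE, TRUE)), "at least one")
  set.seed(5)
  for (rep in 1:25) {
    n <- sample(4:50, 1)
    scores <- round(runif(n), 2)  # rounding forces ties
    pos <- runif(n) < 0.5
    if (!any(pos) || all(pos)) next
    expect_equal(auc_mann_whitney(scores, pos), oracle_auc(scores, pos))
  }
})

test_that("AUC agrees with an independent ROC package on a simulated cohort", {
  skip_if_not_installed("pROC")
  co <- generate_cohort(cohort_config(n_nodules = 300, seed = 9,
                                      resection_probs = c(positive = 1,
                                                          negative = 1)))
  truth <- histology_class(co$histology) %in% c("malignant", "borderline")
  got <- auc_mann_whitney(co$gc_score, truth)
  ref <- as.numeric(pROC::auc(pROC::roc(truth, co$gc_score, quiet = TRUE,
                                        direction = "<")))
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("risk-tier summaries reproduce the published fractions", {
  rc <- resected_cohort()
  s <- alteration_summaries(rc)
  expect_equal(s$numerator[s$metric == "high_risk_fraction"], 13L)
  expect_equal(s$denominator[s$metric == "high_risk_fraction"], 33L)
  expect_equal(s$point[s$metric == "ras_only_risk"], 0.8)
  expect_equal(s$denominator[s$metric == "ras_only_risk"], 10L)
  # the RAS-only stratum row is dropped when the stratum is empty
  s2 <- alteration_summaries(rc, ras_genes = "NOSUCHGENE")
  expect_false("ras_only_risk" %in% s2$metric)
  # no high-risk alterations anywhere -> fraction 0
  none <- rc
  none$alterations <- NA_character_
  s0 <- alteration_summaries(none)
  expect_equal(s0$point[s0$metric == "high_risk_fraction"], 0)
})
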