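test_that("config validation rejects malformed probability vectors", {
  expect_error(cohort_config(class_probs = c(benign = 0.5, borderline = 0.4,
                                             malignant = 0.2)),
               "sum to 1")
  expect_error(cohort_config(bethesda_probs = c(III = 1)), "named over")
  expect_error(cohort_config(resection_probs = c(positive = 1.2,
                                                 negative = 0.3)))
  expect_error(cohort_config(n_nodules = -1))
})

test_that("Beta calibration hits the requested operating point", {
  cal <- calibrate_score_distributions(0.884, 0.533, threshold = 70)
  expect_equal(1 - pbeta(0.70, cal$positive[[1]], cal$positive[[2]]), 0.884,
               tolerance = 1e-6)
  expect_equal(pbeta(0.70, cal$negative[[1]], cal$negative[[2]]), 0.533,
               tolerance = 1e-6)
  # spec 0.5 places the benign median exactly at the threshold
  cal2 <- calibrate_score_distributions(0.9, 0.5, threshold = 70)
  expect_equal(qbeta(0.5, cal2$negative[[1]], cal2$negative[[2]]), 0.70,
               tolerance = 1e-6)
  # degenerate targets are infeasible for any Beta law
  expect_error(calibrate_score_distributions(1, 0.5), "strictly inside")
  expect_error(calibrate_score_distributions(0.9, 0), "strictly inside")
})

test_that("generated cohorts are seed-deterministic, sized and class-balanced", {
  cfg <- cohort_config(n_nodules = 0, seed = 1)
  expect_equal(nrow(generate_cohort(cfg)), 0)

  cfg <- cohort_config(n_nodules = 5800, seed = 123)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co), 5800)
  expect_true(all(co$bethesda %in% c("III", "IV")))
  expect_true(all(co$size_cm > 0))
  expect_true(all(co$histology[!co$resected] == "unresected"))
  expect_true(all(co$histology[co$resected] != "unresected"))
  # class counts within 3 binomial standard deviations of expectation
  cls <- histology_class(co$histology[co$resected])
  # resection is call-dependent, so check the latent mix on a fully
  # resected cohort instead
  co_all <- generate_cohort(cohort_config(n_nodules = 5800, seed = 123,
                                          resection_probs = c(positive = 1,
                                                              negative = 1)))
  cls <- table(histology_class(co_all$histology))
  for (cl in c("benign", "borderline", "malignant")) {
    p <- cohort_config()$class_probs[[cl]]
    expect_lt(abs(cls[[cl]] - 5800 * p), 3 * sqrt(5800 * p * (1 - p)))
  }

  # same config, same seed: byte-identical TSV output
  f1 <- tempfile(); f2 <- tempfile()
  write_nodule_table(generate_cohort(cfg), f1)
  write_nodule_table(generate_cohort(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
  # different seed: different cohort
  co2 <- generate_cohort(cohort_config(n_nodules = 5800, seed = 124))
  expect_false(identical(co$rna_score, co2$rna_score))
})

test_that("generated alteration frequencies track the configured class-conditional rates", {
  co <- generate_cohort(cohort_config(n_nodules = 8000, seed = 77,
                                      reveal_unresected = TRUE))
  cls <- histology_class(co$histology)
  mal <- co$alterations[cls == "malignant"]
  n_mal <- length(mal)
  p_v600e <- 5 / 33
  hits <- sum(grepl("BRAF:V600E", mal))
  expect_lt(abs(hits - n_mal * p_v600e),
            4 * sqrt(n_mal * p_v600e * (1 - p_v600e)))
  # fusions never appear in benign nodules under the defaults
  expect_false(any(grepl("fusion", co$alterations[cls == "benign"])))
  # alteration strings parse under the grammar
  expect_silent(lapply(co$alterations[1:200], parse_alterations))
})

test_that("equal resection probabilities give the null chi-squared regime", {
  set.seed(2026)
  p <- replicate(120, {
    cfg <- cohort_config(n_nodules = 600,
                         seed = sample.int(2^31 - 1, 1),
                         resection_probs = c(positive = 0.4, negative = 0.4),
                         alteration_freqs = NULL)
    resection_rates(generate_cohort(cfg), "gc_call")$comparison$p_value
  })
  # rejection rate at alpha = 0.05 stays near its nominal level
  expect_gt(mean(p < 0.05), 0.005)
  expect_lt(mean(p < 0.05), 0.12)
})

test_that("ROM under borderline-as-malignant dominates borderline-as-benign on every cohort", {
  for (s in 1:5) {
    co <- generate_cohort(cohort_config(n_nodules = 300, seed = s))
    res <- co[co$resected, ]
    expect_gte(rom(res, "as_malignant")$point, rom(res, "as_benign")$point)
  }
})

test_that("cohort bundles carry their generating metadata", {
  cfg <- cohort_config(n_nodules = 30, seed = 5)
  co <- generate_cohort(cfg)
  tf <- tempfile(fileext = ".tsv")
  write_cohort_bundle(co, tf, cfg)
  meta <- jsonlite::read_json(paste0(tf, ".json"), simplifyVector = TRUE)
  expect_equal(meta$n_records, 30)
  expect_equal(meta$config$seed, 5)
  expect_equal(nrow(read_nodule_table(tf)), 30)
})
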