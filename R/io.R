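#' Read and write nodule tables
#'
#' The on-disk interchange format is tab-separated UTF-8 with a mandatory
#' header, `'.'` decimal separator and empty cells for missing values.
#' Required columns: `nodule_id`, `bethesda` (`III`/`IV`), `histology`
#' (a subtype label from [histology_levels()], or `"unresected"`), and
#' `resected` (logical or 0/1). Optional columns: `patient_id`,
#' `size_cm`, `alterations` (semicolon-joined [parse_alteration()]
#' grammar), `rna_score`, `gc_score` (percent), `rna_call`, `gc_call`
#' (`positive`/`negative`). Validation errors name the offending row and
#' column.
#'
#' @param path File path.
#' @param sep Field separator; `"\t"` (default) or `","` for CSV.
#' @return `read_nodule_table()` returns a validated data frame;
#'   `write_nodule_table()` returns `path` invisibly.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write_nodule_table(resected_cohort(), tf)
#' nrow(read_nodule_table(tf))
read_nodule_table <- function(path, sep = "\t") {
  if (!file.exists(path))
    stop("nodule table not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, na.strings = c("", "NA"),
                          quote = "", comment.char = "",
                          fileEncoding = "UTF-8")
  miss <- setdiff(c("nodule_id", "bethesda", "histology", "resected"),
                  names(df))
  if (length(miss))
    stop("nodule table ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  .bad_row <- function(col, rows, why) {
    stop(sprintf("nodule table %s, column '%s', row %s: %s",
                 path, col, paste(utils::head(rows, 5), collapse = ","), why),
         call. = FALSE)
  }
  if (nrow(df) == 0L) return(df)

  bad <- which(!df$bethesda %in% c("III", "IV"))
  if (length(bad)) .bad_row("bethesda", bad, "must be 'III' or 'IV'")
  known <- c(unlist(.histology_levels, use.names = FALSE), "unresected")
  bad <- which(!df$histology %in% known)
  if (length(bad)) .bad_row("histology", bad, "unknown histology label")
  res <- df$resected
  if (is.character(res)) res <- toupper(trimws(res)) %in% c("TRUE", "1", "YES")
  else res <- as.logical(res)
  if (anyNA(res)) .bad_row("resected", which(is.na(res)), "not logical/0-1")
  df$resected <- res
  bad <- which(!df$resected & df$histology != "unresected")
  if (length(bad))
    .bad_row("histology", bad, "unresected nodule with a histology label")
  for (col in c("rna_score", "gc_score")) {
    if (!col %in% names(df)) next
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & is.na(v))
    if (length(bad)) .bad_row(col, bad, "non-numeric score")
    bad <- which(!is.na(v) & (v < 0 | v > 100))
    if (length(bad)) .bad_row(col, bad, "score outside [0, 100]")
    df[[col]] <- v
  }
  for (col in c("rna_call", "gc_call")) {
    if (!col %in% names(df)) next
    bad <- which(!is.na(df[[col]]) &
                 !df[[col]] %in% c("positive", "negative"))
    if (length(bad)) .bad_row(col, bad, "call must be positive/negative")
  }
  if ("alterations" %in% names(df)) {
    for (i in seq_len(nrow(df))) {
      parsed <- tryCatch(parse_alterations(as.character(df$alterations[i])),
                         error = function(e) e)
      if (inherits(parsed, "error"))
        .bad_row("alterations", i, conditionMessage(parsed))
    }
  }
  df
}

#' @rdname read_nodule_table
#' @param records A nodule data frame.
#' @export
write_nodule_table <- function(records, path, sep = "\t") {
  stopifnot(is.data.frame(records))
  utils::write.table(records, path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/load, score, evaluate, curves and comparison
#' into one reproducible bundle written to an output directory:
#'
#' * `nodules.tsv` — the analysed cohort (simulated or loaded, with
#'   scores and calls filled in).
#' * `metrics.tsv` / `metrics.json` — ROM and per-classifier
#'   sensitivity, specificity, PPV, NPV and accuracy with CIs, plus
#'   resection rates when the cohort contains unresected nodules.
#' * `curves_<classifier>.tsv` — expected PPV/NPV over prevalence.
#' * `recommendation_<classifier>.json` — rule-in/rule-out call at the
#'   cohort's own ROM.
#' * `comparisons.json` — chi-squared comparisons against any configured
#'   published `(successes, total)` pairs.
#' * `run_info.json` — package version, seed, config echo and config
#'   hash.
#' * `summary.txt` — human-readable digest.
#'
#' Identical config and seed give an identical bundle. Any stage failure
#' propagates as an error prefixed with the stage name.
#'
#' @param config A named list (or path to a YAML/JSON file) with any of:
#'   `input` (nodule table path), `simulate` (arguments for
#'   [cohort_config()]), `weights` (weight-table TSV path),
#'   `gc_threshold`, `rna_threshold`, `rule`, `freq_threshold`,
#'   `policy`, `ci_method`, `correction`, `npv_target`, `ppv_target`,
#'   `comparators` (named list of
#'   `list(call=, metric=, successes=, total=)` published operating
#'   points),
#'   `seed`, `out_dir`. Exactly one of `input`/`simulate` is required.
#' @return The bundle as a list (cohort, metrics, curves,
#'   recommendations, comparisons, paths), invisibly.
#' @export
#' @examples
#' out <- tempfile()
#' cfg <- list(simulate = list(n_nodules = 120), seed = 42, out_dir = out)
#' bundle <- run_pipeline(cfg)
#' bundle$metrics[bundle$metrics$metric == "rom", ]
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- read_run_config(config)
  stopifnot(is.list(config))
  cfg <- utils::modifyList(
    list(input = NULL, simulate = NULL, weights = NULL,
         gc_threshold = 70, rna_threshold = 10, rule = "saturating_sum",
         freq_threshold = 0.001, policy = "as_malignant",
         ci_method = "wilson", correction = "none",
         npv_target = 0.90, ppv_target = 0.75,
         comparators = NULL, seed = 1L, out_dir = NULL),
    config)
  .stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  cohort <- .stage("load", {
    if (!is.null(cfg$simulate)) {
      sim <- cfg$simulate
      if (is.null(sim$seed)) sim$seed <- cfg$seed
      generate_cohort(do.call(cohort_config, sim))
    } else if (!is.null(cfg$input)) {
      read_nodule_table(cfg$input)
    } else stop("config needs either 'input' or 'simulate'")
  })

  cohort <- .stage("score", {
    w <- if (!is.null(cfg$weights)) read_weight_table(cfg$weights)
         else default_weight_table()
    needs_gc <- "alterations" %in% names(cohort) &&
      !"gc_call" %in% names(cohort)
    if (needs_gc || !is.null(cfg$weights))
      cohort <- score_nodules(cohort, w, cfg$gc_threshold, cfg$rna_threshold,
                              cfg$rule, cfg$freq_threshold)
    if ("rna_score" %in% names(cohort) && !"rna_call" %in% names(cohort))
      cohort$rna_call <- classify(cohort$rna_score, cfg$rna_threshold)
    cohort
  })

  calls <- intersect(c("rna_call", "gc_call"), names(cohort))
  resected <- cohort[as.logical(cohort$resected), , drop = FALSE]

  eval_out <- .stage("evaluate", {
    metrics <- rom(resected, cfg$policy, cfg$ci_method)
    metrics <- cbind(classifier = NA_character_, metrics)
    cts <- list()
    for (cl in calls) {
      ok <- !is.na(resected[[cl]])
      ct <- confusion_table(resected[ok, , drop = FALSE], cl, cfg$policy)
      cts[[cl]] <- ct
      m <- cbind(classifier = sub("_call$", "", cl),
                 binary_metrics(ct, cfg$ci_method))
      metrics <- rbind(metrics, m)
    }
    rr <- list()
    if (any(!cohort$resected)) {
      for (cl in calls) {
        r <- resection_rates(cohort[!is.na(cohort[[cl]]), , drop = FALSE],
                             cl, cfg$ci_method, correction = cfg$correction)
        rr[[cl]] <- r
        m <- cbind(classifier = paste0(sub("_call$", "", cl), "_",
                                       r$rates$stratum),
                   r$rates[-1])
        names(m) <- names(metrics)
        metrics <- rbind(metrics, m)
      }
    }
    if ("alterations" %in% names(resected) && nrow(resected)) {
      s <- tryCatch(alteration_summaries(resected, ci_method = cfg$ci_method),
                    error = function(e) NULL)
      if (!is.null(s)) metrics <- rbind(metrics,
                                        cbind(classifier = "gc", s))
    }
    list(metrics = metrics, cts = cts, resection = rr)
  })

  curve_out <- .stage("curves", {
    rom_pt <- eval_out$metrics$point[eval_out$metrics$metric == "rom"][1]
    lapply(eval_out$cts, function(ct) {
      m <- binary_metrics(ct, "none", metrics = c("sensitivity", "specificity"))
      sens <- m$point[1]; spec <- m$point[2]
      list(curve = prevalence_curve(sens, spec),
           recommendation = recommend_mode(sens, spec, rom_pt,
                                           cfg$npv_target, cfg$ppv_target),
           npv_crossover = npv_crossover(sens, spec, cfg$npv_target),
           ppv_crossover = ppv_crossover(sens, spec, cfg$ppv_target))
    })
  })

  comparisons <- .stage("compare", {
    if (is.null(cfg$comparators)) NULL else
      lapply(cfg$comparators, function(cp) {
        ct <- eval_out$cts[[cp$call]]
        m <- binary_metrics(ct, "none", metrics = cp$metric)
        res <- compare_proportions(m$numerator, m$denominator,
                                   cp$successes, cp$total,
                                   correction = cfg$correction)
        list(metric = cp$metric, own = c(m$numerator, m$denominator),
             published = c(cp$successes, cp$total),
             chi2_stat = res$chi2_stat, p_value = res$p_value)
      })
  })

  bundle <- list(cohort = cohort, metrics = eval_out$metrics,
                 confusion = eval_out$cts, resection = eval_out$resection,
                 curves = curve_out, comparisons = comparisons)
  if (!is.null(cfg$out_dir))
    bundle$paths <- .stage("write", .write_bundle(bundle, cfg))
  invisible(bundle)
}

#' @rdname run_pipeline
#' @param path Path to a YAML (`.yml`/`.yaml`) or JSON config file.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
}

.write_bundle <- function(bundle, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(cfg$out_dir, ...)
  paths <- character(0)
  write_nodule_table(bundle$cohort, p("nodules.tsv"))
  utils::write.table(bundle$metrics, p("metrics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  jsonlite::write_json(bundle$metrics, p("metrics.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  paths <- c(p("nodules.tsv"), p("metrics.tsv"), p("metrics.json"))
  for (cl in names(bundle$curves)) {
    nm <- sub("_call$", "", cl)
    cv <- bundle$curves[[cl]]
    utils::write.table(as.data.frame(cv$curve), p(sprintf("curves_%s.tsv", nm)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    rec <- cv$recommendation
    jsonlite::write_json(
      c(unclass(rec), list(npv_crossover = as.numeric(cv$npv_crossover),
                           ppv_crossover = as.numeric(cv$ppv_crossover))),
      p(sprintf("recommendation_%s.json", nm)),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, p(sprintf("curves_%s.tsv", nm)),
               p(sprintf("recommendation_%s.json", nm)))
  }
  if (!is.null(bundle$comparisons)) {
    jsonlite::write_json(bundle$comparisons, p("comparisons.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, p("comparisons.json"))
  }
  cfg_file <- p("config_echo.json")
  jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1))], cfg_file,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  info <- list(package = "thyrostrat",
               version = as.character(utils::packageVersion("thyrostrat")),
               seed = cfg$seed,
               config_md5 = unname(tools::md5sum(cfg_file)))
  jsonlite::write_json(info, p("run_info.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  summary_lines <- c(
    sprintf("thyrostrat %s pipeline bundle", info$version),
    sprintf("cohort: %d nodules (%d resected)", nrow(bundle$cohort),
            sum(bundle$cohort$resected)),
    utils::capture.output(print(
      bundle$metrics[, c("classifier", "metric", "numerator", "denominator",
                         "point", "ci_low", "ci_high")],
      row.names = FALSE)),
    vapply(names(bundle$curves), function(cl) {
      r <- bundle$curves[[cl]]$recommendation
      sprintf("%s: recommended mode %s at ROM %.1f%%",
              sub("_call$", "", cl), r$mode, 100 * r$rom_used)
    }, character(1))
  )
  writeLines(summary_lines, p("summary.txt"))
  paths <- c(paths, cfg_file, p("run_info.json"), p("summary.txt"))
  paths
}
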