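#' Expected predictive values at a given prevalence
#'
#' For a test with fixed sensitivity and specificity, Bayes' theorem gives
#' the predictive values as functions of disease prevalence `p`:
#'
#' \deqn{PPV = \frac{sens \cdot p}{sens \cdot p + (1-spec)(1-p)}, \qquad
#'       NPV = \frac{spec (1-p)}{spec (1-p) + (1-sens) p}.}
#'
#' The boundary cases are handled by their limits: `PPV(1) = 1` and
#' `NPV(0) = 1`; likewise a perfectly specific test has `PPV` identically
#' 1 and a perfectly sensitive one `NPV` identically 1. An operating
#' point at which the value is undefined everywhere — a test that never
#' calls positive (`sens = 0, spec = 1`) has no PPV, one that never calls
#' negative (`sens = 1, spec = 0`) no NPV — raises an undefined-value
#' error. Vectorized over `p`.
#'
#' @param sens,spec Sensitivity and specificity, fractions in `[0, 1]`.
#' @param p Prevalence of disease, fraction(s) in `[0, 1]`.
#' @return Fraction(s) in `[0, 1]`.
#' @export
#' @examples
#' expected_ppv(0.884, 0.533, 0.741)
#' expected_npv(0.884, 0.533, 0.337)
expected_ppv <- function(sens, spec, p) {
  .check_fraction(sens, "sens"); .check_fraction(spec, "spec")
  .check_fraction(p, "p", vector_ok = TRUE)
  if (sens == 0 && spec == 1)
    stop("expected PPV undefined: test is never positive at this operating point",
         call. = FALSE)
  if (spec == 1) return(rep(1, length(p)))  # limit: no false positives
  num <- sens * p
  den <- num + (1 - spec) * (1 - p)
  ifelse(p == 1, 1, num / den)
}

#' @rdname expected_ppv
#' @export
expected_npv <- function(sens, spec, p) {
  .check_fraction(sens, "sens"); .check_fraction(spec, "spec")
  .check_fraction(p, "p", vector_ok = TRUE)
  if (sens == 1 && spec == 0)
    stop("expected NPV undefined: test is never negative at this operating point",
         call. = FALSE)
  if (sens == 1) return(rep(1, length(p)))  # limit: no false negatives
  num <- spec * (1 - p)
  den <- num + (1 - sens) * p
  ifelse(p == 0, 1, num / den)
}

.check_fraction <- function(x, name, vector_ok = FALSE) {
  if (!vector_ok && length(x) != 1L)
    stop("'", name, "' must be a single number", call. = FALSE)
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
    stop("'", name, "' must be in [0, 1]", call. = FALSE)
}

#' Expected PPV/NPV over the prevalence range
#'
#' Evaluates [expected_ppv()] and [expected_npv()] on a prevalence grid
#' for a fixed operating point, producing the curves used to decide
#' between rule-in and rule-out deployment of a molecular test. PPV is
#' non-decreasing and NPV non-increasing in prevalence.
#'
#' @inheritParams expected_ppv
#' @param grid Increasing prevalence grid in `[0, 1]`; default 1001
#'   equally spaced points.
#' @return A data frame of class `"prevalence_curve"` with columns `p`,
#'   `ppv`, `npv` and attributes `sens`, `spec`.
#' @export
#' @examples
#' pc <- prevalence_curve(0.930, 0.400)
#' head(pc)
prevalence_curve <- function(sens, spec, grid = seq(0, 1, length.out = 1001)) {
  .check_fraction(sens, "sens"); .check_fraction(spec, "spec")
  if (is.unsorted(grid, strictly = TRUE))
    stop("'grid' must be strictly increasing", call. = FALSE)
  out <- data.frame(p = grid,
                    ppv = expected_ppv(sens, spec, grid),
                    npv = expected_npv(sens, spec, grid))
  attr(out, "sens") <- sens
  attr(out, "spec") <- spec
  class(out) <- c("prevalence_curve", "data.frame")
  out
}

#' @export
plot.prevalence_curve <- function(x, ...) {
  graphics::plot(x$p, x$ppv, type = "l", col = "#2166AC", lwd = 2,
                 xlab = "prevalence of malignancy",
                 ylab = "expected predictive value", ylim = c(0, 1), ...)
  graphics::lines(x$p, x$npv, col = "#B2182B", lwd = 2)
  graphics::legend("right", c("PPV", "NPV"), col = c("#2166AC", "#B2182B"),
                   lwd = 2, bty = "n")
  invisible(x)
}

#' Prevalence at which NPV (or PPV) crosses a target
#'
#' `npv_crossover()` returns the largest prevalence `p*` at which the
#' expected NPV still meets `target`; for `p <= p*`, `NPV(p) >= target`.
#' Closed form:
#' \deqn{p^* = \frac{(1-t)\,spec}{(1-t)\,spec + t\,(1-sens)}.}
#' `ppv_crossover()` is the symmetric rule-in counterpart: the smallest
#' prevalence at which expected PPV reaches `target`,
#' \deqn{p^* = \frac{t\,(1-spec)}{t\,(1-spec) + (1-t)\,sens}.}
#'
#' Degenerate operating points (`sens = 1` for NPV, `spec = 1` for PPV)
#' make the predictive value identically 1; the crossover is then the
#' whole range and the returned value (1 resp. 0) carries a
#' `degenerate = TRUE` attribute.
#'
#' @inheritParams expected_ppv
#' @param target Target predictive value in `(0, 1)`.
#' @return The crossover prevalence in `[0, 1]`.
#' @export
#' @examples
#' npv_crossover(38/43, 8/15, 0.90)  # ~0.338
#' npv_crossover(40/43, 6/15, 0.90)  # ~0.389
npv_crossover <- function(sens, spec, target = 0.90) {
  .check_fraction(sens, "sens"); .check_fraction(spec, "spec")
  stopifnot(length(target) == 1L, target > 0, target < 1)
  if (sens == 1)
    return(structure(1, degenerate = TRUE))
  p <- (1 - target) * spec / ((1 - target) * spec + target * (1 - sens))
  unname(p)
}

#' @rdname npv_crossover
#' @export
ppv_crossover <- function(sens, spec, target = 0.75) {
  .check_fraction(sens, "sens"); .check_fraction(spec, "spec")
  stopifnot(length(target) == 1L, target >= 0, target < 1)
  if (target == 0) return(0)
  if (spec == 1)
    return(structure(0, degenerate = TRUE))
  p <- target * (1 - spec) / (target * (1 - spec) + (1 - target) * sens)
  unname(p)
}

#' Recommend rule-in / rule-out deployment at an observed ROM
#'
#' A molecular test earns a *rule-out* role when its expected NPV at the
#' population's risk of malignancy meets the NPV target (a negative
#' result safely defers surgery), and a *rule-in* role when its expected
#' PPV meets the PPV target (a positive result justifies surgery). In
#' high-ROM settings the same operating point that rules out at 20-30%
#' prevalence can only rule in.
#'
#' There is an established 0.90 convention for the rule-out NPV target;
#' no comparable consensus exists for rule-in, so the PPV target defaults
#' to 0.75 and both are configurable.
#'
#' @inheritParams expected_ppv
#' @param rom The prevalence (risk of malignancy) at which the test will
#'   operate, fraction in `(0, 1)`.
#' @param npv_target,ppv_target Decision thresholds.
#' @return An object of class `"mode_recommendation"`: list with `mode`
#'   (`"rule_in"`, `"rule_out"`, `"both"`, `"neither"`), `rom_used`,
#'   `ppv_at_rom`, `npv_at_rom`, `ppv_target`, `npv_target`.
#' @export
#' @examples
#' recommend_mode(0.884, 0.533, rom = 0.741)
#' recommend_mode(0.884, 0.533, rom = 0.20)
recommend_mode <- function(sens, spec, rom, npv_target = 0.90,
                           ppv_target = 0.75) {
  .check_fraction(sens, "sens"); .check_fraction(spec, "spec")
  .check_fraction(rom, "rom")
  ppv <- expected_ppv(sens, spec, rom)
  npv <- expected_npv(sens, spec, rom)
  rule_in <- ppv >= ppv_target
  rule_out <- npv >= npv_target
  mode <- if (rule_in && rule_out) "both"
          else if (rule_in) "rule_in"
          else if (rule_out) "rule_out"
          else "neither"
  structure(list(mode = mode, rom_used = rom, ppv_at_rom = ppv,
                 npv_at_rom = npv, ppv_target = ppv_target,
                 npv_target = npv_target),
            class = "mode_recommendation")
}

#' @export
print.mode_recommendation <- function(x, ...) {
  cat(sprintf(
    "At ROM %.1f%%: expected PPV %.1f%% (target %.0f%%), expected NPV %.1f%% (target %.0f%%)\n",
    100 * x$rom_used, 100 * x$ppv_at_rom, 100 * x$ppv_target,
    100 * x$npv_at_rom, 100 * x$npv_target))
  cat("Recommended deployment: ", gsub("_", "-", x$mode), "\n", sep = "")
  invisible(x)
}
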