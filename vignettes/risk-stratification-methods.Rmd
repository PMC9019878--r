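---
title: "Methods: molecular risk stratification of indeterminate thyroid nodules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: molecular risk stratification of indeterminate thyroid nodules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thyrostrat)
```

## The problem

Roughly a fifth of thyroid fine-needle aspirations return an indeterminate
cytology (Bethesda category III, AUS/FLUS, or IV, FN/SFN): not clearly benign,
not clearly malignant. Molecular testing of the aspirate — point mutations,
indels, gene fusions, expression profiles — is used to reclassify these
nodules. Whether a molecular test should be deployed as a *rule-out* test
(negative result defers surgery) or a *rule-in* test (positive result
justifies it) is not a property of the assay alone: by Bayes' theorem the
predictive values depend on the prevalence of malignancy (the ROM, risk of
malignancy) in the population being tested, and the ROM of resected
indeterminate nodules differs several-fold between practice settings (roughly
10–40% in North American series versus above 70% in strict-triage Asian
settings).

`thyrostrat` implements the full analysis chain for this question:

1. a data model for molecular alterations with a common-variant filter and
   risk tiers,
2. an additive genomic-classifier scoring/interpretation layer,
3. a seeded synthetic-cohort generator,
4. diagnostic-performance estimation against histopathology, and
5. prevalence-projected expected-PPV/NPV decision analysis.

## The interpretation layer

Two classifiers are modelled, mirroring the two families of commercial
assays:

* **Expression (RNA) classifier.** An upstream expression model produces a
  score in `[0, 100]`; scores strictly above the threshold (default **10%**)
  are called positive. The expression model itself (an SVM over transcript
  panels in the assays this emulates) is out of scope: the score is an input
  column in real-data mode and a simulated quantity in synthetic mode. The
  threshold convention is ambiguous in parts of the literature between a
  per-alteration and a per-nodule reading; this package implements a
  per-nodule score threshold and does not let the per-alteration reading leak
  into any other computation.

* **Genomic (DNA-RNA, "GC") classifier.** Each detected alteration carries a
  percentage value reflecting the strength of its association with
  malignancy; the per-nodule score is the combination of these values and is
  positive strictly above the threshold (default **70%**; the threshold
  itself is negative).

Two combination rules are provided. `saturating_sum` — the sum of the values
capped at 100 — is the default because the published description of the score
is literally a sum of percentages; the cap is required for the result to
remain a percentage. `noisy_or` (`100·(1 − Π(1 − v/100))`) is offered as a
smooth alternative that treats each alteration as independent evidence; the
two rules agree exactly on single-alteration nodules. Neither dominates the
other in general, which is why no such ordering is asserted anywhere.

### Weights

No published per-alteration values exist for the assay family this package
models, so the default weight table is the package's own calibration and is
explicitly configurable (TSV, columns `gene`, `kind`, `detail`, `weight`).
The defaults — BRAF V600E 95, TERT 90, any fusion 90, RAS family 60,
BRAF K601E 55, expression flag 75, default 20 — encode the qualitative
pattern reported across resected indeterminate cohorts: high-risk
alterations are individually decisive at the 70% threshold, RAS-like
mutations alone are not, and combinations accumulate. Lookup is total and
deterministic with most-specific-match-first precedence
`(gene, detail)` > `(gene, kind)` > `gene` > `kind` > default, so V600E and
K601E can carry different weights on the same gene.

### Common-variant filter and risk tiers

Variants with a known population frequency strictly above 0.1% are removed
before scoring (the conventional common-SNP cutoff); alterations with
*unknown* frequency are retained, since only variants known to be common are
uninformative. The filter is idempotent and order-preserving.

Risk tiers partition alterations into `high_risk` (BRAF V600E, TERT, any
fusion — near-deterministic markers of malignancy in this setting),
`ras_like` (NRAS/HRAS/KRAS, BRAF K601E — follicular-patterned neoplasia,
not specific for malignancy) and `other`. The tier map uses the same
precedence rules as the weight table.

## Diagnostic-performance estimation

Histopathology of resected nodules is the gold standard. Histologic
borderline entities (NIFTP, WT-UMP) sit between benign and malignant; the
**borderline policy** is therefore an explicit parameter on every
truth-dependent computation. The default `as_malignant` counts them as
disease-positive (they are pre-malignant lesions managed surgically);
`as_benign` is the sensitivity analysis. ROM under `as_malignant` dominates
ROM under `as_benign` by construction.

Proportions are reported with **Wilson score** intervals by default — the
stated method of the source analyses and the better-behaved interval near
boundaries — with the continuity-corrected Wald interval (`wald_cc`) offered
as a second dialect because some published interval bounds in this
literature follow it (e.g. 6/15 gives 19.8–64.3% under Wilson but 11.9–68.1%
under Wald+CC). Published bounds in this field match neither dialect
consistently, so no attempt is made to reproduce printed CI bounds; every
report names the dialect it used. Metrics with zero denominators raise
errors naming the metric rather than returning `NaN`.

Cross-study 2×2 comparisons use the Pearson chi-squared statistic without
continuity correction by default (this reproduces the printed comparison
regime of the published cross-study table; Yates is a flag). AUC is the
Mann–Whitney statistic computed via midranks, identical to pair enumeration
with ties counted one half.

One count discrepancy in the source material is carried, not resolved: the
published per-histology listing implies 8 benign GC-positive nodules
(46 positives in total), while the published performance table prints
PPV = 84.4% (38/45) and NPV = 61.5% (8/13), implying 7 false positives.
The shipped per-nodule table reproduces the per-histology listing; the four
GC operating-point metrics are therefore anchored to the published confusion
counts (tp = 38, fp = 7, tn = 8, fn = 5) where the two disagree. Sensitivity
(38/43) agrees between the two sources.

The RAS-alone summary follows the narrower published definition: among
nodules whose detected alterations are RAS-family mutations only
(NRAS/HRAS/KRAS by default, configurable via `ras_genes`), the fraction with
malignant or borderline histology. BRAF K601E — RAS-like in tier — is
excluded from this stratum by default because the source analyses report it
separately; including it would change the stratum from 10 to 12 nodules in
the shipped cohort.

## Prevalence-projected decision analysis

For fixed sensitivity and specificity,

$$\mathrm{PPV}(p) = \frac{S\,p}{S\,p + (1-C)(1-p)}, \qquad
  \mathrm{NPV}(p) = \frac{C\,(1-p)}{C\,(1-p) + (1-S)\,p},$$

with `S` sensitivity, `C` specificity and `p` the prevalence. Curves are
evaluated on 1001 equally spaced prevalence points with endpoints set by
their limits (no division at the boundary); degenerate operating points
(perfect sensitivity or specificity) return the constant limit and are
flagged. The crossover prevalences have closed forms,

$$p^{*}_{\mathrm{NPV}} = \frac{(1-t)\,C}{(1-t)\,C + t\,(1-S)}, \qquad
  p^{*}_{\mathrm{PPV}} = \frac{t\,(1-C)}{t\,(1-C) + (1-t)\,S},$$

and are verified against numeric root-finding to 1e-9 in the test suite.

The mode recommendation applies two thresholds at the cohort's own ROM: a
rule-out flag when expected NPV ≥ 0.90 (the established convention for
deferring surgery on a negative test) and a rule-in flag when expected
PPV ≥ 0.75. No numeric rule-in consensus exists in this literature; 0.75 was
chosen once as a value comfortably below the PPVs (0.82–0.84) that motivated
rule-in deployment in the high-ROM setting this package models, and both
thresholds are arguments. At the shipped cohort's operating points the
rule-out NPV target is reached only below ≈ 34% (GC) / ≈ 39% (RNA)
prevalence; one published narrative quotes a single crossover of 30.9%,
which is not derivable from any printed operating-point pair and is
deliberately not hard-coded or targeted anywhere in this package.

```{r curves, fig.width = 6, fig.height = 4}
plot(prevalence_curve(38 / 43, 8 / 15))
recommend_mode(38 / 43, 8 / 15, rom = rom(resected_cohort())$point)
```

## The synthetic cohort generator

`generate_cohort()` draws nodules from a fully specified generative model so
every downstream stage is testable without access to patient data:

* latent class `benign`/`borderline`/`malignant` (defaults 15/58, 10/58,
  33/58 — the resected-cohort mix of the high-ROM setting emulated),
  histologic subtype within class, Bethesda category (62/38 III/IV) and
  log-normal nodule size (median 1.0 cm, IQR ≈ 0.7–1.5);
* per-alteration independent Bernoulli draws with class-conditional
  frequencies read off the published histology-by-alteration listing (e.g.
  BRAF V600E in 5/33 malignant and nowhere else, RAS in 2/15 benign, 3/10
  borderline, 5/33 malignant);
* classifier scores from class-conditional **Beta distributions calibrated
  to the configured operating point**: one shape fixed at 2, the other
  solved with `uniroot` so that the disease-positive class exceeds the
  threshold with probability `target_sens` and the benign class stays at or
  below it with probability `target_spec` (achieved tail probabilities match
  to 1e-6; targets of exactly 0 or 1 are infeasible for any Beta law and
  raise a calibration error);
* borderline nodules score from the disease-positive distribution by
  default (most published borderline nodules test positive); a separate
  Beta is configurable;
* resection as a Bernoulli draw given the GC call (defaults 0.43 positive /
  0.35 negative — the published "management ignores the molecular result"
  regime), with histology revealed only for resected nodules unless
  `reveal_unresected = TRUE`.

The config seed fixes the cohort bit-for-bit through a single global RNG
stream, and `write_cohort_bundle()` serializes the config beside the data.

What the generator does **not** emulate: co-occurrence structure between
alterations (the one published TERT+BRAF V600E double carrier is not a
product of independent Bernoullis), any dependence of score on the specific
alteration profile (scores and alterations are conditionally independent
given class), within-patient correlation of multiple nodules, and
verification bias beyond the explicit call-dependent resection probability.
Passing parameter-recovery tests on this generator therefore shows the
estimators are correct under the stated model, not that the model captures
every feature of real cohorts.

## Problem sizes and numerical choices

The test suite sizes its simulations to be decisive yet quick: parameter
recovery uses 500 replicates of n = 5000 fully resected cohorts (Wilson CI
coverage of both operating-point parameters is required to reach 93%;
the analytically expected coverage under these conditions is 95.0%);
Wilson coverage itself is checked with 10,000 binomial replicates at
p = 0.3, n = 50; the null resection-rate regime uses 120 replicates of
n = 600. Oracle-equivalence checks (chi-squared, AUC, crossovers) run on
1000, 50 and 50 random instances respectively. The Bayes identity
`PPV = expected_ppv(sens, spec, prev)` holds to 1e-12 on every confusion
table, being algebraic.

Tie-breaks and degenerate inputs: the positivity thresholds are strict
(`score > threshold`); AUC ties count one half; empty alteration lists score
0; empty cohorts produce zero-count confusion tables but undefined metrics
raise; Wilson bounds at k = 0 and k = n are pinned to exactly 0 and 1 against
floating-point drift.

## The shipped cohort table

`resected_cohort()` loads a 58-nodule per-nodule transcription of a
published resected indeterminate cohort (15 benign / 10 borderline / 33
malignant; 49 RNA-positive; 46 GC-positive in the per-histology listing).
The per-nodule rows reproduce the published group totals exactly;
identifiers, Bethesda categories and sizes are synthetic placeholders, and
the assignment of alterations to individual nodules within a histology group
is arbitrary — every shipped summary is invariant to it.
`indeterminate_cohort()` extends it to the full 140-nodule testing cohort
with unresected records whose per-classifier margins match the published
resection analysis exactly; the unpublished joint RNA×GC call distribution
of unresected nodules uses the maximal-overlap assignment.

## Known limitations

* The alteration text grammar cannot distinguish hyphenated HGNC symbols
  (e.g. NKX2-1) from fusion pairs; such genes must enter via the TSV/VCF
  path with an explicit kind.
* The expression classifier is a threshold on an externally supplied or
  simulated score; nothing about its internals is modelled.
* The default weight table is a documented stand-in calibrated to reproduce
  a qualitative call pattern, not a fitted model.
* Printed confidence-interval bounds from the emulated literature are not
  reproduced (their dialect is internally inconsistent); point estimates
  and count ratios are.
* The bootstrap-free AUC comparison between two classifiers is out of
  scope; only single-classifier AUC is provided.
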