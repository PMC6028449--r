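---
title: "Screening for advanced Parkinson's disease: the CDEPA rule engine, its validation statistics, and the synthetic-cohort model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CDEPA methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdepa)
```

## The instrument and its rule semantics

The CDEPA questionnaire screens for advanced Parkinson's disease (APD)
with yes/no symptom items in six domains (general characteristics,
disability, treatment-related motor, disease-related motor, disease-related
non-motor, neuropsychiatric/cognitive). Each item carries a certainty tier
— *definitive*, *probable* or *possible* — and three rules map a patient's
answers to a case-level certainty:

1. any definitive-tier symptom present ⟹ case **definitive**;
2. probable-tier symptoms present in at least two *distinct* domains ⟹
   case **definitive**;
3. a possible-tier symptom in a disease-related domain together with a
   possible-tier symptom in the neuropsychiatric/cognitive domain ⟹ case
   **probable**.

Otherwise the case inherits the highest tier among present symptoms
(probable, possible, or none). The binary screen calls a patient
*advanced* iff the case level reaches `diagnosis_threshold`
(default **definitive**; setting it to probable is supported for
sensitivity analyses).

Three semantic decisions deserve explicit statement because the flattened
published table leaves them open:

* **Single-pass promotion.** The promotions operate on *symptom-tier*
  certainties only. A case promoted to probable by rule 3 contributes no
  "probable symptoms" to rule 2; there is no fixed-point iteration. Rule 2
  reads "two *symptoms* of the probable level", which fixes this reading.
* **Column ambiguities.** The domain/tier placement of five items
  (symptomatic dysautonomia, excessive daytime somnolence, moderate–severe
  apathy, psychotic symptoms, mild cognitive impairment) cannot be
  recovered unambiguously from the typeset table. The packaged rule map
  assigns apathy to the probable tier and the other four to the possible
  tier, consistent with the instrument's structure, and flags every such
  entry with a `column-unresolved` comment in
  `inst/extdata/cdepa_table1.yaml`. Because the rule map is data, a user
  can correct any assignment against the original consensus instrument
  without touching code.
* **Missing answers** coerce to "no" with a warning (presence must be
  affirmed; the screening-conservative alternative of coercing to "yes"
  would manufacture symptoms), or raise an error in strict mode. The
  off-time/on-time >25% thresholds inside two item definitions are treated
  as already-adjudicated yes/no inputs; the engine computes no diary
  percentages.

The engine is evaluated in two interchangeable implementations — a
per-patient reference path (`classify_case()`) and a vectorized cohort
path (`classify_cohort()`) — whose equality over random response patterns,
together with exhaustive agreement with a literal clause transcription
over all $2^8$ patterns of a reduced rule set, is part of the test suite.
Monotonicity (flipping any answer from "no" to "yes" never lowers the case
level) holds by construction and is property-tested.

## Scale scoring

SCOPA-Motor, NMSS, CISI-PD, CGIS/PGIS and Hoehn–Yahr staging are scored
with range validation and no imputation: an instrument with any missing
item yields an `NA` score flagged incomplete, since the study design
offers no basis for imputing clinician-rated items.

One layout choice is worth recording. The SCOPA-Motor is described as 21
items in three sections, yet its printed section ranges (0–42 examination,
0–21 ADL, 0–6 dyskinesias + 0–6 fluctuations) cannot arise from 21
uniformly 0–3-scored items. The scorer is therefore *range-driven*, and
the default column schema uses 14 + 7 + 2 + 2 item scores of 0–3 so the
printed maxima hold exactly; the per-item labels are instrument data, not
code. Similarly, half-stages of the modified Hoehn–Yahr scale are rejected
because the validation design uses integer stages only.

The five-level clinical-judgment stage (initial, mild, moderate, advanced,
late-stage) binarizes with advanced + late-stage as the gold-standard
"advanced" class.

## Validation statistics

All 2×2 quantities derive from one `contingency_2x2(tp, fp, fn, tn)`
container: sensitivity, specificity, predictive values, accuracy,
false-positive/negative rates, and the binary-classifier AUC defined as
$(\mathrm{Se} + \mathrm{Sp})/2$ — the convention the validation design
itself names ("ROC analysis for binary classifiers"); a rank-based AUC is
deliberately not substituted. Zero-denominator statistics return `NA` with
a message while the remaining statistics are still computed.

Cohen's kappa uses $\kappa = (p_o - p_e)/(1 - p_e)$ with the
Fleiss–Cohen–Everitt large-sample variance for its standard error; the 95%
CI is reported for completeness but is not a quantity the validation
design specifies, so nothing downstream asserts it. Landis–Koch band edges
are applied to kappa rounded to two decimals, the precision at which the
bands are stated.

The Mann–Whitney U test is implemented in-package because its contract
here — mid-rank U, an *exact enumeration* two-sided p-value for
$\min(n_1, n_2) \le 8$ that remains valid under ties, and a tie- plus
continuity-corrected normal approximation otherwise — is not the behaviour
of `stats::wilcox.test` with tied data (which abandons exactness). The
approximate path is cross-checked against `wilcox.test`, and the exact
path against full permutation enumeration, in the tests. Kruskal–Wallis
delegates to `stats::kruskal.test` (with the degenerate all-tied case
defined as $H = 0$), Fisher's exact test to `stats::fisher.test` (whose
two-sided rule is the required hypergeometric sum), and Spearman's ρ is
the Pearson correlation of mid-ranks; each is still verified against a
first-principles oracle.

The Youden-optimal cutoff scans the rule "positive if score ≥ c" over
every observed score value and maximizes $J = \mathrm{Se} + \mathrm{Sp} -
1$, breaking ties toward the smallest cutoff; a single-valued score vector
returns that value with $J = 0$ and a warning rather than an error.

Power for the design's one-sample proportion test is the two-sided
normal-approximation power with boundaries
$p_0 \pm z_{1-\alpha/2}\sqrt{p_0(1-p_0)/n}$ evaluated under the
alternative's variance (both tails included). The design sentence this
implements is terse; the reading $p_0 = 0.25$, $p_1 = 0.40$, $n = 100$,
$\alpha = 0.05$ is the one standard formulation that yields the planned
0.91, and a Monte-Carlo exact-binomial oracle confirms the approximation
to within 0.02.

## The synthetic-cohort model

No patient data accompany the validation study, so the generator exists to
give every pipeline stage a realistic, fully seeded input. Its structure:

* **Hoehn–Yahr stage** drawn from the study frequencies
  (9.4/33.3/29.8/22.2/5.3%).
* **Latent severity** $s = \mathrm{HY} + U(-0.5, 0.5)$. The continuum is a
  working construct the study implies but never defines; uniform
  within-stage jitter is the weakest assumption that makes severity
  continuous while preserving stage ordering.
* **Clinical-judgment stage** from cutting $s + N(0, \sigma)$ at four
  thresholds. $\sigma = 0.70$ and thresholds $(1.147, 2.336, 3.213,
  4.717)$ were calibrated once (`scripts/calibrate.R`) so that large
  cohorts show stage marginals of $(.10, .274, .25, .30, .076)$ — hence a
  37.6% gold-standard advanced fraction — and a stage–HY Spearman ρ of
  ≈ 0.78, the study's reported coherence between clinical judgment and
  staging.
* **Symptom answers**: item $j$ is "yes" with probability
  $\mathrm{logit}^{-1}(\beta_j (s - m_j))$. Slopes are tier-wide
  (definitive 2.2, probable 1.8, possible 1.4 per severity unit — steep
  enough that definitive symptoms concentrate in late disease, shallow
  enough that every item retains variance at n = 5000 for parameter
  recovery). Midpoints are a tier base (definitive 3.90, probable 3.20,
  possible 3.00) plus fixed per-item offsets chosen a priori on clinical
  grounds (e.g. dementia and severe dysphagia rarer, ten-year evolution
  common). The two identifiable bases were grid-searched once so that
  large simulated cohorts reproduce a ~63.0% questionnaire-advanced
  fraction with confusion-cell proportions near (63, 46, 2, 62)/173; the
  achieved values (0.631 advanced, TP cell 0.355, FN 0.020) are frozen.
* **Scale scores** are drawn from group-conditional truncated normals
  (inverse-CDF truncation, integer rounding) keyed on the patient's
  *questionnaire* classification — matching how the study tabulates them —
  then decomposed into valid item scores, so every scored instrument
  satisfies its summation and range invariants exactly. For the NMSS the
  decomposition targets the drawn domain total with the nearest achievable
  severity×frequency products; the realised total may drift by a point or
  two, and the realised items are authoritative. Joint correlation among
  scales beyond the shared severity-through-classification pathway is not
  modelled (no covariance information exists to calibrate it). CGIS/PGIS
  group parameters are **extrapolations** — the study references but does
  not print them — anchored loosely to the reported CGIS cutoff of 6, and
  are marked as such in the config.
* **Rater noise**: a second administration flips each answer
  independently with probability 0.020 (calibrated to an inter-rater
  diagnosis kappa ≈ 0.88); a retest uses 0.028 (kappa ≈ 0.83).
* **Demographics** (age 68.4 ± 10.5, 40.4% women, duration 10.3 ± 5.8
  truncated at ≥ 2 years) are carried for realism; nothing downstream
  conditions on them, mirroring the validation analysis.

What passing simulator-based tests show — and what they do not: the
generator reproduces the *marginal and pairwise* structure the validation
relies on (stage distribution, confusion cells, stage–HY correlation,
reliability), so pipeline correctness and statistical plumbing are well
exercised. It does not reproduce patient-level phenomenology: symptom
co-occurrence beyond shared severity, scale-to-scale correlation at fixed
classification, informative missingness, or recruitment effects. Results
on real cohorts can therefore differ even if every property test passes.

```{r calibration, eval = FALSE}
cfg <- default_sim_config()
co <- simulate_cohort({cfg$n <- 10000L; cfg}, seed = 1)
mean(co$truth$gold_dx == "advanced")            # ~0.376
mean(co$classification$diagnosis == "advanced") # ~0.630
```

## Numerical and design choices

* Proportions are computed exactly from integer counts; printed-precision
  renderings (percentages to one decimal, kappa to two, round-half-up via
  R's `round`) appear only in `print` methods and report `rendered`
  blocks, never in stored values.
* Exact Mann–Whitney enumeration switches on at $\min(n_1,n_2) \le 8$
  (≤ 12 870 labelings), keeping the exact path affordable while covering
  the tie-heavy small samples where the normal approximation is worst.
* Tie-breaks: Youden cutoffs toward the smallest cutoff; `which.max`
  semantics make this deterministic.
* Degenerate inputs are contracts, not crashes: empty tables, single-class
  labels, constant vectors and all-tied groups each have a defined error
  or defined value documented on the operation.
* Problem sizes in the test suite (10 000-pattern monotonicity sweeps,
  n = 10 000 calibration cohorts, n = 5000 recovery cohorts, 50-seed
  cutoff sweeps) were chosen so the whole suite runs in well under a
  minute while keeping Monte-Carlo error far below every asserted
  tolerance.

## Known limitations

* The rule map's five `column-unresolved` tier assignments are editorial
  choices pending the original consensus instrument.
* The CISI-PD discrimination cutoff is *not* a sharp property of the
  simulated design: under the published group distributions (advanced
  13.0 ± 4.0, non-advanced 5.1 ± 3.2, n = 109/64) the theoretical Youden
  J at integer cutoffs 9 and 10 differs by ~0.001, an order of magnitude
  below the sampling noise of J at n = 173, so single-cohort Youden
  scans split between 9 and 10 across seeds. The package reports the
  modal cutoff across seeds and the full per-cutoff table rather than
  pretending the optimum is stable.
* Binary AUC = (Se+Sp)/2 is a definition choice matching the validation
  design, not an estimate of a rank AUC from graded scores.
* Inter-rater and test–retest kappas of the real study cannot be
  recomputed without the raw paired ratings; the generator treats them as
  calibration anchors, and reliability assertions are interval properties,
  not point reproductions.
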