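# cdepa

Rule-based screening for advanced Parkinson's disease (APD) and the
statistics to validate it.

Deciding when Parkinson's disease has become *advanced* matters clinically —
it is the point where conventional pharmacotherapy starts failing and
device-aided therapies (deep brain stimulation, apomorphine or intestinal
levodopa infusion) enter the picture — yet neurologists have no agreed
bedside criterion. The CDEPA questionnaire ("Cuestionario De Enfermedad de
Parkinson Avanzada") is a short screening checklist for exactly this
decision: a set of yes/no symptom items in six domains, each carrying a
*certainty tier* (definitive, probable, possible), with combination rules
that promote a case up the tiers. This package is for clinical researchers
and biostatisticians who want to apply the instrument to tabular cohort
data, audit or modify its rule map, and run the complete screening-test
validation analysis — or rehearse that analysis on synthetic cohorts before
any patient data exist.

## What is implemented

**The rule engine.** Symptoms live in an editable YAML rule map
(`inst/extdata/cdepa_table1.yaml`), not in code. A case is classified

- **definitive** if any definitive-tier symptom is present (severe
  disability requiring help for ADL, motor fluctuations with off time >25%
  with limitation, severe dysphagia, recurrent falls, or dementia), or if
  probable-tier symptoms span ≥ 2 distinct domains;
- **probable** if any probable-tier symptom is present, or a possible-tier
  symptom in a disease-related domain co-occurs with one in the
  neuropsychiatric/cognitive domain;
- **possible** if any possible-tier symptom is present; **none** otherwise.

The binary screen is *advanced* iff the case level reaches the configurable
threshold (definitive by default). Every classification carries its
evidence (the fired clause and contributing symptom ids).

**Clinical scales.** Range-validated scoring for Hoehn–Yahr staging,
SCOPA-Motor (sections 0–42 / 0–21 / 0–6 + 0–6, total 0–75), the Non-Motor
Symptoms Scale (30 items, item = severity 0–3 × frequency 1–4, nine
domains, total 0–360), CISI-PD (four items 0–6), CGIS/PGIS global
impressions, and binarization of the five-level clinical-judgment stage
(initial/mild/moderate → non-advanced; advanced/late-stage → advanced).

**Validation statistics.** For an index test against a gold standard with
counts (TP, FP, FN, TN):

    Se = TP/(TP+FN)   Sp = TN/(TN+FP)   PPV = TP/(TP+FP)   NPV = TN/(TN+FN)
    accuracy = (TP+TN)/n                AUC_binary = (Se+Sp)/2
    kappa = (p_o − p_e)/(1 − p_e)       Youden J = Se + Sp − 1

plus Landis–Koch interpretation bands for kappa, percent agreement,
Spearman's ρ on mid-ranks, Mann–Whitney U (exact enumeration for
min(n₁,n₂) ≤ 8, tie- and continuity-corrected normal approximation
otherwise), Kruskal–Wallis, Fisher's exact test, Youden-optimal cutoff
scanning, and the normal-approximation power of the two-sided one-sample
proportion test.

**Synthetic cohorts.** A seeded generator in which a latent severity
(HY stage + within-stage jitter) drives the clinical-judgment stage, the
per-symptom logistic response models, and — through the resulting
questionnaire classification — group-conditional scale scores. Defaults
are calibrated study conditions (see `vignettes/cdepa-methods.Rmd`).

## Worked example

Reproduce the validation statistics from the published 2×2 classification
(63 true positives, 46 false positives, 2 false negatives, 62 true
negatives):

```r
library(cdepa)
t2 <- contingency_2x2(tp = 63, fp = 46, fn = 2, tn = 62)
diagnostic_performance(t2)
#> Sensitivity was 96.9%; specificity was 57.4%; false positives were 42.6%;
#> false negatives were 3.1%; positive predictive value was 57.8%;
#> negative predictive value was 96.9%; total accuracy was 72.3%
#> Area under the curve (binary classifier): 77.2%
cohen_kappa(t2)
#> Cohen's kappa 0.48 (moderate), 95% CI 0.37-0.59, n = 173
#>   observed agreement 72.3%, expected 46.8%
```

The screen misses almost no truly advanced patient (Se 96.9%, NPV 96.9%)
at the cost of many false alarms (Sp 57.4%) — the profile one wants in a
screening instrument — and agrees moderately (κ = 0.48) with the
clinician's gold standard.

Classify a cohort and run the whole pipeline on synthetic data:

```r
cohort  <- simulate_cohort(default_sim_config(), seed = 1)
dataset <- as_study_dataset(cohort)       # adds 2nd-rater + retest blocks
report  <- run_validation(dataset)
report
#> CDEPA validation report (n = 173 )
#> ...
#> inter-rater: agreement 96.5%, kappa 0.92 (almost perfect)
#> test-retest: agreement 96.0%, kappa 0.90 (almost perfect)
#> CISI-PD Youden cutoff: >= 10; CGIS: >= 6
write_report(report, "report.json")
```

A thin command-line front end with the same operations ships in
`inst/cli/cdepa.R` (`classify`, `validate`, `stats`, `simulate`,
`replicate-paper`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","cdepa.R",package="cdepa"))')" \
  stats --table 63,46,2,62
```

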