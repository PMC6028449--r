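# Study-replication pipeline: assemble a dataset (simulated or read from
# CSV), classify with the rule engine, binarize the gold standard, compute
# every validation statistic and render a structured report.

#' Assemble a study dataset
#'
#' Bundles the components of a validation study. Patient-id sets must be
#' consistent across all components present.
#'
#' @param responses wide questionnaire response data.frame (rater #1).
#' @param scales item-level scales data.frame (layout of [read_scales()]),
#'   including `hy` and `clinical_stage`.
#' @param rater2 optional second-rater response data.frame.
#' @param retest optional retest response data.frame.
#' @return `cdepa_dataset` object.
#' @export
study_dataset <- function(responses, scales, rater2 = NULL, retest = NULL) {
  ids <- sort(as.character(responses$patient_id))
  check <- function(comp, what) {
    if (is.null(comp)) return(invisible())
    if (!identical(sort(as.character(comp$patient_id)), ids))
      stop("patient ids of `", what,
           "` do not match the responses component", call. = FALSE)
  }
  check(scales, "scales")
  check(rater2, "rater2")
  check(retest, "retest")
  structure(list(responses = responses, scales = scales,
                 rater2 = rater2, retest = retest),
            class = "cdepa_dataset")
}

#' Convert a simulated cohort into a study dataset
#'
#' Optionally attaches simulated second-rater and retest response blocks
#' drawn with the configuration's calibrated flip probabilities.
#'
#' @param cohort a `cdepa_cohort` from [simulate_cohort()].
#' @param rater2,retest logical; simulate the corresponding reliability
#'   block.
#' @param seed base seed for the reliability blocks (offset internally so
#'   the two blocks use distinct streams).
#' @return `cdepa_dataset`.
#' @export
as_study_dataset <- function(cohort, rater2 = TRUE, retest = TRUE,
                             seed = cohort$seed + 1000L) {
  stopifnot(inherits(cohort, "cdepa_cohort"))
  cfg <- cohort$config
  study_dataset(
    responses = cohort$responses,
    scales = cohort$scales,
    rater2 = if (rater2)
      simulate_second_rater(cohort, cfg$rater_flip_prob, seed = seed),
    retest = if (retest)
      simulate_second_rater(cohort, cfg$retest_flip_prob, seed = seed + 1L))
}

#' Read a study dataset from CSV files
#'
#' @param responses_path,scales_path required component paths.
#' @param rater2_path,retest_path optional reliability component paths.
#' @param rules optional rule set for immediate schema checking of response
#'   files.
#' @return `cdepa_dataset`.
#' @export
read_dataset <- function(responses_path, scales_path, rater2_path = NULL,
                         retest_path = NULL, rules = NULL) {
  study_dataset(
    responses = read_responses(responses_path, rules),
    scales = read_scales(scales_path),
    rater2 = if (!is.null(rater2_path)) read_responses(rater2_path, rules),
    retest = if (!is.null(retest_path)) read_responses(retest_path, rules))
}

#' Write a study dataset to CSV files
#'
#' @param dataset `cdepa_dataset`.
#' @param prefix output path prefix; writes `<prefix>_responses.csv`,
#'   `<prefix>_scales.csv` and, when present, `<prefix>_rater2.csv` /
#'   `<prefix>_retest.csv`.
#' @return Named vector of written paths, invisibly.
#' @export
write_dataset <- function(dataset, prefix) {
  stopifnot(inherits(dataset, "cdepa_dataset"))
  paths <- c(responses = paste0(prefix, "_responses.csv"),
             scales = paste0(prefix, "_scales.csv"))
  utils::write.csv(dataset$responses, paths["responses"], row.names = FALSE)
  utils::write.csv(dataset$scales, paths["scales"], row.names = FALSE)
  for (comp in c("rater2", "retest")) {
    if (!is.null(dataset[[comp]])) {
      p <- paste0(prefix, "_", comp, ".csv")
      utils::write.csv(dataset[[comp]], p, row.names = FALSE)
      paths[comp] <- p
    }
  }
  invisible(paths)
}

# simple stable fingerprint for provenance (djb2 over the serialized text)
.fingerprint <- function(x) {
  s <- paste(utils::capture.output(utils::str(x)), collapse = "\n")
  h <- 5381
  for (v in utf8ToInt(s)) h <- (h * 33 + v) %% 2^31
  sprintf("%08x", h)
}

.reliability_block <- function(rules, dx1, responses2, what) {
  cl2 <- classify_cohort(rules, responses2)
  dx2 <- cl2$diagnosis[match(names(dx1), cl2$patient_id)]
  tab <- table(factor(dx1, c("advanced", "non-advanced")),
               factor(dx2, c("advanced", "non-advanced")))
  list(component = what,
       percent_agreement = percent_agreement(tab),
       kappa = cohen_kappa(tab))
}

#' Run the full validation analysis
#'
#' Classifies the cohort with the rule engine, binarizes the gold-standard
#' clinical stage, and computes the whole validation battery: the 2x2
#' contingency table and diagnostic performance, Cohen's kappa against the
#' gold standard, Fisher's exact test of the table, Mann-Whitney group
#' comparisons of every scored scale between the questionnaire's advanced
#' and non-advanced groups, Youden cutoffs for the CISI-PD total and CGIS,
#' and — when second-rater / retest response blocks are present —
#' inter-rater and test-retest agreement (percent agreement and kappa).
#' Components not supplied yield explicitly absent report sections, never
#' silent zeros.
#'
#' @param dataset a `cdepa_dataset`.
#' @param rules a [cdepa_ruleset()].
#' @return `cdepa_validation` object.
#' @export
run_validation <- function(dataset, rules = default_ruleset()) {
  stopifnot(inherits(dataset, "cdepa_dataset"),
            inherits(rules, "cdepa_ruleset"))
  classification <- classify_cohort(rules, dataset$responses)
  scored <- score_scales(dataset$scales)
  m <- match(classification$patient_id, scored$patient_id)
  if (anyNA(m)) stop("scales lack some response patients", call. = FALSE)
  scored <- scored[m, ]
  if (anyNA(scored$gold_dx))
    stop("missing gold-standard clinical stage", call. = FALSE)
  if (length(unique(scored$gold_dx)) < 2L)
    stop("gold standard is single-class; validation statistics degenerate",
         call. = FALSE)

  ct <- build_contingency(classification$diagnosis, scored$gold_dx)
  perf <- diagnostic_performance(ct)
  kap <- cohen_kappa(ct)
  fisher_p <- fisher_exact(ct)

  adv <- classification$diagnosis == "advanced"
  measures <- c("hy", "sms_examination", "sms_adl", "sms_dyskinesias",
                "sms_fluctuations", "sms_total",
                paste0("nmss_", names(nmss_domains())), "nmss_total",
                "cisi_total", "cgis", "pgis")
  group_tests <- do.call(rbind, lapply(measures, function(v) {
    x <- scored[[v]]
    gc <- mann_whitney_u(x[adv], x[!adv])
    data.frame(measure = v,
               mean_advanced = mean(x[adv]), sd_advanced = stats::sd(x[adv]),
               mean_non_advanced = mean(x[!adv]),
               sd_non_advanced = stats::sd(x[!adv]),
               U = gc$statistic, p_value = gc$p_value,
               stringsAsFactors = FALSE)
  }))

  cutoffs <- list(
    cisi_total = optimal_cutoff(scored$cisi_total, classification$diagnosis),
    cgis = optimal_cutoff(scored$cgis, classification$diagnosis))

  dx1 <- stats::setNames(classification$diagnosis, classification$patient_id)
  reliability <- list(
    inter_rater = if (!is.null(dataset$rater2))
      .reliability_block(rules, dx1, dataset$rater2, "inter-rater"),
    test_retest = if (!is.null(dataset$retest))
      .reliability_block(rules, dx1, dataset$retest, "test-retest"))

  structure(list(
    n = nrow(classification),
    classification = classification,
    contingency = ct,
    performance = perf,
    kappa = kap,
    fisher_p = fisher_p,
    stage_hy_rho = spearman_rho(
      match(scored$clinical_stage, clinical_stages()), scored$hy),
    group_tests = group_tests,
    cutoffs = cutoffs,
    reliability = reliability,
    provenance = list(
      package_version = as.character(utils::packageVersion("cdepa")),
      ruleset_fingerprint = .fingerprint(rules),
      n_symptoms = nrow(rules$symptoms))),
    class = "cdepa_validation")
}

#' @export
print.cdepa_validation <- function(x, ...) {
  cat("CDEPA validation report (n =", x$n, ")\n\n")
  print(as.matrix(x$contingency))
  cat("\n")
  print(x$performance)
  print(x$kappa)
  cat(sprintf("Fisher exact p = %.3g; Spearman rho(stage, HY) = %.2f\n",
              x$fisher_p, x$stage_hy_rho))
  for (rel in x$reliability) if (!is.null(rel))
    cat(sprintf("%s: agreement %.1f%%, kappa %.2f (%s)\n", rel$component,
                100 * rel$percent_agreement, rel$kappa$kappa,
                rel$kappa$landis_koch_label))
  cat(sprintf("CISI-PD Youden cutoff: >= %g; CGIS: >= %g\n",
              x$cutoffs$cisi_total$cutoff, x$cutoffs$cgis$cutoff))
  invisible(x)
}

#' @export
summary.cdepa_validation <- function(object, ...) {
  print(object)
  cat("\nGroup comparisons (questionnaire advanced vs non-advanced):\n")
  gt <- object$group_tests
  gt$p_value <- signif(gt$p_value, 3)
  for (cl in c("mean_advanced", "sd_advanced", "mean_non_advanced",
               "sd_non_advanced", "U"))
    gt[[cl]] <- round(gt[[cl]], 1)
  print(gt, row.names = FALSE)
  invisible(object)
}

#' Serialize a validation report to JSON
#'
#' Numbers are stored at full precision; a `rendered` block carries the
#' printed-precision strings (percentages to one decimal, kappa to two) so
#' the rounding policy never contaminates the stored values.
#'
#' @param report `cdepa_validation`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "cdepa_validation"))
  perf <- report$performance
  out <- list(
    n = report$n,
    contingency = list(tp = report$contingency$tp, fp = report$contingency$fp,
                       fn = report$contingency$fn, tn = report$contingency$tn),
    performance = perf[c("sensitivity", "specificity", "ppv", "npv",
                         "accuracy", "fp_rate", "fn_rate", "auc_binary")],
    kappa = report$kappa[c("kappa", "p_o", "p_e", "se", "ci95",
                           "landis_koch_label")],
    fisher_p = report$fisher_p,
    stage_hy_rho = report$stage_hy_rho,
    group_tests = report$group_tests,
    cutoffs = list(cisi_total = report$cutoffs$cisi_total$cutoff,
                   cgis = report$cutoffs$cgis$cutoff),
    reliability = lapply(report$reliability, function(rel) {
      if (is.null(rel)) return("absent")
      list(percent_agreement = rel$percent_agreement,
           kappa = rel$kappa$kappa, ci95 = rel$kappa$ci95)
    }),
    provenance = report$provenance,
    rendered = list(
      performance_summary = paste0(utils::capture.output(print(perf)),
                              collapse = " "),
      kappa = sprintf("%.2f (%s)", report$kappa$kappa,
                      report$kappa$landis_koch_label)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
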