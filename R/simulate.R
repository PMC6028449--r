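# Seeded synthetic-cohort generator.  A latent disease severity (Hoehn-Yahr
# stage plus continuous within-stage jitter) drives the clinical-judgment
# stage (ordinal cut of severity + Gaussian noise), the per-symptom
# questionnaire answers (logistic models in severity) and, through the
# resulting questionnaire classification, the clinical-scale scores
# (group-conditional truncated normals).  All defaults are frozen study
# conditions calibrated once by scripts/calibrate.R.

# achievable NMSS item scores (severity 0-3 x frequency 1-4) and one fixed
# factorization per score
.nmss_achievable <- c(0, 1, 2, 3, 4, 6, 8, 9, 12)
.nmss_sev_of  <- c(0, 1, 1, 1, 1, NA, 2, NA, 2, 3, NA, NA, 3)  # index score+1
.nmss_freq_of <- c(1, 1, 2, 3, 4, NA, 3, NA, 4, 3, NA, NA, 4)

# inverse-CDF truncated-normal draw, rounded to integer within [lo, hi]
.rtnorm_int <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  x <- stats::qnorm(stats::runif(n, plo, phi), mean, sd)
  pmin(hi, pmax(lo, round(x)))
}

# split integer totals (vector) into k items each 0..max_item, balanced
.split_items <- function(totals, k, max_item) {
  base <- totals %/% k
  rem <- totals %% k
  m <- matrix(base, nrow = length(totals), ncol = k)
  for (i in seq_len(k)) m[, i] <- m[, i] + (i <= rem)
  if (any(m > max_item)) stop("internal: item overflow in .split_items")
  m
}

# decompose target domain totals into k NMSS item scores drawn from the
# achievable set; totals may drift by a point or two, the realised domain
# score is always the sum of the realised items
.nmss_split <- function(totals, k) {
  ach <- .nmss_achievable
  mids <- utils::head(ach, -1) + diff(ach) / 2
  nearest <- function(v) ach[findInterval(v, mids) + 1L]
  remaining <- pmin(totals, 12 * k)
  m <- matrix(0L, nrow = length(totals), ncol = k)
  for (i in seq_len(k)) {
    ideal <- remaining / (k - i + 1)
    x <- nearest(ideal)
    over <- x > remaining
    if (any(over))
      x[over] <- ach[findInterval(remaining[over] + 1e-9, ach)]
    m[, i] <- x
    remaining <- remaining - x
  }
  m
}

#' Default calibrated simulation configuration
#'
#' The packaged study conditions: cohort size 173; Hoehn-Yahr stage
#' probabilities (9.4/33.3/29.8/22.2/5.3%); an ordinal stage model whose
#' noise and thresholds were calibrated once so that, in large cohorts, the
#' gold-standard advanced fraction is ~0.376 and Spearman rho between
#' clinical stage and HY is ~0.78; per-symptom logistic models in latent
#' severity calibrated so the questionnaire flags ~63% advanced with the
#' confusion structure of the validation study; group-conditional scale
#' models taken from the published advanced/non-advanced means and SDs
#' (CGIS/PGIS group parameters are extrapolations — the source table does
#' not print them — anchored to the reported CGIS cutoff of 6); rater and
#' retest answer-flip probabilities calibrated to inter-rater kappa ~0.88
#' and test-retest kappa ~0.83; demographics (age 68.4 +/- 10.5, 40.4%
#' women, duration 10.3 +/- 5.8 years).
#'
#' @return `cdepa_sim_config` object (a named list).
#' @export
default_sim_config <- function() {
  level_slope <- c(definitive = 2.2, probable = 1.8, possible = 1.4)
  base_mid <- c(definitive = 3.90, probable = 3.20, possible = 3.00)
  offsets <- c(
    disability_help_adl = -0.2, fluctuations_off25_limit = -0.1,
    severe_dysphagia = 0.3, recurrent_falls = 0.0, dementia = 0.4,
    evolution_10y = -0.6, disability_limit_no_help = -0.2,
    dyskinesia_on25 = 0.0, moderate_dysphagia = 0.2, freezing_gait = 0.0,
    hallucinations_no_insight = 0.4, apathy_moderate_severe = 0.1,
    dysarthria_moderate_severe = 0.0, postural_equilibrium = -0.3,
    symptomatic_dysautonomia = 0.0, daytime_somnolence = -0.2,
    chronic_hallucinations_insight = 0.3, psychotic_symptoms = 0.5,
    mild_cognitive_impairment = -0.1)
  rules <- default_ruleset()
  sy <- rules$symptoms
  slope <- unname(level_slope[sy$level])
  midpoint <- unname(base_mid[sy$level] + offsets[sy$id])
  symptom_models <- data.frame(
    id = sy$id, level = sy$level,
    intercept = -slope * midpoint, slope = slope,
    stringsAsFactors = FALSE)

  structure(list(
    n = 173L,
    hy_probs = c(0.094, 0.333, 0.298, 0.222, 0.053),
    stage_model = list(
      noise_sd = 0.70,
      thresholds = c(1.147, 2.336, 3.213, 4.717)),
    symptom_models = symptom_models,
    scale_models = list(
      sms = list(
        examination  = list(k = 14L, item_max = 3L,
                            adv = c(16.1, 6.4), non = c(6.6, 4.1)),
        adl          = list(k = 7L, item_max = 3L,
                            adv = c(10.3, 4.5), non = c(2.9, 2.6)),
        dyskinesias  = list(k = 2L, item_max = 3L,
                            adv = c(2.2, 1.9), non = c(0.5, 1.2)),
        fluctuations = list(k = 2L, item_max = 3L,
                            adv = c(2.7, 1.6), non = c(0.6, 1.1))),
      nmss = list(
        cardiovascular = list(k = 2L, adv = c(1.2, 2.2), non = c(0.5, 1.3)),
        sleep_fatigue = list(k = 4L, adv = c(11.4, 8.7), non = c(5.3, 5.7)),
        mood_cognition = list(k = 6L, adv = c(12.4, 15.3), non = c(4.8, 11.2)),
        perceptual_hallucinations = list(k = 3L, adv = c(1.9, 4.3),
                                         non = c(0.4, 1.8)),
        attention_memory = list(k = 3L, adv = c(5.9, 8.0), non = c(2.6, 5.1)),
        gastrointestinal = list(k = 3L, adv = c(5.8, 6.3), non = c(2.3, 3.3)),
        urinary = list(k = 3L, adv = c(9.8, 8.7), non = c(4.8, 6.6)),
        sexual = list(k = 2L, adv = c(4.4, 6.1), non = c(3.2, 5.8)),
        miscellaneous = list(k = 4L, adv = c(8.2, 7.5), non = c(4.8, 4.9))),
      cisi = list(adv = c(13.0, 4.0), non = c(5.1, 3.2)),
      cgis = list(adv = c(6.3, 0.8), non = c(4.2, 1.0)),  # extrapolated
      pgis = list(adv = c(4.8, 0.8), non = c(3.2, 1.0))), # extrapolated
    rater_flip_prob = 0.020,
    retest_flip_prob = 0.028,
    demographics = list(age_mean = 68.4, age_sd = 10.5, prop_women = 0.404,
                        duration_mean = 10.3, duration_sd = 5.8)),
    class = "cdepa_sim_config")
}

.validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "cdepa_sim_config") || is.list(cfg))
  if (abs(sum(cfg$hy_probs) - 1) > 1e-9)
    stop("hy_probs must sum to 1", call. = FALSE)
  if (length(cfg$hy_probs) != 5L || any(cfg$hy_probs < 0))
    stop("hy_probs must be 5 non-negative probabilities", call. = FALSE)
  if (cfg$stage_model$noise_sd <= 0)
    stop("stage noise SD must be positive", call. = FALSE)
  if (is.unsorted(cfg$stage_model$thresholds, strictly = TRUE))
    stop("stage thresholds must be strictly increasing", call. = FALSE)
  for (p in c(cfg$rater_flip_prob, cfg$retest_flip_prob))
    if (p < 0 || p > 0.5)
      stop("flip probabilities must lie in [0, 0.5]", call. = FALSE)
  invisible(cfg)
}

#' @export
print.cdepa_sim_config <- function(x, ...) {
  cat("CDEPA synthetic-cohort configuration\n")
  cat("  n =", x$n, "; HY probs:", paste(x$hy_probs, collapse = "/"), "\n")
  cat("  stage noise SD", x$stage_model$noise_sd, "; thresholds",
      paste(round(x$stage_model$thresholds, 3), collapse = ", "), "\n")
  cat("  ", nrow(x$symptom_models), "symptom models; rater flip",
      x$rater_flip_prob, "; retest flip", x$retest_flip_prob, "\n")
  invisible(x)
}

#' Simulate a synthetic validation cohort
#'
#' Deterministic given `seed`. For each patient: HY stage from
#' `hy_probs`; latent severity = HY + U(-0.5, 0.5); clinical-judgment
#' stage by cutting severity + N(0, noise_sd) at the calibrated thresholds;
#' each symptom answered "yes" with probability
#' plogis(intercept + slope * severity); scale scores drawn from the
#' group-conditional truncated normals keyed on the patient's questionnaire
#' classification, then decomposed into valid item scores (so every scored
#' instrument satisfies its range and summation invariants exactly).
#'
#' @param cfg a [default_sim_config()]-style configuration.
#' @param seed integer RNG seed.
#' @param rules rule set used to classify the simulated answers (the scale
#'   models condition on this classification).
#' @return `cdepa_cohort` object: data.frames `truth` (patient_id, hy,
#'   latent_severity, clinical_stage, gold_dx, demographics),
#'   `responses` (wide yes/no), `scales` (item-level),
#'   `classification` (the rule-engine output), plus `seed`.
#' @export
simulate_cohort <- function(cfg = default_sim_config(), seed = 1L,
                            rules = default_ruleset()) {
  .validate_sim_config(cfg)
  n <- as.integer(cfg$n)
  if (n < 0L) stop("n must be non-negative", call. = FALSE)
  empty <- function() {
    structure(list(truth = data.frame(), responses = data.frame(),
                   scales = data.frame(), classification = data.frame(),
                   seed = seed, config = cfg),
              class = "cdepa_cohort")
  }
  if (n == 0L) return(empty())
  set.seed(as.integer(seed))

  pid <- sprintf("P%04d", seq_len(n))
  hy <- sample.int(5L, n, replace = TRUE, prob = cfg$hy_probs)
  sev <- hy + stats::runif(n, -0.5, 0.5)
  z <- sev + stats::rnorm(n, 0, cfg$stage_model$noise_sd)
  stage <- clinical_stages()[
    findInterval(z, cfg$stage_model$thresholds) + 1L]
  gold <- gold_standard_binary(stage)

  sm <- cfg$symptom_models
  resp <- matrix("no", nrow = n, ncol = nrow(sm),
                 dimnames = list(NULL, sm$id))
  for (j in seq_len(nrow(sm))) {
    p <- stats::plogis(sm$intercept[j] + sm$slope[j] * sev)
    resp[, j] <- ifelse(stats::runif(n) < p, "yes", "no")
  }
  responses <- data.frame(patient_id = pid, resp, stringsAsFactors = FALSE,
                          check.names = FALSE)

  classification <- classify_cohort(rules, responses)
  adv <- classification$diagnosis == "advanced"
  par_of <- function(mdl) list(mean = ifelse(adv, mdl$adv[1], mdl$non[1]),
                               sd = ifelse(adv, mdl$adv[2], mdl$non[2]))

  scales <- data.frame(patient_id = pid, stringsAsFactors = FALSE)
  # S-MS sections
  sms_cols <- list(examination = "sms_ex_%02d", adl = "sms_adl_%02d",
                   dyskinesias = "sms_dysk_%02d", fluctuations = "sms_fluct_%02d")
  for (sec in names(cfg$scale_models$sms)) {
    mdl <- cfg$scale_models$sms[[sec]]
    pp <- par_of(mdl)
    tot <- .rtnorm_int(n, pp$mean, pp$sd, 0, mdl$k * mdl$item_max)
    items <- .split_items(tot, mdl$k, mdl$item_max)
    colnames(items) <- sprintf(sms_cols[[sec]], seq_len(mdl$k))
    scales <- cbind(scales, items)
  }
  # NMSS domains -> severity/frequency items
  item0 <- 0L
  for (dom in names(cfg$scale_models$nmss)) {
    mdl <- cfg$scale_models$nmss[[dom]]
    pp <- par_of(mdl)
    tot <- .rtnorm_int(n, pp$mean, pp$sd, 0, mdl$k * 12L)
    items <- .nmss_split(tot, mdl$k)
    for (i in seq_len(mdl$k)) {
      scales[[sprintf("nmss_%02d_sev", item0 + i)]] <-
        .nmss_sev_of[items[, i] + 1L]
      scales[[sprintf("nmss_%02d_freq", item0 + i)]] <-
        .nmss_freq_of[items[, i] + 1L]
    }
    item0 <- item0 + mdl$k
  }
  # CISI-PD, global impressions
  pp <- par_of(cfg$scale_models$cisi)
  cisi_tot <- .rtnorm_int(n, pp$mean, pp$sd, 0, 24)
  cisi_items <- .split_items(cisi_tot, 4L, 6L)
  colnames(cisi_items) <- sprintf("cisi_%d", 1:4)
  scales <- cbind(scales, cisi_items)
  pp <- par_of(cfg$scale_models$cgis)
  scales$cgis <- .rtnorm_int(n, pp$mean, pp$sd, 1, 7)
  pp <- par_of(cfg$scale_models$pgis)
  scales$pgis <- .rtnorm_int(n, pp$mean, pp$sd, 1, 6)
  scales$hy <- hy
  scales$clinical_stage <- stage

  dg <- cfg$demographics
  truth <- data.frame(
    patient_id = pid, hy = hy, latent_severity = sev,
    clinical_stage = stage, gold_dx = gold,
    age = round(as.numeric(.rtnorm_int(n, dg$age_mean * 10, dg$age_sd * 10,
                                       300, 990)) / 10, 1),
    sex = ifelse(stats::runif(n) < dg$prop_women, "female", "male"),
    disease_duration = round(as.numeric(
      .rtnorm_int(n, dg$duration_mean * 10, dg$duration_sd * 10,
                  20, 400)) / 10, 1),
    stringsAsFactors = FALSE)

  structure(list(truth = truth, responses = responses, scales = scales,
                 classification = classification, seed = seed, config = cfg),
            class = "cdepa_cohort")
}

#' @export
print.cdepa_cohort <- function(x, ...) {
  n <- nrow(x$truth)
  cat("Synthetic CDEPA cohort: n =", n, "(seed", x$seed, ")\n")
  if (n > 0) {
    cat("  gold-standard advanced:",
        sprintf("%.1f%%", 100 * mean(x$truth$gold_dx == "advanced")), "\n")
    cat("  questionnaire advanced:",
        sprintf("%.1f%%",
                100 * mean(x$classification$diagnosis == "advanced")), "\n")
  }
  invisible(x)
}

#' Simulate a second rater (or a retest) of the questionnaire
#'
#' Each yes/no answer is independently flipped with probability
#' `flip_prob`, emulating independent administration of the instrument by a
#' second neurologist (or a later retest by the same rater).
#'
#' @param responses wide response data.frame (e.g. `cohort$responses`), or a
#'   `cdepa_cohort` whose responses are taken.
#' @param flip_prob per-answer flip probability in `[0, 0.5]`.
#' @param seed integer RNG seed.
#' @return Response data.frame of the same shape.
#' @export
simulate_second_rater <- function(responses, flip_prob, seed = 1L) {
  if (inherits(responses, "cdepa_cohort")) responses <- responses$responses
  if (flip_prob < 0 || flip_prob > 0.5)
    stop("flip_prob must lie in [0, 0.5]", call. = FALSE)
  set.seed(as.integer(seed))
  out <- responses
  cols <- setdiff(names(out), "patient_id")
  for (cl in cols) {
    flip <- stats::runif(nrow(out)) < flip_prob
    out[[cl]] <- ifelse(flip, ifelse(out[[cl]] == "yes", "no", "yes"),
                        out[[cl]])
  }
  out
}

#' Write a simulated cohort to CSV files
#'
#' Writes `<prefix>_responses.csv`, `<prefix>_scales.csv` and
#' `<prefix>_truth.csv` (UTF-8, comma-separated, header row).
#'
#' @param cohort a `cdepa_cohort`.
#' @param prefix output path prefix.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_cohort <- function(cohort, prefix) {
  stopifnot(inherits(cohort, "cdepa_cohort"))
  paths <- c(responses = paste0(prefix, "_responses.csv"),
             scales = paste0(prefix, "_scales.csv"),
             truth = paste0(prefix, "_truth.csv"))
  utils::write.csv(cohort$responses, paths["responses"], row.names = FALSE)
  utils::write.csv(cohort$scales, paths["scales"], row.names = FALSE)
  utils::write.csv(cohort$truth, paths["truth"], row.names = FALSE)
  invisible(paths)
}
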