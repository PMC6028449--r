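#' Validate one patient's questionnaire responses against a rule set
#'
#' Every symptom of the instrument is answered "yes" (present) or "no"
#' (absent). Answers for symptom ids not in the rule set are always an
#' error. Missing answers (absent names, `NA`, or empty strings) are coerced
#' to "no" with a warning by default — presence must be affirmed — or raise
#' an error when `strict = TRUE`.
#'
#' @param rules a [cdepa_ruleset()].
#' @param answers named character vector or list; names are symptom ids,
#'   values "yes"/"no" (`NA`/"" treated as missing).
#' @param patient_id identifier attached to the validated responses.
#' @param strict logical; if TRUE missing answers are an error.
#' @return A `cdepa_responses` object: a complete named "yes"/"no" vector
#'   over all rule-set symptom ids, in rule-set order.
#' @export
validate_responses <- function(rules, answers, patient_id = "patient",
                               strict = FALSE) {
  stopifnot(inherits(rules, "cdepa_ruleset"))
  answers <- unlist(answers)
  if (is.null(names(answers)) && length(answers) > 0L)
    stop("answers must be named by symptom id", call. = FALSE)
  ids <- rules$symptoms$id
  unknown <- setdiff(names(answers), ids)
  if (length(unknown) > 0L)
    stop("[", patient_id, "] answer(s) for unknown symptom id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)

  ans <- as.character(answers)
  ans[ans == ""] <- NA_character_
  names(ans) <- names(answers)
  bad <- names(ans)[!is.na(ans) & !ans %in% c("yes", "no")]
  if (length(bad) > 0L)
    stop("[", patient_id, "] answers must be yes/no; offending id(s): ",
         paste(bad, collapse = ", "), call. = FALSE)

  full <- stats::setNames(rep(NA_character_, length(ids)), ids)
  full[names(ans)] <- ans
  missing_ids <- ids[is.na(full)]
  if (length(missing_ids) > 0L) {
    if (strict)
      stop("[", patient_id, "] missing answer(s) for: ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
    warning("[", patient_id, "] ", length(missing_ids),
            " missing answer(s) coerced to \"no\": ",
            paste(missing_ids, collapse = ", "), call. = FALSE)
    full[missing_ids] <- "no"
  }
  structure(full, patient_id = as.character(patient_id),
            class = "cdepa_responses")
}

#' Classify one patient with the CDEPA certainty rules
#'
#' Single-pass evaluation of the instrument's rules, highest certainty
#' first:
#' \itemize{
#'   \item definitive — at least one definitive-level symptom present, or
#'     probable-level symptoms present spanning at least
#'     `promotion_b_min_areas` distinct areas;
#'   \item probable — at least one probable-level symptom present, or a
#'     possible-level symptom in a disease-related area (motor or non-motor)
#'     together with a possible-level symptom in the
#'     neuropsychiatric/cognitive area;
#'   \item possible — any possible-level symptom present;
#'   \item none — no symptom present.
#' }
#' Promotions act on symptom-level certainties only: a case promoted to
#' probable by the possible-pair rule does not feed the probable-combination
#' rule. The binary diagnosis is "advanced" iff the case level reaches the
#' rule set's `diagnosis_threshold`.
#'
#' @param rules a [cdepa_ruleset()].
#' @param resp a `cdepa_responses` object from [validate_responses()].
#' @return A `cdepa_case` object: `patient_id`, `case_level` (ordered
#'   factor), `diagnosis` ("advanced"/"non-advanced"), and `evidence`, a
#'   list of fired clauses with their contributing symptom ids.
#' @export
classify_case <- function(rules, resp) {
  stopifnot(inherits(rules, "cdepa_ruleset"))
  if (!inherits(resp, "cdepa_responses"))
    stop("responses must be validated with validate_responses() first",
         call. = FALSE)
  sy <- rules$symptoms
  if (!identical(names(resp), sy$id))
    stop("responses do not match the rule set; re-validate", call. = FALSE)

  yes <- sy[resp == "yes", , drop = FALSE]
  def_yes  <- yes$id[yes$level == "definitive"]
  prob_yes <- yes$id[yes$level == "probable"]
  poss_yes <- yes$id[yes$level == "possible"]
  prob_areas <- unique(yes$area[yes$level == "probable"])
  poss_disease <- yes$id[yes$level == "possible" & yes$area %in% .disease_areas]
  poss_neuro   <- yes$id[yes$level == "possible" & yes$area == .neuro_area]

  evidence <- list()
  if (length(def_yes) > 0L) {
    level <- "definitive"
    evidence <- list(list(rule = "definitive_symptom", symptoms = def_yes))
  } else if (length(prob_areas) >= rules$promotion_b_min_areas) {
    level <- "definitive"
    evidence <- list(list(rule = "probable_combination", symptoms = prob_yes))
  } else if (length(prob_yes) > 0L) {
    level <- "probable"
    evidence <- list(list(rule = "probable_symptom", symptoms = prob_yes))
  } else if (length(poss_disease) > 0L && length(poss_neuro) > 0L) {
    level <- "probable"
    evidence <- list(list(
      rule = "possible_combination",
      symptoms = yes$id[yes$level == "possible" &
                          yes$area %in% c(.disease_areas, .neuro_area)]))
  } else if (length(poss_yes) > 0L) {
    level <- "possible"
    evidence <- list(list(rule = "possible_symptom", symptoms = poss_yes))
  } else {
    level <- "none"
  }

  lv <- cdepa_levels(level)
  dx <- if (lv >= cdepa_levels(rules$diagnosis_threshold)) "advanced"
        else "non-advanced"
  structure(
    list(patient_id = attr(resp, "patient_id"),
         case_level = lv, diagnosis = dx, evidence = evidence),
    class = "cdepa_case")
}

#' @export
print.cdepa_case <- function(x, ...) {
  cat(sprintf("CDEPA case %s: level %s, diagnosis %s\n",
              x$patient_id, as.character(x$case_level), x$diagnosis))
  for (ev in x$evidence)
    cat("  ", ev$rule, ": ", paste(ev$symptoms, collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

.evidence_string <- function(evidence) {
  if (length(evidence) == 0L) return("")
  paste(vapply(evidence, function(ev)
    paste0(ev$rule, ":", paste(ev$symptoms, collapse = "+")), ""),
    collapse = ";")
}

#' Classify a cohort of questionnaire responses
#'
#' Equivalent to element-wise [classify_case()] over a wide response table
#' (the rules are evaluated in one vectorized pass for speed; the per-case
#' and cohort paths are interchangeable). Order is preserved and the result
#' is deterministic. Validation errors carry the patient id.
#'
#' @param rules a [cdepa_ruleset()].
#' @param responses data.frame with a `patient_id` column plus one column
#'   per symptom id holding "yes"/"no" (empty/`NA` = missing answer), or a
#'   list of already-validated `cdepa_responses`.
#' @param strict passed to [validate_responses()]; with a data.frame input,
#'   missing cells are coerced to "no" with a single summary warning unless
#'   strict.
#' @return data.frame with columns `patient_id`, `case_level`, `diagnosis`,
#'   `evidence` (clause string), one row per input patient.
#' @export
classify_cohort <- function(rules, responses, strict = FALSE) {
  stopifnot(inherits(rules, "cdepa_ruleset"))
  if (!is.data.frame(responses)) {
    # list of per-patient response vectors
    cases <- lapply(responses, function(r) {
      if (!inherits(r, "cdepa_responses"))
        r <- validate_responses(rules, r, strict = strict)
      classify_case(rules, r)
    })
    return(data.frame(
      patient_id = vapply(cases, function(cs) cs$patient_id, ""),
      case_level = vapply(cases, function(cs) as.character(cs$case_level), ""),
      diagnosis = vapply(cases, function(cs) cs$diagnosis, ""),
      evidence = vapply(cases, function(cs) .evidence_string(cs$evidence), ""),
      stringsAsFactors = FALSE))
  }

  if (!"patient_id" %in% names(responses))
    stop("responses table needs a `patient_id` column", call. = FALSE)
  ids <- as.character(responses$patient_id)
  sy <- rules$symptoms
  cols <- setdiff(names(responses), "patient_id")
  unknown <- setdiff(cols, sy$id)
  if (length(unknown) > 0L)
    stop("answer column(s) for unknown symptom id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)

  n <- nrow(responses)
  m <- matrix(NA_character_, nrow = n, ncol = nrow(sy),
              dimnames = list(NULL, sy$id))
  for (cl in cols) m[, cl] <- as.character(responses[[cl]])
  m[!is.na(m) & m == ""] <- NA_character_
  bad <- !is.na(m) & !m %in% c("yes", "no")
  if (any(bad)) {
    i <- which(rowSums(bad) > 0)[1]
    stop("[", ids[i], "] answers must be yes/no; offending id(s): ",
         paste(colnames(m)[bad[i, ]], collapse = ", "), call. = FALSE)
  }
  if (anyNA(m)) {
    if (strict) {
      i <- which(rowSums(is.na(m)) > 0)[1]
      stop("[", ids[i], "] missing answer(s) for: ",
           paste(colnames(m)[is.na(m[i, ])], collapse = ", "), call. = FALSE)
    }
    warning(sum(is.na(m)), " missing answer(s) coerced to \"no\" across ",
            sum(rowSums(is.na(m)) > 0), " patient(s)", call. = FALSE)
    m[is.na(m)] <- "no"
  }

  yes <- m == "yes"
  is_def <- sy$level == "definitive"
  is_prob <- sy$level == "probable"
  is_poss <- sy$level == "possible"
  # distinct areas spanned by probable-level "yes" answers
  areas <- unique(sy$area)
  prob_area_hit <- vapply(areas, function(a)
    rowSums(yes[, is_prob & sy$area == a, drop = FALSE]) > 0, logical(n))
  if (n == 1L) prob_area_hit <- matrix(prob_area_hit, nrow = 1L)
  n_prob_areas <- rowSums(prob_area_hit)

  any_def <- rowSums(yes[, is_def, drop = FALSE]) > 0
  any_prob <- rowSums(yes[, is_prob, drop = FALSE]) > 0
  any_poss <- rowSums(yes[, is_poss, drop = FALSE]) > 0
  poss_disease <- rowSums(
    yes[, is_poss & sy$area %in% .disease_areas, drop = FALSE]) > 0
  poss_neuro <- rowSums(
    yes[, is_poss & sy$area == .neuro_area, drop = FALSE]) > 0

  promo_b <- !any_def & n_prob_areas >= rules$promotion_b_min_areas
  promo_c <- !any_def & !promo_b & !any_prob & poss_disease & poss_neuro
  level <- ifelse(any_def | promo_b, "definitive",
           ifelse(any_prob | promo_c, "probable",
           ifelse(any_poss, "possible", "none")))
  dx <- ifelse(cdepa_levels(level) >= cdepa_levels(rules$diagnosis_threshold),
               "advanced", "non-advanced")

  rule <- ifelse(any_def, "definitive_symptom",
          ifelse(promo_b, "probable_combination",
          ifelse(any_prob, "probable_symptom",
          ifelse(promo_c, "possible_combination",
          ifelse(any_poss, "possible_symptom", "")))))
  ev_cols <- list(
    definitive_symptom = is_def, probable_combination = is_prob,
    probable_symptom = is_prob,
    possible_combination = is_poss &
      (sy$area %in% .disease_areas | sy$area == .neuro_area),
    possible_symptom = is_poss)
  evidence <- character(n)
  fired <- which(rule != "")
  for (i in fired) {
    sel <- yes[i, ] & ev_cols[[rule[i]]]
    evidence[i] <- paste0(rule[i], ":",
                          paste(sy$id[sel], collapse = "+"))
  }
  data.frame(patient_id = ids, case_level = level, diagnosis = dx,
             evidence = evidence, stringsAsFactors = FALSE)
}

#' Read a cohort response CSV
#'
#' Expected layout: UTF-8 comma-separated with a header, a `patient_id`
#' column and one column per symptom id with values yes/no (empty cell =
#' missing answer).
#'
#' @param path CSV file path.
#' @param rules optional [cdepa_ruleset()]; when given, columns are checked
#'   against its symptom ids immediately.
#' @return data.frame of raw responses.
#' @export
read_responses <- function(path, rules = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!"patient_id" %in% names(df))
    stop("response CSV lacks a `patient_id` column: ", path, call. = FALSE)
  if (!is.null(rules)) {
    unknown <- setdiff(setdiff(names(df), "patient_id"), rules$symptoms$id)
    if (length(unknown) > 0L)
      stop("response CSV has column(s) not in the rule set: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  df
}

#' Write cohort responses or classifications to CSV
#'
#' @param x data.frame (responses or the output of [classify_cohort()]).
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
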