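#' Symptom areas of the CDEPA checklist
#'
#' The six symptom domains of the questionnaire. Every symptom belongs to
#' exactly one area; the combination rules refer to them (promotion to
#' definitive requires probable symptoms from distinct areas, promotion to
#' probable pairs a disease-related area with the neuropsychiatric/cognitive
#' area).
#'
#' @return Character vector of the six area labels.
#' @export
cdepa_areas <- function() {
  c("general_characteristics", "disability", "treatment_motor",
    "disease_motor", "disease_non_motor", "neuropsychiatric_cognitive")
}

#' Certainty levels of a CDEPA case or symptom
#'
#' Ordered certainty vocabulary. Individual symptoms carry one of
#' possible/probable/definitive; a case classification may additionally be
#' "none" when no symptom is present.
#'
#' @param x optional character vector to coerce to an ordered factor over the
#'   certainty levels.
#' @return With no argument, the ordered level labels (lowest first);
#'   otherwise `x` as an ordered factor.
#' @export
cdepa_levels <- function(x) {
  lv <- c("none", "possible", "probable", "definitive")
  if (missing(x)) return(lv)
  bad <- setdiff(unique(as.character(x)), lv)
  if (length(bad) > 0L)
    stop("unknown certainty level(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  ordered(as.character(x), levels = lv)
}

# disease-related areas whose possible-level symptoms can pair with a
# neuropsychiatric/cognitive possible symptom to promote the case to probable
.disease_areas <- c("disease_motor", "disease_non_motor")
.neuro_area <- "neuropsychiatric_cognitive"

#' Construct a validated CDEPA rule set
#'
#' A rule set is the symptom taxonomy (id, label, area, certainty level) plus
#' the two tunable combination-rule parameters: the number of distinct areas
#' probable-level symptoms must span to promote a case to definitive, and the
#' case level at or above which the binary diagnosis is "advanced".
#'
#' @param symptoms data.frame with columns `id`, `label`, `area`, `level`.
#'   Ids must be unique; areas drawn from [cdepa_areas()]; levels one of
#'   possible/probable/definitive ("none" is not a symptom level).
#' @param promotion_b_min_areas integer >= 2; distinct areas required for the
#'   probable-to-definitive combination promotion (default 2).
#' @param diagnosis_threshold case level at or above which the diagnosis is
#'   advanced; "definitive" by default, settable to "probable" for
#'   sensitivity analyses.
#' @return An object of class `cdepa_ruleset`.
#' @seealso [default_ruleset()], [read_ruleset()], [classify_case()]
#' @export
cdepa_ruleset <- function(symptoms, promotion_b_min_areas = 2L,
                          diagnosis_threshold = "definitive") {
  if (!is.data.frame(symptoms))
    stop("`symptoms` must be a data.frame", call. = FALSE)
  need <- c("id", "label", "area", "level")
  miss <- setdiff(need, names(symptoms))
  if (length(miss) > 0L)
    stop("symptom table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  symptoms <- as.data.frame(symptoms)[need]
  for (cl in need) symptoms[[cl]] <- as.character(symptoms[[cl]])

  dup <- unique(symptoms$id[duplicated(symptoms$id)])
  if (length(dup) > 0L)
    stop("duplicate symptom id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  bad_area <- setdiff(unique(symptoms$area), cdepa_areas())
  if (length(bad_area) > 0L)
    stop("unknown area(s): ", paste(bad_area, collapse = ", "), call. = FALSE)
  bad_lvl <- setdiff(unique(symptoms$level),
                     c("possible", "probable", "definitive"))
  if (length(bad_lvl) > 0L)
    stop("symptom level must be possible/probable/definitive; got: ",
         paste(bad_lvl, collapse = ", "), call. = FALSE)
  if (!any(symptoms$level == "definitive"))
    stop("rule set must contain at least one definitive-level symptom",
         call. = FALSE)

  promotion_b_min_areas <- as.integer(promotion_b_min_areas)
  if (is.na(promotion_b_min_areas) || promotion_b_min_areas < 2L)
    stop("`promotion_b_min_areas` must be an integer >= 2", call. = FALSE)
  if (!diagnosis_threshold %in% c("possible", "probable", "definitive"))
    stop("`diagnosis_threshold` must be possible/probable/definitive",
         call. = FALSE)

  rownames(symptoms) <- NULL
  structure(
    list(symptoms = symptoms,
         promotion_b_min_areas = promotion_b_min_areas,
         diagnosis_threshold = diagnosis_threshold),
    class = "cdepa_ruleset")
}

#' Read a rule set from a YAML or JSON rule map
#'
#' Schema: `symptoms:` list of `{id, label, area, level}` entries, plus
#' optional `promotion_b_min_areas` and `diagnosis_threshold` scalars.
#'
#' @param path path to a YAML (or JSON, which YAML subsumes) rule-map file.
#' @return A validated [cdepa_ruleset()].
#' @export
read_ruleset <- function(path) {
  if (!file.exists(path))
    stop("rule map not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$symptoms) || length(cfg$symptoms) == 0L)
    stop("rule map has no `symptoms` entries: ", path, call. = FALSE)
  get1 <- function(s, f) {
    v <- s[[f]]
    if (is.null(v)) stop("symptom entry missing field `", f, "` in ", path,
                         call. = FALSE)
    as.character(v)
  }
  symptoms <- do.call(rbind, lapply(cfg$symptoms, function(s)
    data.frame(id = get1(s, "id"), label = get1(s, "label"),
               area = get1(s, "area"), level = get1(s, "level"),
               stringsAsFactors = FALSE)))
  cdepa_ruleset(
    symptoms,
    promotion_b_min_areas = if (is.null(cfg$promotion_b_min_areas)) 2L
                            else cfg$promotion_b_min_areas,
    diagnosis_threshold = if (is.null(cfg$diagnosis_threshold)) "definitive"
                          else cfg$diagnosis_threshold)
}

#' The packaged default CDEPA rule set
#'
#' Loads the questionnaire shipped with the package: 19 symptoms in six
#' areas, five of them definitive (severe disability requiring help for
#' activities of daily living, motor fluctuations with off time >25% with
#' limitation, severe dysphagia, recurrent falls, dementia). The file
#' `inst/extdata/cdepa_table1.yaml` is editable data, not code; entries whose
#' certainty column could not be fixed from the published flattened table are
#' flagged there for review.
#'
#' @return A [cdepa_ruleset()].
#' @export
default_ruleset <- function() {
  read_ruleset(system.file("extdata", "cdepa_table1.yaml", package = "cdepa",
                           mustWork = TRUE))
}

#' @export
print.cdepa_ruleset <- function(x, ...) {
  cat("CDEPA rule set:", nrow(x$symptoms), "symptoms in",
      length(unique(x$symptoms$area)), "areas\n")
  tab <- table(factor(x$symptoms$level,
                      levels = c("possible", "probable", "definitive")))
  cat("  levels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  cat("  promotion to definitive: >=", x$promotion_b_min_areas,
      "distinct areas of probable symptoms\n")
  cat("  advanced-PD threshold: case level >=", x$diagnosis_threshold, "\n")
  invisible(x)
}
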