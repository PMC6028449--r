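# Clinical rating scales of the validation battery: Hoehn-Yahr staging,
# SCOPA-Motor (S-MS), Non-Motor Symptoms Scale (NMSS), CISI-PD, clinician
# and patient global impressions, and the five-level clinical-judgment
# stage that serves as gold standard.

.check_items <- function(x, lo, hi, what, n = NULL) {
  x <- suppressWarnings(as.numeric(x))
  if (!is.null(n) && length(x) != n)
    stop(what, ": expected ", n, " items, got ", length(x), call. = FALSE)
  bad <- which(!is.na(x) & (x < lo | x > hi | x != round(x)))
  if (length(bad) > 0L)
    stop(what, ": item(s) ", paste(bad, collapse = ", "),
         " outside integer range [", lo, ",", hi, "]", call. = FALSE)
  x
}

#' Score the SCOPA-Motor scale (S-MS)
#'
#' Sections and ranges: examination 0-42, activities of daily living 0-21,
#' complications 0-12 split as dyskinesias 0-6 and motor fluctuations 0-6;
#' total 0-75. The default item layout (14 examination, 7 ADL, 2 dyskinesia
#' and 2 fluctuation item scores, each 0-3) realises those section maxima;
#' the per-item labels are instrument data, not code.
#'
#' Any missing item makes the affected section and the total `NA` and flags
#' the score incomplete: no imputation is performed.
#'
#' @param examination,adl,dyskinesias,fluctuations integer item vectors
#'   (0-3 each) of lengths 14, 7, 2, 2.
#' @return `sms_score` object: section sums, `total`, and `incomplete` flag.
#' @export
score_sms <- function(examination, adl, dyskinesias, fluctuations) {
  ex <- .check_items(examination, 0, 3, "examination", 14L)
  ad <- .check_items(adl, 0, 3, "adl", 7L)
  dy <- .check_items(dyskinesias, 0, 3, "dyskinesias", 2L)
  fl <- .check_items(fluctuations, 0, 3, "fluctuations", 2L)
  s <- list(examination = sum(ex), adl = sum(ad),
            dyskinesias = sum(dy), fluctuations = sum(fl))
  s$total <- s$examination + s$adl + s$dyskinesias + s$fluctuations
  s$incomplete <- anyNA(c(ex, ad, dy, fl))
  structure(s, class = "sms_score")
}

#' NMSS domain item partition
#'
#' Nine domains over the 30 items, in instrument order.
#' @return Named integer vector of items per domain.
#' @export
nmss_domains <- function() {
  c(cardiovascular = 2L, sleep_fatigue = 4L, mood_cognition = 6L,
    perceptual_hallucinations = 3L, attention_memory = 3L,
    gastrointestinal = 3L, urinary = 3L, sexual = 2L, miscellaneous = 4L)
}

#' Score the Non-Motor Symptoms Scale (NMSS)
#'
#' Each of the 30 items is severity (0-3) times frequency (1-4), so an item
#' score lies in 0-12 and is zero exactly when severity is zero. Domain
#' scores sum the items of the partition in [nmss_domains()]; the total
#' (0-360) sums the domains.
#'
#' @param severity,frequency integer vectors of length 30.
#' @return `nmss_score` object: `items` (30 item scores), `domains` (named
#'   vector of 9 domain sums), `total`, `incomplete`.
#' @export
score_nmss <- function(severity, frequency) {
  sev <- .check_items(severity, 0, 3, "severity", 30L)
  frq <- .check_items(frequency, 1, 4, "frequency", 30L)
  items <- sev * frq
  dom_n <- nmss_domains()
  idx <- rep(names(dom_n), dom_n)
  domains <- vapply(names(dom_n),
                    function(d) sum(items[idx == d]), numeric(1))
  structure(list(items = items, domains = domains,
                 total = sum(domains), incomplete = anyNA(items)),
            class = "nmss_score")
}

#' Score the CISI-PD global severity index
#'
#' Four clinician-rated items (motor signs, disability, motor complications,
#' cognitive status), each 0 (normal) to 6 (very severe); total 0-24.
#'
#' @param items integer vector of length 4.
#' @return `cisi_score` object with `items`, `total`, `incomplete`.
#' @export
score_cisi <- function(items) {
  it <- .check_items(items, 0, 6, "cisi", 4L)
  structure(list(items = it, total = sum(it), incomplete = anyNA(it)),
            class = "cisi_score")
}

#' Validate a Hoehn-Yahr stage
#'
#' Integer stages 1-5 only; the modified scale's half stages are rejected.
#'
#' @param stage numeric vector.
#' @return Integer vector of validated stages.
#' @export
hy_stage <- function(stage) {
  s <- suppressWarnings(as.numeric(stage))
  bad <- which(!is.na(s) & !s %in% 1:5)
  if (length(bad) > 0L)
    stop("Hoehn-Yahr stage must be an integer 1-5; offending position(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  as.integer(s)
}

#' Validate clinician / patient global impressions
#'
#' CGIS has seven response options (1 "normal, not at all ill" to 7); PGIS
#' has six (1 "normal" to 6 "severe").
#'
#' @param cgis,pgis integer vectors.
#' @return list with validated `cgis` and `pgis`.
#' @export
global_impressions <- function(cgis, pgis) {
  list(cgis = .check_items(cgis, 1, 7, "cgis"),
       pgis = .check_items(pgis, 1, 6, "pgis"))
}

#' Labels of the five-level clinical-judgment stage (gold standard)
#' @return Character vector, mildest first.
#' @export
clinical_stages <- function() {
  c("initial", "mild", "moderate", "advanced", "late_stage")
}

#' Binarize the gold-standard clinical stage
#'
#' Initial, mild and moderate stages are non-advanced disease; advanced and
#' late-stage are advanced.
#'
#' @param stage character vector of stage labels.
#' @return Character vector "advanced"/"non-advanced".
#' @export
gold_standard_binary <- function(stage) {
  stage <- as.character(stage)
  bad <- setdiff(unique(stage[!is.na(stage)]), clinical_stages())
  if (length(bad) > 0L)
    stop("unknown clinical stage label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  ifelse(is.na(stage), NA_character_,
         ifelse(stage %in% c("advanced", "late_stage"),
                "advanced", "non-advanced"))
}

# Column layout of the per-patient scales CSV (one row per patient).
.scales_columns <- function() {
  c("patient_id",
    sprintf("sms_ex_%02d", 1:14), sprintf("sms_adl_%02d", 1:7),
    sprintf("sms_dysk_%02d", 1:2), sprintf("sms_fluct_%02d", 1:2),
    as.vector(rbind(sprintf("nmss_%02d_sev", 1:30),
                    sprintf("nmss_%02d_freq", 1:30))),
    sprintf("cisi_%d", 1:4), "cgis", "pgis", "hy", "clinical_stage")
}

#' Read a scales CSV
#'
#' One row per patient; namespaced item columns (`sms_ex_01` ...,
#' `nmss_01_sev`/`nmss_01_freq` ..., `cisi_1` ... `cisi_4`, `cgis`, `pgis`,
#' `hy`, `clinical_stage`). Unknown columns are a schema error naming the
#' column.
#'
#' @param path CSV file path.
#' @return data.frame of raw item scores.
#' @export
read_scales <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  unknown <- setdiff(names(df), .scales_columns())
  if (length(unknown) > 0L)
    stop("scales CSV has unknown column(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  miss <- setdiff(.scales_columns(), names(df))
  if (length(miss) > 0L)
    stop("scales CSV lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}

#' Score all instruments for a cohort scales table
#'
#' Applies [score_sms()], [score_nmss()] and [score_cisi()] row-wise and
#' validates staging and global impressions, yielding one summary row per
#' patient.
#'
#' @param scales data.frame in the layout of [read_scales()].
#' @return data.frame with per-patient section/domain/total scores,
#'   `cgis`, `pgis`, `hy`, `clinical_stage` and `gold_dx`.
#' @export
score_scales <- function(scales) {
  pick <- function(row, cols) as.numeric(unlist(row[cols]))
  rows <- lapply(seq_len(nrow(scales)), function(i) {
    row <- scales[i, ]
    sms <- score_sms(pick(row, sprintf("sms_ex_%02d", 1:14)),
                     pick(row, sprintf("sms_adl_%02d", 1:7)),
                     pick(row, sprintf("sms_dysk_%02d", 1:2)),
                     pick(row, sprintf("sms_fluct_%02d", 1:2)))
    nm <- score_nmss(pick(row, sprintf("nmss_%02d_sev", 1:30)),
                     pick(row, sprintf("nmss_%02d_freq", 1:30)))
    ci <- score_cisi(pick(row, sprintf("cisi_%d", 1:4)))
    gi <- global_impressions(row$cgis, row$pgis)
    out <- data.frame(
      patient_id = as.character(row$patient_id),
      sms_examination = sms$examination, sms_adl = sms$adl,
      sms_dyskinesias = sms$dyskinesias, sms_fluctuations = sms$fluctuations,
      sms_total = sms$total,
      stringsAsFactors = FALSE)
    for (d in names(nm$domains)) out[[paste0("nmss_", d)]] <- nm$domains[[d]]
    out$nmss_total <- nm$total
    out$cisi_total <- ci$total
    out$cgis <- gi$cgis
    out$pgis <- gi$pgis
    out$hy <- hy_stage(row$hy)
    out$clinical_stage <- as.character(row$clinical_stage)
    out
  })
  out <- do.call(rbind, rows)
  out$gold_dx <- gold_standard_binary(out$clinical_stage)
  out
}
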