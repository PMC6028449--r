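r_full <- default_ruleset()

test_that("response validation coerces or rejects missing answers", {
  ans <- all_no(r_full)
  v <- validate_responses(r_full, ans, "p1")
  expect_s3_class(v, "cdepa_responses")
  expect_true(all(v == "no"))

  partial <- ans[-3]
  expect_warning(v2 <- validate_responses(r_full, partial, "p1"),
                 "coerced")
  expect_equal(unname(v2[names(ans)[3]]), "no")
  expect_error(validate_responses(r_full, partial, "p1", strict = TRUE),
               "missing answer")

  bad <- c(ans, not_a_symptom = "yes")
  expect_error(validate_responses(r_full, bad, "p1"), "not_a_symptom")
  wrong <- ans; wrong[1] <- "maybe"
  expect_error(validate_responses(r_full, wrong, "p1"), "yes/no")
})

test_that("single symptoms and combination promotions classify as stated", {
  cases <- list(
    # all absent
    list(set = character(0), level = "none", dx = "non-advanced"),
    # one definitive symptom alone is diagnostic
    list(set = "dementia", level = "definitive", dx = "advanced"),
    # two probable symptoms from different areas promote to definitive
    list(set = c("evolution_10y", "moderate_dysphagia"),
         level = "definitive", dx = "advanced"),
    # disease-area possible + neuropsychiatric possible promote to probable
    list(set = c("dysarthria_moderate_severe", "mild_cognitive_impairment"),
         level = "probable", dx = "non-advanced"),
    # two probables in the SAME area do not promote
    list(set = c("moderate_dysphagia", "freezing_gait"),
         level = "probable", dx = "non-advanced"),
    # a single possible symptom stays possible
    list(set = "daytime_somnolence", level = "possible", dx = "non-advanced"),
    # two possibles both in disease areas do not promote
    list(set = c("dysarthria_moderate_severe", "symptomatic_dysautonomia"),
         level = "possible", dx = "non-advanced"))
  for (cs in cases) {
    ans <- all_no(r_full)
    ans[cs$set] <- "yes"
    got <- classify_case(r_full, validate_responses(r_full, ans, "p"))
    expect_equal(as.character(got$case_level), cs$level,
                 label = paste(cs$set, collapse = "+"))
    expect_equal(got$diagnosis, cs$dx)
    if (cs$level != "none") {
      expect_gt(length(got$evidence), 0)
      expect_setequal(got$evidence[[1]]$symptoms, cs$set)
    }
  }
})

test_that("diagnosis threshold and promotion span are configurable", {
  r_prob <- cdepa_ruleset(r_full$symptoms, diagnosis_threshold = "probable")
  ans <- all_no(r_prob); ans["freezing_gait"] <- "yes"
  got <- classify_case(r_prob, validate_responses(r_prob, ans, "p"))
  expect_equal(got$diagnosis, "advanced")

  r_wide <- cdepa_ruleset(r_full$symptoms, promotion_b_min_areas = 3L)
  ans <- all_no(r_wide)
  ans[c("evolution_10y", "moderate_dysphagia")] <- "yes"
  got <- classify_case(r_wide, validate_responses(r_wide, ans, "p"))
  expect_equal(as.character(got$case_level), "probable")
})

test_that("engine matches the clause transcription over all 2^8 patterns", {
  r8 <- reduced_ruleset()
  grid <- all_patterns(r8)
  df <- data.frame(patient_id = sprintf("p%03d", seq_len(nrow(grid))), grid,
                   stringsAsFactors = FALSE, check.names = FALSE)
  got <- classify_cohort(r8, df)
  want <- vapply(seq_len(nrow(grid)), function(i)
    oracle_case_level(r8, unlist(grid[i, ])), "")
  expect_identical(got$case_level, want)
  expect_identical(got$diagnosis,
                   ifelse(want == "definitive", "advanced", "non-advanced"))
})

test_that("cohort classification equals the per-case path and is deterministic", {
  set.seed(101)
  df <- random_response_df(r_full, 400)
  a <- classify_cohort(r_full, df)
  b <- classify_cohort(r_full, df)
  expect_identical(a, b)
  expect_identical(a$patient_id, df$patient_id)

  per_case <- lapply(seq_len(nrow(df)), function(i) {
    ans <- unlist(df[i, -1])
    classify_case(r_full, validate_responses(r_full, ans, df$patient_id[i]))
  })
  expect_identical(a$case_level,
                   vapply(per_case, function(cs) as.character(cs$case_level), ""))
  expect_identical(a$diagnosis,
                   vapply(per_case, function(cs) cs$diagnosis, ""))

  expect_identical(nrow(classify_cohort(r_full, df[0, ])), 0L)
})

test_that("flipping an answer from no to yes never lowers the case level", {
  set.seed(77)
  df <- random_response_df(r_full, 800)
  base <- classify_cohort(r_full, df)
  flipped <- df
  for (i in seq_len(nrow(df))) {
    noes <- which(unlist(df[i, -1]) == "no")
    if (length(noes) == 0) next
    j <- sample(noes, 1) + 1L
    flipped[i, j] <- "yes"
  }
  after <- classify_cohort(r_full, flipped)
  expect_true(all(cdepa_levels(after$case_level) >=
                    cdepa_levels(base$case_level)))
})

test_that("a definitive symptom dominates regardless of other answers", {
  set.seed(5)
  df <- random_response_df(r_full, 300)
  df$severe_dysphagia <- "yes"
  got <- classify_cohort(r_full, df)
  expect_true(all(got$diagnosis == "advanced"))
  expect_true(all(got$case_level == "definitive"))
})

test_that("evidence cites only yes-answered symptoms of the firing clause", {
  set.seed(9)
  df <- random_response_df(r_full, 250)
  got <- classify_cohort(r_full, df)
  sy <- r_full$symptoms
  level_req <- c(definitive_symptom = "definitive",
                 probable_combination = "probable",
                 probable_symptom = "probable",
                 possible_combination = "possible",
                 possible_symptom = "possible")
  for (i in seq_len(nrow(got))) {
    if (got$evidence[i] == "") {
      expect_equal(got$case_level[i], "none")
      next
    }
    parts <- strsplit(got$evidence[i], ":", fixed = TRUE)[[1]]
    rule <- parts[1]
    ids <- strsplit(parts[2], "+", fixed = TRUE)[[1]]
    expect_true(all(unlist(df[i, ids]) == "yes"))
    expect_true(all(sy$level[match(ids, sy$id)] == level_req[[rule]]))
  }
})

test_that("response CSVs round-trip and unknown columns are named", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  set.seed(3)
  df <- random_response_df(r_full, 20)
  write_cohort_csv(df, tmp)
  back <- read_responses(tmp, r_full)
  expect_equal(back, df)

  df$extra_col <- "yes"
  write_cohort_csv(df, tmp)
  expect_error(read_responses(tmp, r_full), "extra_col")
})
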