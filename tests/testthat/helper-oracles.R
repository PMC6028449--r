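# Shared fixtures and independent first-principles oracles used across the
# suite.  Oracles are written directly from the definitions (combination
# clauses, kappa formula, permutation enumeration, hypergeometric sums) and
# share no code with the package implementations they check.

# a reduced 8-symptom rule set spanning all levels and the rule-relevant
# areas, small enough for exhaustive 2^8 enumeration
reduced_ruleset <- function() {
  cdepa_ruleset(data.frame(
    id = c("d1", "d2", "p1", "p2", "p3", "q1", "q2", "q3"),
    label = paste("symptom", 1:8),
    area = c("disability", "neuropsychiatric_cognitive",
             "general_characteristics", "disease_motor", "disease_motor",
             "disease_motor", "disease_non_motor",
             "neuropsychiatric_cognitive"),
    level = c("definitive", "definitive", "probable", "probable", "probable",
              "possible", "possible", "possible"),
    stringsAsFactors = FALSE))
}

# literal transcription of the instrument's certainty clauses, evaluated as
# a flat truth table over the answers (independent of the engine)
oracle_case_level <- function(ruleset, answers) {
  sy <- ruleset$symptoms
  present <- sy[answers[sy$id] == "yes", , drop = FALSE]
  clause_a <- any(present$level == "definitive")
  clause_b <- length(unique(present$area[present$level == "probable"])) >=
    ruleset$promotion_b_min_areas
  has_probable <- any(present$level == "probable")
  clause_c <- any(present$level == "possible" &
                    present$area %in% c("disease_motor", "disease_non_motor")) &&
    any(present$level == "possible" &
          present$area == "neuropsychiatric_cognitive")
  has_possible <- any(present$level == "possible")
  if (clause_a || clause_b) "definitive"
  else if (has_probable || clause_c) "probable"
  else if (has_possible) "possible"
  else "none"
}

# all yes/no patterns over the ids of a rule set
all_patterns <- function(ruleset) {
  ids <- ruleset$symptoms$id
  grid <- expand.grid(rep(list(c("no", "yes")), length(ids)),
                      stringsAsFactors = FALSE)
  names(grid) <- ids
  grid
}

random_response_df <- function(ruleset, n, p_yes = 0.25) {
  ids <- ruleset$symptoms$id
  m <- matrix(sample(c("yes", "no"), n * length(ids), replace = TRUE,
                     prob = c(p_yes, 1 - p_yes)),
              nrow = n, dimnames = list(NULL, ids))
  data.frame(patient_id = sprintf("p%05d", seq_len(n)), m,
             stringsAsFactors = FALSE, check.names = FALSE)
}

# Cohen's kappa from its definition, loops and all
oracle_kappa <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  p_o <- 0
  for (i in seq_len(nrow(tab))) p_o <- p_o + tab[i, i] / n
  p_e <- 0
  for (i in seq_len(nrow(tab)))
    p_e <- p_e + (sum(tab[i, ]) / n) * (sum(tab[, i]) / n)
  (p_o - p_e) / (1 - p_e)
}

# exact two-sided Mann-Whitney p by enumerating every group labeling of the
# pooled sample (distance of U from its null mean as the extremity measure)
oracle_mwu_exact <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  mu <- n1 * n2 / 2
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  labelings <- utils::combn(n1 + n2, n1)
  extreme <- 0L
  for (j in seq_len(ncol(labelings))) {
    u <- sum(r[labelings[, j]]) - n1 * (n1 + 1) / 2
    if (abs(u - mu) >= abs(u_obs - mu) - 1e-9) extreme <- extreme + 1L
  }
  extreme / ncol(labelings)
}

# two-sided Fisher p by direct hypergeometric enumeration over all tables
# with the observed margins
oracle_fisher <- function(tp, fp, fn, tn) {
  m <- tp + fn; n <- fp + tn; k <- tp + fp
  x_all <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(x_all, m, n, k)
  p_obs <- stats::dhyper(tp, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# tie-corrected Kruskal-Wallis H from the rank-sum formula
oracle_kw_h <- function(groups) {
  x <- unlist(groups)
  N <- length(x)
  r <- rank(x)
  off <- 0
  h <- 0
  for (g in groups) {
    idx <- off + seq_along(g)
    h <- h + sum(r[idx])^2 / length(g)
    off <- off + length(g)
  }
  h <- 12 / (N * (N + 1)) * h - 3 * (N + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# "no" baseline answers for a rule set
all_no <- function(ruleset) {
  stats::setNames(rep("no", nrow(ruleset$symptoms)), ruleset$symptoms$id)
}
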