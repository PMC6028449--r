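# Validation statistics: 2x2 diagnostic performance, chance-corrected
# agreement, nonparametric comparisons, cutoff finding and power.

#' Build a 2x2 contingency table from paired diagnoses
#'
#' Rows are the index test (the questionnaire), columns the reference (gold
#' standard); `tp` counts patients called advanced by both.
#'
#' @param index_dx,reference_dx equal-length vectors of binary labels.
#' @param positive the label counted as a positive (default "advanced").
#' @return `contingency_2x2` object with counts `tp`, `fp`, `fn`, `tn`.
#' @export
build_contingency <- function(index_dx, reference_dx, positive = "advanced") {
  if (length(index_dx) != length(reference_dx))
    stop("index and reference vectors differ in length", call. = FALSE)
  if (length(index_dx) == 0L)
    stop("empty diagnosis vectors", call. = FALSE)
  ip <- index_dx == positive
  rp <- reference_dx == positive
  contingency_2x2(sum(ip & rp), sum(ip & !rp), sum(!ip & rp), sum(!ip & !rp))
}

#' Construct a 2x2 contingency table from counts
#'
#' @param tp,fp,fn,tn non-negative integer counts (tp = positive by both
#'   index test and reference).
#' @return `contingency_2x2` object.
#' @export
contingency_2x2 <- function(tp, fp, fn, tn) {
  k <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(k)) || any(k < 0) || any(k != round(k)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (sum(k) == 0) stop("contingency table is empty", call. = FALSE)
  storage.mode(k) <- "integer"
  structure(as.list(k), class = "contingency_2x2")
}

#' @export
as.matrix.contingency_2x2 <- function(x, ...) {
  matrix(c(x$tp, x$fn, x$fp, x$tn), nrow = 2,
         dimnames = list(index = c("advanced", "non-advanced"),
                         reference = c("advanced", "non-advanced")))
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  print(as.matrix(x))
  invisible(x)
}

#' Diagnostic performance of an index test against a gold standard
#'
#' Computes sensitivity, specificity, positive and negative predictive
#' values, accuracy, false-positive and false-negative rates, and the
#' binary-classifier AUC defined as (sensitivity + specificity)/2. A
#' statistic with a zero denominator is returned as `NA` with a message;
#' the others are still computed.
#'
#' @param t a [contingency_2x2()].
#' @return `diag_performance` object of proportions in `[0,1]`.
#' @export
diagnostic_performance <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  ratio <- function(num, den, what) {
    if (den == 0) {
      message("undefined ", what, ": zero denominator")
      return(NA_real_)
    }
    num / den
  }
  n <- t$tp + t$fp + t$fn + t$tn
  sens <- ratio(t$tp, t$tp + t$fn, "sensitivity")
  spec <- ratio(t$tn, t$tn + t$fp, "specificity")
  out <- list(
    sensitivity = sens, specificity = spec,
    ppv = ratio(t$tp, t$tp + t$fp, "PPV"),
    npv = ratio(t$tn, t$tn + t$fn, "NPV"),
    accuracy = (t$tp + t$tn) / n,
    fp_rate = if (is.na(spec)) NA_real_ else 1 - spec,
    fn_rate = if (is.na(sens)) NA_real_ else 1 - sens,
    auc_binary = if (is.na(sens) || is.na(spec)) NA_real_
                 else (sens + spec) / 2,
    n = n, table = t)
  structure(out, class = "diag_performance")
}

#' @export
print.diag_performance <- function(x, ...) {
  pc <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%", 100 * v)
  cat(sprintf(paste0(
    "Sensitivity was %s; specificity was %s; false positives were %s; ",
    "false negatives were %s; positive predictive value was %s; ",
    "negative predictive value was %s; total accuracy was %s\n"),
    pc(x$sensitivity), pc(x$specificity), pc(x$fp_rate), pc(x$fn_rate),
    pc(x$ppv), pc(x$npv), pc(x$accuracy)))
  cat(sprintf("Area under the curve (binary classifier): %s\n",
              pc(x$auc_binary)))
  invisible(x)
}

#' Landis-Koch interpretation of a kappa value
#'
#' Bands: 0.00-0.20 negligible, 0.21-0.40 weak, 0.41-0.60 moderate,
#' 0.61-0.80 substantial, 0.81-1.00 almost perfect. Band edges are applied
#' to the value rounded to two decimals (the scale is stated at that
#' precision); negative kappa is labelled "below negligible".
#'
#' @param kappa numeric in `[-1,1]`.
#' @return Character label.
#' @export
landis_koch <- function(kappa) {
  k <- round(kappa, 2)
  if (k < 0) "below negligible"
  else if (k <= 0.20) "negligible"
  else if (k <= 0.40) "weak"
  else if (k <= 0.60) "moderate"
  else if (k <= 0.80) "substantial"
  else "almost perfect"
}

#' Cohen's kappa for a square agreement table
#'
#' Chance-corrected agreement kappa = (p_o - p_e)/(1 - p_e) with observed
#' agreement p_o = trace/n and expected agreement p_e from the margins.
#' The standard error uses the large-sample asymptotic variance of
#' Fleiss, Cohen and Everitt; the 95% CI is kappa +/- 1.96 se truncated to
#' `[-1,1]`.
#'
#' @param t square matrix of agreement counts (raters in rows/columns, same
#'   category order), or a [contingency_2x2()] read as an agreement table.
#' @return `kappa_result`: `kappa`, `p_o`, `p_e`, `se`, `ci95`,
#'   `landis_koch_label`, `n`.
#' @export
cohen_kappa <- function(t) {
  if (inherits(t, "contingency_2x2")) t <- as.matrix(t)
  t <- as.matrix(t)
  if (nrow(t) != ncol(t)) stop("agreement table must be square", call. = FALSE)
  n <- sum(t)
  if (n <= 0) stop("agreement table is empty", call. = FALSE)
  p <- t / n
  pi. <- rowSums(p)
  p.j <- colSums(p)
  p_o <- sum(diag(p))
  p_e <- sum(pi. * p.j)
  if (1 - p_e < .Machine$double.eps^0.5)
    stop("kappa undefined: expected agreement is 1 (both raters constant)",
         call. = FALSE)
  kappa <- (p_o - p_e) / (1 - p_e)

  # Fleiss-Cohen-Everitt asymptotic variance
  k <- nrow(p)
  a <- sum(diag(p) * (1 - (pi. + p.j) * (1 - kappa))^2)
  b <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j)
    b <- b + p[i, j] * (p.j[i] + pi.[j])^2
  b <- (1 - kappa)^2 * b
  cc <- (kappa - p_e * (1 - kappa))^2
  v <- (a + b - cc) / (n * (1 - p_e)^2)
  se <- sqrt(max(v, 0))
  ci <- pmin(1, pmax(-1, kappa + c(-1, 1) * 1.96 * se))
  structure(list(kappa = kappa, p_o = p_o, p_e = p_e, se = se, ci95 = ci,
                 landis_koch_label = landis_koch(kappa), n = n),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa %.2f (%s), 95%% CI %.2f-%.2f, n = %d\n",
              x$kappa, x$landis_koch_label, x$ci95[1], x$ci95[2], x$n))
  cat(sprintf("  observed agreement %.1f%%, expected %.1f%%\n",
              100 * x$p_o, 100 * x$p_e))
  invisible(x)
}

#' Percent agreement of a square agreement table
#'
#' @param t square matrix of counts (or [contingency_2x2()]).
#' @return Proportion of agreeing pairs (trace/n).
#' @export
percent_agreement <- function(t) {
  if (inherits(t, "contingency_2x2")) t <- as.matrix(t)
  t <- as.matrix(t)
  if (nrow(t) != ncol(t)) stop("agreement table must be square", call. = FALSE)
  n <- sum(t)
  if (n <= 0) stop("agreement table is empty", call. = FALSE)
  sum(diag(t)) / n
}

#' Spearman rank-order correlation
#'
#' Pearson correlation of mid-ranks (average ranks on ties).
#'
#' @param x,y equal-length numeric/ordinal vectors (length >= 3).
#' @return rho in `[-1,1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("rho undefined for constant input", call. = FALSE)
  stats::cor(rank(x), rank(y))
}

#' Mann-Whitney U test
#'
#' U computed from rank sums with average ranks on ties. For
#' `min(n1, n2) <= 8` (or `exact = TRUE`) the two-sided p-value is obtained
#' by exhaustive enumeration of all group labelings of the pooled sample
#' (permutation-exact, valid under ties); otherwise by the tie-corrected
#' normal approximation with continuity correction.
#'
#' @param a,b numeric vectors (non-empty).
#' @param exact force (`TRUE`)/suppress (`FALSE`) the enumeration path;
#'   default `NULL` chooses by sample size.
#' @return `group_comparison` object: `statistic` (U for group `a`),
#'   `p_value`, `method`, `n`.
#' @export
mann_whitney_u <- function(a, b, exact = NULL) {
  a <- as.numeric(a[!is.na(a)]); b <- as.numeric(b[!is.na(b)])
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty", call. = FALSE)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_of <- function(idx_a) sum(r[idx_a]) - n1 * (n1 + 1) / 2
  U <- u_of(seq_len(n1))
  mu <- n1 * n2 / 2

  if (is.null(exact)) exact <- min(n1, n2) <= 8L
  if (exact) {
    combs <- utils::combn(n1 + n2, n1)
    us <- apply(combs, 2, function(ix) sum(r[ix])) - n1 * (n1 + 1) / 2
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    n <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
      z <- max(z, 0)
      p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    }
    method <- "normal approximation, tie + continuity corrected"
  }
  structure(list(statistic = U, p_value = p, method = method,
                 n = c(n1 = n1, n2 = n2)),
            class = "group_comparison")
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H with a chi-square reference distribution on k-1 degrees
#' of freedom (delegating to [stats::kruskal.test()]).
#'
#' @param groups list of >= 2 non-empty numeric vectors.
#' @return `group_comparison` object: `statistic` (H), `p_value`, `df`, `n`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, 0L) == 0L))
    stop("all groups must be non-empty", call. = FALSE)
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  if (length(unique(x)) == 1L) {
    # all observations tied across every group: no rank variation, H = 0
    return(structure(list(statistic = 0, p_value = 1,
                          df = length(groups) - 1L,
                          n = vapply(groups, length, 0L)),
                     class = "group_comparison"))
  }
  kt <- stats::kruskal.test(x, g)
  structure(list(statistic = unname(kt$statistic),
                 p_value = kt$p.value, df = unname(kt$parameter),
                 n = vapply(groups, length, 0L)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("statistic = %.3f, p = %.4g (%s), n = %s\n",
              x$statistic, x$p_value,
              if (is.null(x$method)) "Kruskal-Wallis" else x$method,
              paste(x$n, collapse = "/")))
  invisible(x)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value summing hypergeometric probabilities no larger than
#' the observed table's (the [stats::fisher.test()] rule).
#'
#' @param t a [contingency_2x2()] or 2x2 count matrix.
#' @return p-value.
#' @export
fisher_exact <- function(t) {
  if (inherits(t, "contingency_2x2")) t <- as.matrix(t)
  stats::fisher.test(as.matrix(t))$p.value
}

#' Youden-optimal cutoff for an ordinal score
#'
#' Evaluates the rule "positive if score >= c" at every observed score
#' value, computing sensitivity and specificity against the binary labels,
#' and returns the cutoff maximizing Youden's J = sensitivity +
#' specificity - 1. Ties are broken toward the smallest cutoff. When all
#' scores are equal the (degenerate) single value is returned with J = 0
#' and a warning.
#'
#' @param scores numeric/ordinal vector.
#' @param labels parallel binary vector.
#' @param positive label treated as the positive class (default "advanced").
#' @return `cutoff_result`: `cutoff`, `youden_j`, and `table` with
#'   per-cutoff sensitivity/specificity/J.
#' @export
optimal_cutoff <- function(scores, labels, positive = "advanced") {
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- as.numeric(scores[ok]); labels <- labels[ok]
  pos <- labels == positive
  if (all(pos) || !any(pos))
    stop("both classes must be present in `labels`", call. = FALSE)
  cand <- sort(unique(scores))
  tab <- do.call(rbind, lapply(cand, function(cc) {
    call_pos <- scores >= cc
    data.frame(cutoff = cc,
               sensitivity = sum(call_pos & pos) / sum(pos),
               specificity = sum(!call_pos & !pos) / sum(!pos))
  }))
  tab$youden_j <- tab$sensitivity + tab$specificity - 1
  if (length(cand) == 1L) {
    warning("all scores equal; degenerate cutoff", call. = FALSE)
    best <- 1L
  } else {
    best <- which.max(tab$youden_j)  # which.max takes the first = smallest c
  }
  structure(list(cutoff = tab$cutoff[best], youden_j = tab$youden_j[best],
                 table = tab),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("Youden-optimal cutoff: score >= %g (J = %.3f)\n",
              x$cutoff, x$youden_j))
  invisible(x)
}

#' Power of the two-sided one-sample proportion test
#'
#' Normal-approximation power: the rejection boundaries are
#' p0 +/- z_(1-alpha/2) sqrt(p0(1-p0)/n); the power is the probability,
#' under the alternative p1, of the sample proportion falling beyond
#' either boundary (the opposite-tail term is included, though negligible
#' away from the null).
#'
#' @param p0 null proportion (0 < p0 < 1).
#' @param p1 alternative proportion (0 < p1 < 1).
#' @param n sample size (>= 10).
#' @param alpha two-sided significance level (default 0.05).
#' @return Power in `[0,1]`.
#' @export
power_one_sample_prop <- function(p0, p1, n, alpha = 0.05) {
  if (!(p0 > 0 && p0 < 1) || !(p1 > 0 && p1 < 1))
    stop("p0 and p1 must lie strictly in (0,1)", call. = FALSE)
  if (n < 10) stop("n must be at least 10", call. = FALSE)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0,1)", call. = FALSE)
  z <- stats::qnorm(1 - alpha / 2)
  se0 <- sqrt(p0 * (1 - p0) / n)
  se1 <- sqrt(p1 * (1 - p1) / n)
  upper <- p0 + z * se0
  lower <- p0 - z * se0
  stats::pnorm((p1 - upper) / se1) + stats::pnorm((lower - p1) / se1)
}
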