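test_that("contingency construction partitions paired diagnoses", {
  idx <- c("advanced", "advanced", "non-advanced", "non-advanced")
  expect_equal(unclass(build_contingency(idx, idx))[c("fp", "fn")],
               list(fp = 0L, fn = 0L))
  t2 <- build_contingency(rep("advanced", 2), rep("non-advanced", 2))
  expect_equal(c(t2$tp, t2$fp), c(0L, 2L))
  expect_error(build_contingency("advanced", character(0)), "length")
  expect_error(contingency_2x2(0, 0, 0, 0), "empty")
  expect_error(contingency_2x2(-1, 1, 1, 1), "non-negative")
})

test_that("diagnostic performance identities hold on random tables", {
  set.seed(14)
  for (i in 1:25) {
    t <- contingency_2x2(sample(1:60, 1), sample(1:60, 1),
                         sample(1:60, 1), sample(1:60, 1))
    p <- diagnostic_performance(t)
    expect_equal(p$sensitivity + p$fn_rate, 1)
    expect_equal(p$specificity + p$fp_rate, 1)
    expect_equal(p$auc_binary, (p$sensitivity + p$specificity) / 2)
    expect_equal(p$accuracy, (t$tp + t$tn) / p$n)
    expect_equal(p$ppv, t$tp / (t$tp + t$fp))
    expect_equal(p$npv, t$tn / (t$tn + t$fn))
  }
  perfect <- diagnostic_performance(contingency_2x2(7, 0, 0, 11))
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "ppv", "npv",
                                "accuracy", "auc_binary")]),
               c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1,
                 accuracy = 1, auc_binary = 1))
  flat <- diagnostic_performance(contingency_2x2(1, 1, 1, 1))
  expect_equal(unlist(flat[c("sensitivity", "specificity", "ppv", "npv",
                             "accuracy")]), rep(0.5, 5), ignore_attr = TRUE)
})

test_that("degenerate margins yield NA for the affected statistic only", {
  expect_message(p <- diagnostic_performance(contingency_2x2(0, 3, 0, 5)),
                 "sensitivity")
  expect_true(is.na(p$sensitivity))
  expect_false(is.na(p$specificity))
  expect_false(is.na(p$accuracy))
})

test_that("kappa matches a first-principles oracle on random 2x2 tables", {
  set.seed(31)
  for (i in 1:25) {
    tab <- matrix(sample(0:40, 4, replace = TRUE), 2)
    if (sum(tab) == 0) tab[1, 1] <- 1
    k <- try(cohen_kappa(tab), silent = TRUE)
    o <- oracle_kappa(tab)
    if (!is.finite(o)) {
      expect_s3_class(k, "try-error")
    } else {
      expect_equal(k$kappa, o)
    }
  }
})

test_that("kappa edge behaviour: perfection, independence, symmetry", {
  perfect <- cohen_kappa(matrix(c(12, 0, 0, 30), 2))
  expect_equal(perfect$kappa, 1)
  expect_equal(perfect$landis_koch_label, "almost perfect")

  indep <- cohen_kappa(matrix(c(1, 1, 1, 1), 2))
  expect_equal(indep$kappa, 0)
  expect_equal(indep$p_o, 0.5)
  expect_equal(indep$p_e, 0.5)

  # invariant to simultaneous permutation of the category order
  tab <- matrix(c(20, 5, 8, 40), 2)
  expect_equal(cohen_kappa(tab)$kappa, cohen_kappa(tab[2:1, 2:1])$kappa)
  expect_true(abs(cohen_kappa(tab)$kappa) <= 1)

  expect_error(cohen_kappa(matrix(c(5, 0, 0, 0), 2)), "undefined")
})

test_that("Landis-Koch bands label the printed ranges", {
  expect_equal(landis_koch(0.10), "negligible")
  expect_equal(landis_koch(0.30), "weak")
  expect_equal(landis_koch(0.48), "moderate")
  expect_equal(landis_koch(0.70), "substantial")
  expect_equal(landis_koch(0.90), "almost perfect")
  expect_equal(landis_koch(-0.2), "below negligible")
})

test_that("percent agreement reproduces the printed reliability fractions", {
  expect_equal(percent_agreement(matrix(c(9, 0, 0, 4), 2)), 1)
  # 92/96 is the only integer count printing as 95.8% at n = 96
  expect_equal(round(100 * 92 / 96, 1), 95.8)
  expect_equal(percent_agreement(matrix(c(60, 2, 2, 32), 2)), 92 / 96)
  # 43/46 likewise prints as the reported 93.5%
  expect_equal(round(100 * percent_agreement(matrix(c(30, 2, 1, 13), 2)), 1),
               93.5)
})

test_that("Spearman rho equals the rank-difference formula", {
  expect_equal(spearman_rho(1:7, 1:7), 1)
  expect_equal(spearman_rho(1:7, 7:1), -1)
  # hand computation: d = (0,1,-1,1,-1), sum d^2 = 4... using the classic
  # 1 - 6*sum(d^2)/(n(n^2-1)) for untied data
  x <- c(1, 2, 3, 4, 5); y <- c(1, 3, 2, 5, 4)
  expect_equal(spearman_rho(x, y), 1 - 6 * 4 / (5 * 24))
  expect_equal(spearman_rho(x, y), 0.8)
  expect_error(spearman_rho(c(1, 1, 1), c(1, 2, 3)), "constant")

  set.seed(8)
  for (i in 1:20) {
    a <- sample(1:5, 12, replace = TRUE)
    b <- a + sample(-2:2, 12, replace = TRUE)
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    expect_equal(spearman_rho(a, b),
                 suppressWarnings(stats::cor.test(a, b,
                                                  method = "spearman")$estimate),
                 ignore_attr = TRUE)
  }
})

test_that("Mann-Whitney U: rank-sum identities and exact enumeration", {
  expect_equal(mann_whitney_u(5, 5)$statistic, 0.5)
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4))$statistic, 0)

  set.seed(13)
  for (i in 1:20) {
    n1 <- sample(3:7, 1); n2 <- sample(3:8, 1)
    a <- sample(1:6, n1, replace = TRUE)
    b <- sample(1:6, n2, replace = TRUE) + sample(0:2, 1)
    res <- mann_whitney_u(a, b)
    expect_equal(res$p_value, oracle_mwu_exact(a, b))
    # U_a + U_b = n1 * n2
    expect_equal(res$statistic + mann_whitney_u(b, a)$statistic, n1 * n2)
    expect_true(res$p_value > 0 && res$p_value <= 1)
  }
})

test_that("Mann-Whitney normal approximation tracks wilcox.test", {
  set.seed(19)
  a <- rnorm(40, 0); b <- rnorm(35, 0.7)
  res <- mann_whitney_u(a, b)
  wt <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(res$statistic, unname(wt$statistic))
  expect_equal(res$p_value, wt$p.value, tolerance = 1e-10)
})

test_that("Kruskal-Wallis H equals the rank-sum formula with ties", {
  set.seed(23)
  for (i in 1:20) {
    groups <- lapply(1:3, function(g)
      sample(1:8, sample(4:9, 1), replace = TRUE))
    res <- kruskal_wallis(groups)
    expect_equal(res$statistic, oracle_kw_h(groups))
    expect_equal(res$df, 2)
  }
  same <- kruskal_wallis(list(rep(2, 5), rep(2, 4)))
  expect_equal(same$statistic, 0)
  expect_error(kruskal_wallis(list(1:3)), "2 groups")

  # k = 2 consistency with the U test on clear separation
  a <- 1:10; b <- 11:20
  expect_lt(kruskal_wallis(list(a, b))$p_value, 0.05)
  expect_lt(mann_whitney_u(a, b)$p_value, 0.05)
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  expect_equal(fisher_exact(contingency_2x2(5, 5, 5, 5)), 1)
  expect_equal(fisher_exact(contingency_2x2(10, 0, 0, 10)),
               oracle_fisher(10, 0, 0, 10))
  set.seed(37)
  for (i in 1:20) {
    k <- sample(0:12, 4, replace = TRUE)
    if (sum(k) == 0) k[1] <- 1
    expect_equal(fisher_exact(contingency_2x2(k[1], k[2], k[3], k[4])),
                 oracle_fisher(k[1], k[2], k[3], k[4]), tolerance = 1e-9)
  }
  # tables proportional to their margins carry no association
  expect_equal(fisher_exact(contingency_2x2(4, 8, 2, 4)), 1)
})

test_that("Youden cutoff scans observed values with smallest-c tie-break", {
  perfect <- optimal_cutoff(c(1, 2, 9, 10),
                            c("non-advanced", "non-advanced",
                              "advanced", "advanced"))
  expect_equal(perfect$cutoff, 9)
  expect_equal(perfect$youden_j, 1)
  expect_equal(nrow(perfect$table), 4)

  expect_warning(deg <- optimal_cutoff(rep(5, 6),
                                       rep(c("advanced", "non-advanced"), 3)),
                 "degenerate")
  expect_equal(deg$cutoff, 5)
  expect_equal(deg$youden_j, 0)

  # exhaustive check of the J maximum against a direct scan
  set.seed(41)
  for (i in 1:10) {
    sc <- sample(0:24, 60, replace = TRUE)
    lb <- ifelse(runif(60) < stats::plogis((sc - 9) / 3),
                 "advanced", "non-advanced")
    if (length(unique(lb)) < 2) next
    res <- optimal_cutoff(sc, lb)
    js <- vapply(sort(unique(sc)), function(cc)
      mean(sc[lb == "advanced"] >= cc) +
        mean(sc[lb == "non-advanced"] < cc) - 1, 0)
    expect_equal(res$youden_j, max(js))
    expect_equal(res$cutoff, sort(unique(sc))[which.max(js)])
  }
  expect_error(optimal_cutoff(1:4, rep("advanced", 4)), "both classes")
})

test_that("one-sample proportion power behaves across the parameter space", {
  # null equals alternative: power collapses to the test size
  expect_equal(round(power_one_sample_prop(0.25, 0.25, 100), 2), 0.05)
  # monotone in effect size and n
  expect_lt(power_one_sample_prop(0.25, 0.30, 100),
            power_one_sample_prop(0.25, 0.40, 100))
  expect_lt(power_one_sample_prop(0.25, 0.35, 50),
            power_one_sample_prop(0.25, 0.35, 200))
  expect_error(power_one_sample_prop(0, 0.4, 100), "strictly")
  expect_error(power_one_sample_prop(0.25, 0.4, 5), "at least 10")
})
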