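# Nonparametric tests, Holm adjustment, adjusted contrasts, power.

# independent enumeration oracle for the two-sided Mann-Whitney p
mw_enum_oracle <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  mu <- n1 * (n - n1) / 2
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  hits <- 0; total <- 0
  for (sel in utils::combn(n, n1, simplify = FALSE)) {
    u <- sum(r[sel]) - n1 * (n1 + 1) / 2
    total <- total + 1
    if (abs(u - mu) >= abs(u_obs - mu) - 1e-9) hits <- hits + 1
  }
  hits / total
}

test_that("Mann-Whitney exact path matches hand and enumeration oracles", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_raw, 2 / 6)
  expect_identical(r$method, "MANN_WHITNEY")

  # identical multisets: p = 1 by symmetry
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_raw, 1)

  set.seed(5)
  for (rep in 1:5) {
    x <- rnorm(8); y <- rnorm(8)
    expect_equal(mann_whitney(x, y)$p_raw, mw_enum_oracle(x, y),
                 tolerance = 1e-12)
  }
  # with ties
  x <- c(1, 1, 2, 5); y <- c(1, 2, 2, 7)
  expect_equal(mann_whitney(x, y)$p_raw, mw_enum_oracle(x, y),
               tolerance = 1e-12)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney approximate path agrees with wilcox.test", {
  set.seed(6)
  x <- rnorm(30); y <- rnorm(25, 0.4)
  r <- mann_whitney(x, y)
  expect_identical(r$method, "MANN_WHITNEY_APPROX")
  w <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(r$p_raw, w$p.value, tolerance = 1e-10)
  expect_equal(r$statistic, unname(w$statistic))
})

test_that("Kruskal-Wallis H and its identities", {
  r <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(r$statistic, 32 / 7, tolerance = 1e-12)  # 4.5714...
  k <- kruskal.test(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(r$statistic, unname(k$statistic))
  expect_equal(r$p_raw, k$p.value)

  # two untied groups: H equals the squared normal-approx MW z
  set.seed(8)
  x <- rnorm(12); y <- rnorm(15)
  h <- kruskal_wallis(list(x, y))$statistic
  u <- mann_whitney(x, y)$statistic
  z <- (u - 12 * 15 / 2) / sqrt(12 * 15 * 28 / 12)
  expect_equal(h, z^2, tolerance = 1e-10)

  expect_warning(r <- kruskal_wallis(list(c(1, 1), c(1, 1))), "tied")
  expect_equal(r$p_raw, 1)
  expect_error(kruskal_wallis(list(1:3)), ">= 2")
})

test_that("Fisher 2x2 exact p by hypergeometric point-probability rule", {
  expect_equal(fisher_exact(matrix(c(1, 0, 0, 1), 2))$p_raw, 1)
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), 2))$p_raw, 2 / 252)
  # printed count pairs: 15/29 vs 5/41 high TG PRS
  tab <- matrix(c(15, 14, 5, 36), 2, byrow = TRUE)
  p <- fisher_exact(tab)$p_raw
  expect_equal(p, fisher.test(tab)$p.value, tolerance = 1e-9)
  set.seed(9)
  for (rep in 1:20) {
    t2 <- matrix(rpois(4, 6), 2)
    if (any(rowSums(t2) == 0) || any(colSums(t2) == 0)) next
    expect_equal(fisher_exact(t2)$p_raw, fisher.test(t2)$p.value,
                 tolerance = 1e-9)
  }
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("Fisher r x c enumeration matches fisher.test; MC is seeded", {
  set.seed(10)
  for (rep in 1:10) {
    t3 <- matrix(rpois(6, 4), 2, 3)
    if (any(rowSums(t3) == 0) || any(colSums(t3) == 0)) next
    r <- fisher_exact(t3)
    expect_identical(r$method, "FISHER_RxC")
    expect_equal(r$p_raw, fisher.test(t3)$p.value, tolerance = 1e-9)
  }
  big <- matrix(rpois(12, 60), 3, 4)
  set.seed(1); p1 <- fisher_exact(big, max_tables = 10, mc_reps = 2e4)
  set.seed(1); p2 <- fisher_exact(big, max_tables = 10, mc_reps = 2e4)
  expect_identical(p1$p_raw, p2$p_raw)
  expect_identical(p1$method, "FISHER_RxC_MC")
  expect_false(is.na(p1$mc_se))
  # MC estimate consistent with the exact value
  exact <- fisher_exact(big)$p_raw
  expect_lt(abs(p1$p_raw - exact), 4 * p1$mc_se + 1e-4)
})

test_that("Holm step-down formula, properties, and p.adjust agreement", {
  expect_equal(holm_adjust(0.04), 0.04)
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  set.seed(12)
  for (rep in 1:50) {
    p <- runif(sample(1:8, 1))
    a <- holm_adjust(p)
    expect_equal(a, p.adjust(p, "holm"), tolerance = 1e-12)
    expect_true(all(a >= p) && all(a <= 1))
    o <- order(p)
    expect_true(all(diff(a[o]) >= -1e-12))
    expect_equal(a[o][1], min(1, length(p) * p[o][1]))  # Bonferroni on min
  }
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("adjusted contrasts detect a real group effect and flag fallback", {
  set.seed(13)
  n <- 200
  g <- rep(c("A", "B", "C"), each = n)
  cov <- data.frame(age = rnorm(3 * n, 50, 8),
                    sex = rbinom(3 * n, 1, 0.5))
  y <- rnorm(3 * n) + ifelse(g == "C", 1.2, 0)   # C shifted
  res <- adjusted_pairwise_contrasts(y, g, cov)
  expect_equal(nrow(res), 3)
  expect_true(all(res$method == "LOGISTIC_WALD"))
  expect_lt(res$p_adjusted[res$contrast == "A vs C"], 0.05)
  expect_lt(res$p_adjusted[res$contrast == "B vs C"], 0.05)
  expect_gt(res$p_adjusted[res$contrast == "A vs B"], 0.05)
  expect_true(all(res$p_adjusted >= res$p_raw))

  # a group with (almost) no events forces the Mann-Whitney fallback
  y2 <- c(rnorm(50, 0), rnorm(50, 0))
  y2[1:50] <- -abs(y2[1:50])      # group A never exceeds the median... ensure
  y2[51:100] <- abs(y2[51:100]) + 1
  g2 <- rep(c("A", "B"), each = 50)
  res2 <- adjusted_pairwise_contrasts(y2, g2, NULL)
  expect_true(res2$fallback_used[1])
  expect_match(res2$method[1], "MANN_WHITNEY")
  expect_error(adjusted_pairwise_contrasts(rep(1, 20), rep(c("A", "B"), 10), NULL),
               "constant")
})

test_that("single-factor comparisons against control", {
  set.seed(14)
  g <- rep(c("FD", "FH", "CONTROL"), each = 40)
  y <- rnorm(120) + ifelse(g == "FD", 2, 0)
  res <- single_factor_comparison(y, g)
  expect_equal(nrow(res), 2)
  expect_lt(res$p_adjusted[res$contrast == "FD vs CONTROL"], 0.05)
  # single contrast: adjusted equals raw
  res1 <- single_factor_comparison(y[g != "FH"], g[g != "FH"])
  expect_equal(res1$p_adjusted, res1$p_raw)
  # categorical outcome goes through Fisher
  x <- factor(rbinom(120, 1, ifelse(g == "FH", 0.8, 0.2)))
  resc <- single_factor_comparison(x, g)
  expect_match(resc$method[resc$contrast == "FH vs CONTROL"], "FISHER")
  expect_lt(resc$p_adjusted[resc$contrast == "FH vs CONTROL"], 0.05)
  expect_error(single_factor_comparison(y, rep("FD", 120)), "control")
})

test_that("detectable difference: inverse consistency, limits, scaling", {
  d <- detectable_difference(1000, 1000, 1)
  expect_equal(t_test_power(d, 1000, 1000, 1), 0.80, tolerance = 1e-6)
  # normal-approximation limit
  norm_limit <- (qnorm(0.975) + qnorm(0.8)) * sqrt(2 / 1000)
  expect_equal(d, norm_limit, tolerance = 0.01 * norm_limit)
  # monotone in n, equivariant in sd
  expect_gt(detectable_difference(29, 41, 1), detectable_difference(100, 100, 1))
  expect_equal(detectable_difference(29, 41, 2),
               2 * detectable_difference(29, 41, 1), tolerance = 1e-8)
  expect_error(detectable_difference(1, 10, 1))
})

test_that("summaries reproduce printed-style medians and percentages", {
  s <- summarize_values(c(1, 2, 3, 4, 5))
  expect_equal(c(s$median, s$q1, s$q3), c(3, 2, 4))
  s1 <- summarize_values(42)
  expect_true(s1$median == s1$q1 && s1$q1 == s1$q3)
  cat51 <- summarize_values(factor(rep(c("yes", "no"), c(51, 10))))
  expect_equal(cat51$percent[cat51$level == "yes"], 100 * 51 / 61)
  expect_identical(count_percent(51, 61), "51 (83.6)")
  expect_identical(count_percent(72, 180), "72 (40.0)")
  expect_error(summarize_values(numeric(0)), "empty")
})
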