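.comparison_result <- function(contrast, method, statistic, p_raw,
                               p_adjusted = NA_real_, fallback_used = FALSE,
                               mc_se = NA_real_) {
  data.frame(contrast = contrast, method = method, statistic = statistic,
             p_raw = p_raw, p_adjusted = p_adjusted,
             fallback_used = fallback_used, mc_se = mc_se,
             stringsAsFactors = FALSE)
}

#' Mann-Whitney U test (two-sided, midrank ties)
#'
#' Computes the U statistic for the first sample from pooled midranks.
#' When the combined sample size does not exceed `exact_cutoff` the exact
#' permutation p-value is used: the fraction of all label assignments
#' whose U is at least as far from its null mean `n1*n2/2` as observed.
#' Larger samples use the tie-corrected normal approximation (no
#' continuity correction).
#'
#' @param x,y Non-empty numeric samples.
#' @param exact_cutoff Combined-size bound for exact enumeration
#'   (default 20).
#' @return One-row comparison data.frame (`method` is `"MANN_WHITNEY"` or
#'   `"MANN_WHITNEY_APPROX"`).
#' @export
mann_whitney <- function(x, y, exact_cutoff = 20) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n <= exact_cutoff) {
    idx <- utils::combn(n, n1)
    usum <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(usum - mu) >= abs(u - mu) - 1e-9)
    return(.comparison_result("x vs y", "MANN_WHITNEY", u, p))
  }
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) {
    warning("all observations tied; p = 1")
    return(.comparison_result("x vs y", "MANN_WHITNEY_APPROX", u, 1))
  }
  z <- (u - mu) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  .comparison_result("x vs y", "MANN_WHITNEY_APPROX", u, p)
}

#' Kruskal-Wallis test (tie-corrected)
#'
#' @param groups List of two or more non-empty numeric samples.
#' @return One-row comparison data.frame; statistic is the tie-corrected H,
#'   p from the chi-square approximation with k-1 df.
#' @export
kruskal_wallis <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2 || any(!lengths(groups))) {
    stop("need >= 2 non-empty groups")
  }
  k <- length(groups)
  all_x <- unlist(groups)
  n <- length(all_x)
  r <- rank(all_x)
  idx <- rep(seq_len(k), lengths(groups))
  rsum <- tapply(r, idx, sum)
  h <- 12 / (n * (n + 1)) * sum(rsum^2 / lengths(groups)) - 3 * (n + 1)
  ties <- table(r)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr <= 0) {
    warning("all observations tied; p = 1")
    return(.comparison_result("omnibus", "KRUSKAL_WALLIS", 0, 1))
  }
  h <- h / corr
  p <- stats::pchisq(h, df = k - 1, lower.tail = FALSE)
  .comparison_result("omnibus", "KRUSKAL_WALLIS", h, p)
}

.log_table_prob <- function(tab, lr, lc, ln) {
  # multivariate hypergeometric probability of a table with fixed margins
  sum(lr) + sum(lc) - ln - sum(lgamma(tab + 1))
}

.table_space_bound <- function(row_sums, n_cols) {
  # compositions of each free row into n_cols non-negative parts
  r <- length(row_sums)
  prod(choose(row_sums[-r] + n_cols - 1, n_cols - 1))
}

.enum_tables <- function(row_sums, col_sums) {
  r <- length(row_sums); c <- length(col_sums)
  out <- list()
  rec_row <- function(tab, i, remaining_cols) {
    if (i == r) {
      tab[r, ] <- remaining_cols   # forced last row; margins balance by design
      out[[length(out) + 1L]] <<- tab
      return(invisible(NULL))
    }
    comp <- function(j, left, row) {
      if (j == c) {
        if (left <= remaining_cols[c]) {
          row[c] <- left
          tab[i, ] <- row
          rec_row(tab, i + 1L, remaining_cols - row)
        }
        return(invisible(NULL))
      }
      for (v in 0:min(left, remaining_cols[j])) {
        row[j] <- v
        comp(j + 1L, left - v, row)
      }
    }
    comp(1L, row_sums[i], integer(c))
  }
  rec_row(matrix(0L, r, c), 1L, col_sums)
  out
}

#' Two-sided Fisher exact test
#'
#' For 2x2 tables the p-value sums the hypergeometric point probabilities
#' of all tables no more probable than the observed one (the
#' point-probability convention). For r x c tables the same rule is applied
#' by exhaustive enumeration of tables with the observed margins when at
#' most `max_tables` tables exist; otherwise a seeded Monte-Carlo estimate
#' (Patefield sampling via [stats::r2dtable()]) is returned with its
#' standard error in `mc_se`.
#'
#' @param tab Matrix of non-negative integer counts.
#' @param max_tables Enumeration bound (default 1e6).
#' @param mc_reps Monte-Carlo replicates when enumeration is infeasible.
#' @return One-row comparison data.frame; `method` is `"FISHER_2x2"`,
#'   `"FISHER_RxC"` or `"FISHER_RxC_MC"`. The statistic is the observed
#'   table log-probability (2x2: the sample odds ratio).
#' @export
fisher_exact <- function(tab, max_tables = 1e6, mc_reps = 1e5) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers")
  }
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (n == 0) stop("empty table")
  rel_eps <- 1 + 1e-7
  if (all(dim(tab) == c(2, 2))) {
    m <- cs[1]; k <- rs[1]
    support <- max(0, k - cs[2]):min(k, m)
    probs <- stats::dhyper(support, m, cs[2], k)
    p_obs <- stats::dhyper(tab[1, 1], m, cs[2], k)
    p <- sum(probs[probs <= p_obs * rel_eps])
    or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
    return(.comparison_result("2x2", "FISHER_2x2", or, min(1, p)))
  }
  lr <- lgamma(rs + 1); lc <- lgamma(cs + 1); ln <- lgamma(n + 1)
  lp_obs <- .log_table_prob(tab, lr, lc, ln)
  if (.table_space_bound(rs, length(cs)) <= max_tables) {
    tables <- .enum_tables(rs, cs)
    lps <- vapply(tables, .log_table_prob, numeric(1), lr, lc, ln)
    p <- sum(exp(lps[lps <= lp_obs + log(rel_eps)]))
    return(.comparison_result("rxc", "FISHER_RxC", lp_obs, min(1, p)))
  }
  sims <- stats::r2dtable(mc_reps, rs, cs)
  lps <- vapply(sims, .log_table_prob, numeric(1), lr, lc, ln)
  hits <- sum(lps <= lp_obs + log(rel_eps))
  p <- (hits + 1) / (mc_reps + 1)
  se <- sqrt(p * (1 - p) / mc_reps)
  .comparison_result("rxc", "FISHER_RxC_MC", lp_obs, p, mc_se = se)
}

#' Holm-Bonferroni step-down adjustment
#'
#' `p_adj(i) = max_{j <= i} min(1, (m - j + 1) * p_(j))` along the sorted
#' raw p-values, returned in the original input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
holm_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (!m) return(numeric(0))
  o <- order(p)
  adj_sorted <- cummax(pmin(1, (m - seq_len(m) + 1) * p[o]))
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

.pair_label <- function(a, b) paste(a, "vs", b)

#' Covariate-adjusted pairwise contrasts via median-split logistic models
#'
#' A continuous outcome is discretized against the whole-sample median
#' (indicator of exceeding it); for each pair of groups a logistic model
#' of the indicator on the pair-membership dummy plus the covariates is
#' fitted and the Wald p-value for the dummy reported. On
#' non-convergence, complete separation (any fitted probability within
#' 1e-8 of 0 or 1, or |coefficient| > 15), or when either group carries
#' fewer than `min_events` events or non-events, the model is abandoned
#' for that pair and the unadjusted Mann-Whitney test on the original
#' outcome is used instead (`fallback_used = TRUE`). Rows with missing
#' values are list-wise deleted. Holm adjustment is applied over the
#' pairwise family.
#'
#' @param outcome Numeric outcome (or logical, taken as already binary).
#' @param group_labels Group label per observation.
#' @param covariates data.frame of covariates (may be NULL for none).
#' @param discretize_at_median Discretize a numeric outcome (default TRUE).
#' @param min_events Minimum events and non-events per group (default 5).
#' @return data.frame of comparison rows, one per unordered group pair.
#' @export
adjusted_pairwise_contrasts <- function(outcome, group_labels,
                                        covariates = NULL,
                                        discretize_at_median = TRUE,
                                        min_events = 5) {
  stopifnot(length(outcome) == length(group_labels))
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == length(outcome))
    cc <- stats::complete.cases(outcome, group_labels, covariates)
  } else {
    cc <- stats::complete.cases(outcome, group_labels)
  }
  outcome <- outcome[cc]; group_labels <- group_labels[cc]
  if (!is.null(covariates)) covariates <- covariates[cc, , drop = FALSE]
  if (is.logical(outcome)) {
    y_all <- outcome
  } else if (discretize_at_median) {
    med <- stats::median(outcome)
    y_all <- outcome > med
  } else {
    y_all <- outcome > 0
  }
  if (length(unique(y_all)) < 2) stop("outcome is constant after discretization")
  groups <- sort(unique(group_labels))
  if (length(groups) < 2) stop("need >= 2 groups")
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    sel <- group_labels %in% pr
    y <- y_all[sel]
    d <- as.integer(group_labels[sel] == pr[2])
    label <- .pair_label(pr[1], pr[2])
    ev <- table(factor(y, c(FALSE, TRUE)), factor(d, 0:1))
    enough <- all(ev >= min_events)
    fit_ok <- FALSE
    if (enough) {
      dat <- data.frame(y = y, d = d)
      if (!is.null(covariates)) dat <- cbind(dat, covariates[sel, , drop = FALSE])
      fit <- tryCatch(
        suppressWarnings(stats::glm(y ~ ., data = dat, family = stats::binomial(),
                                    control = stats::glm.control(maxit = 50))),
        error = function(e) NULL)
      if (!is.null(fit) && fit$converged &&
          !any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8) &&
          all(abs(stats::coef(fit)[-1]) < 15, na.rm = TRUE) &&
          !is.na(stats::coef(fit)["d"])) {
        sm <- summary(fit)$coefficients
        z <- sm["d", "z value"]; p <- sm["d", "Pr(>|z|)"]
        fit_ok <- TRUE
        return(.comparison_result(label, "LOGISTIC_WALD", z, p))
      }
    }
    if (!fit_ok) {
      xo <- outcome[sel]
      mw <- mann_whitney(xo[d == 0], xo[d == 1])
      .comparison_result(label, mw$method, mw$statistic, mw$p_raw,
                         fallback_used = TRUE)
    }
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- holm_adjust(res$p_raw)
  res
}

#' Single-factor comparisons of each study group against the control
#'
#' For sparse outcomes (the control-group situation) no covariate model is
#' fitted: a continuous outcome is compared by the Mann-Whitney test and a
#' categorical one by Fisher's exact test, each study group against the
#' control, with Holm adjustment over the family.
#'
#' @param outcome Numeric, logical or factor outcome.
#' @param group_labels Group label per observation.
#' @param control_label Label of the control group.
#' @return data.frame of comparison rows.
#' @export
single_factor_comparison <- function(outcome, group_labels,
                                     control_label = "CONTROL") {
  if (!control_label %in% group_labels) stop("control group absent")
  others <- setdiff(sort(unique(group_labels)), control_label)
  if (!length(others)) stop("no study groups to compare")
  rows <- lapply(others, function(g) {
    sel_g <- group_labels == g & !is.na(outcome)
    sel_c <- group_labels == control_label & !is.na(outcome)
    label <- .pair_label(g, control_label)
    if (is.numeric(outcome)) {
      r <- mann_whitney(outcome[sel_g], outcome[sel_c])
    } else {
      f <- factor(outcome[sel_g | sel_c])
      gl <- factor(ifelse(group_labels[sel_g | sel_c] == g, g, control_label))
      r <- fisher_exact(table(gl, f))
    }
    r$contrast <- label
    r
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- holm_adjust(res$p_raw)
  res
}

#' Two-sample t power function (noncentral t)
#' @param delta True mean difference.
#' @param n1,n2 Group sizes.
#' @param sd Common standard deviation.
#' @param alpha Two-sided significance level.
#' @return Power of the two-sided two-sample t test.
#' @export
t_test_power <- function(delta, n1, n2, sd, alpha = 0.05) {
  df <- n1 + n2 - 2
  ncp <- delta / (sd * sqrt(1 / n1 + 1 / n2))
  tc <- stats::qt(1 - alpha / 2, df)
  1 - stats::pt(tc, df, ncp) + stats::pt(-tc, df, ncp)
}

#' Minimal detectable difference at given power (noncentral t)
#'
#' Finds the smallest true difference for which the two-sided two-sample
#' t test at level `alpha` attains the requested power, by root finding on
#' the noncentral-t power function with `ncp = delta / (sd *
#' sqrt(1/n1 + 1/n2))` and `df = n1 + n2 - 2`.
#'
#' @param n1,n2 Group sizes (>= 2).
#' @param sd Common standard deviation (> 0), in the parameter's units.
#' @param alpha Two-sided type-I error, default 0.05.
#' @param power Target power, default 0.80.
#' @return The detectable difference, same units as `sd`.
#' @export
detectable_difference <- function(n1, n2, sd, alpha = 0.05, power = 0.80) {
  stopifnot(n1 >= 2, n2 >= 2, sd > 0, alpha > 0, alpha < 1,
            power > 0, power < 1)
  f <- function(d) t_test_power(d, n1, n2, sd, alpha) - power
  upper <- sd
  while (f(upper) < 0) upper <- upper * 2
  stats::uniroot(f, c(0, upper), tol = 1e-10)$root
}

#' Descriptive summary: median (Q1; Q3) or count (percent)
#'
#' Numeric input yields the median and quartiles (linear-interpolation
#' quantiles, R type 7) of the non-missing values; categorical input
#' yields counts and percentages of non-missing observations.
#'
#' @param x Numeric, logical, factor or character vector.
#' @return For numeric `x`: one-row data.frame `n`, `median`, `q1`, `q3`.
#'   For categorical `x`: data.frame `level`, `n`, `percent` (one decimal
#'   place resolution retained; `percent` is not rounded).
#' @export
summarize_values <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) stop("empty input")
  if (is.numeric(x)) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    return(data.frame(n = length(x), median = q[2], q1 = q[1], q3 = q[3]))
  }
  tab <- table(x)
  data.frame(level = names(tab), n = as.integer(tab),
             percent = 100 * as.integer(tab) / length(x),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Format a count as "n (percent)" with one decimal, as in clinical tables
#'
#' Uses round-half-up (the clinical-table convention: 6.25% prints as
#' 6.3), not R's default round-half-to-even.
#' @param k Count. @param n Denominator.
#' @return String like `"72 (40.0)"`.
#' @export
count_percent <- function(k, n) {
  sprintf("%d (%.1f)", k, floor(1000 * k / n + 0.5) / 10)
}
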