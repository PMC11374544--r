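# Two-group statistical protocol: a Kolmogorov-Smirnov normality screen on
# each group (with the Lilliefors correction, since mean and SD are estimated
# from the sample), then Student's t-test if both groups look normal, else
# the Mann-Whitney U test; descriptives follow the distribution (mean+-SD for
# normal, median with (Q1, Q3) otherwise). Two-sided throughout, alpha 0.05.

#' Kolmogorov-Smirnov normality screen (Lilliefors correction)
#'
#' One-sample KS statistic of the sample against a normal distribution with
#' mean and SD estimated from the same sample. Because parameters are
#' estimated, the plain KS null distribution is anticonservative; the p-value
#' uses the Dallal-Wilkinson (1986) approximation with Stephens' (1974)
#' modified statistic for large p, the standard Lilliefors-test practice.
#'
#' @param x Numeric sample, n >= 3, not all equal.
#' @param alpha Significance level for the verdict (default 0.05).
#' @return List: `statistic` (D), `p_value`, `normal` (TRUE iff
#'   p >= alpha), `n`.
#' @export
ks_normality <- function(x, alpha = 0.05) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3) pw_stop("pw_validation_error", "normality screen needs n >= 3")
  if (stats::sd(x) == 0) {
    pw_stop("pw_degenerate_sample", "constant sample: normality undefined")
  }
  z <- sort((x - mean(x)) / stats::sd(x))
  p <- stats::pnorm(z)
  i <- seq_len(n)
  D <- max(pmax(i / n - p, p - (i - 1) / n))
  # Dallal & Wilkinson (1986) analytic approximation
  nd <- if (n > 100) 100 else n
  Dd <- if (n > 100) D * (n / 100)^0.49 else D
  pvalue <- exp(-7.01256 * Dd^2 * (nd + 2.78019) +
                  2.99587 * Dd * sqrt(nd + 2.78019) - 0.122119 +
                  0.974598 / sqrt(nd) + 1.67997 / nd)
  if (pvalue > 0.1) {
    # Stephens (1974) modified statistic, valid in the high-p region
    KK <- (sqrt(n) - 0.01 + 0.85 / sqrt(n)) * D
    pvalue <-
      if (KK <= 0.302) 1
      else if (KK <= 0.5) 2.76773 - 19.828315 * KK + 80.709644 * KK^2 -
        138.55152 * KK^3 + 81.541484 * KK^4
      else if (KK <= 0.9) -4.901232 + 40.662806 * KK - 97.490286 * KK^2 +
        94.029866 * KK^3 - 32.355711 * KK^4
      else if (KK <= 1.31) 6.198765 - 19.558097 * KK + 23.186922 * KK^2 -
        12.234627 * KK^3 + 2.423045 * KK^4
      else 0
  }
  pvalue <- min(max(pvalue, 0), 1)
  list(statistic = D, p_value = pvalue, normal = pvalue >= alpha, n = n)
}

mwu_statistic <- function(x, y) {
  # U for group x: number of (x_i, y_j) pairs with x_i > y_j, ties count 1/2
  r <- rank(c(x, y))
  n1 <- length(x)
  sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact null by complete enumeration of rank assignments when
#' `n1 + n2 <= 16` and the pooled sample is tie-free; otherwise the normal
#' approximation with tie correction (no continuity correction, matching
#' common statistical-package defaults). The exact two-sided p-value is
#' `P(|U - n1*n2/2| >= |u_obs - n1*n2/2|)` under the permutation null.
#'
#' @param x,y Non-empty numeric samples.
#' @return List: `U` (for the first sample), `p_value`, `method`
#'   ("exact" or "normal_approx"), `n1`, `n2`.
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) {
    pw_stop("pw_validation_error", "both samples must be non-empty")
  }
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  u <- mwu_statistic(x, y)
  ties <- anyDuplicated(pooled) > 0
  if (N <= 16 && !ties) {
    r <- rank(pooled)
    combos <- utils::combn(N, n1)
    us <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    centre <- n1 * n2 / 2
    p <- mean(abs(us - centre) >= abs(u - centre) - 1e-9)
    return(list(U = u, p_value = p, method = "exact", n1 = n1, n2 = n2))
  }
  mu <- n1 * n2 / 2
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) {
    # all observations tied: no evidence either way
    return(list(U = u, p_value = 1, method = "normal_approx",
                n1 = n1, n2 = n2))
  }
  z <- (u - mu) / sqrt(sigma2)
  list(U = u, p_value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal_approx", n1 = n1, n2 = n2)
}

#' Two-sample Student's t-test (two-sided)
#'
#' Pooled-variance by default (the classical Student test); Welch's unequal
#' variance form available via `welch = TRUE`.
#'
#' @param x,y Samples with at least two observations each.
#' @param welch Use the Welch-Satterthwaite form instead of pooled variance.
#' @return List: `t`, `df`, `p_value`.
#' @export
student_t <- function(x, y, welch = FALSE) {
  if (length(x) < 2 || length(y) < 2) {
    pw_stop("pw_validation_error", "t-test needs n >= 2 per group")
  }
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    if (se2 <= 0) pw_stop("pw_degenerate_sample", "zero variance in both groups")
    tt <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    if (sp2 <= 0) pw_stop("pw_degenerate_sample", "zero pooled variance")
    tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  list(t = tt, df = df, p_value = 2 * stats::pt(-abs(tt), df))
}

describe_sample <- function(x, normal) {
  if (normal) {
    sprintf("%.2f +- %.2f", mean(x), stats::sd(x))
  } else {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    sprintf("%.2f (%.2f, %.2f)", q[2], q[1], q[3])
  }
}

#' Normality-gated comparison of two per-day series
#'
#' Applies the full protocol for one variable: Lilliefors-corrected KS screen
#' on each group, Student's t-test if both pass (p >= alpha), Mann-Whitney U
#' otherwise, plus descriptives formatted to match the chosen test (mean+-SD
#' for the parametric branch, median (Q1, Q3) for the non-parametric one).
#' Variables in `exclude` (by default the sparsely-observed dessert and
#' "other" categories) yield an explicit skip result rather than a silent
#' omission.
#'
#' @param x,y Per-day-unit series for the two cases.
#' @param variable Variable name carried into the result.
#' @param alpha Significance level (default 0.05).
#' @param exclude Variable names to skip.
#' @param welch Use Welch's t in the parametric branch.
#' @return List of class `pw_comparison`: variable, n1, n2, normality
#'   verdicts, `test_used` ("student_t", "mann_whitney_u" or "skipped"),
#'   `statistic`, `p_value`, `significant`, formatted `descriptives`, and
#'   `skip_reason` when skipped.
#' @export
compare_cases <- function(x, y, variable = "value", alpha = 0.05,
                          exclude = c("other", "dessert"), welch = FALSE) {
  if (variable %in% exclude) {
    return(structure(list(variable = variable, n1 = length(x), n2 = length(y),
                          test_used = "skipped",
                          skip_reason = "excluded category: too few observations",
                          statistic = NA_real_, p_value = NA_real_,
                          significant = NA), class = "pw_comparison"))
  }
  if (!length(x) || !length(y)) {
    pw_stop("pw_validation_error", "both series must be non-empty")
  }
  norm1 <- tryCatch(ks_normality(x, alpha), pw_degenerate_sample = function(e) {
    list(normal = FALSE, p_value = NA_real_, statistic = NA_real_)
  })
  norm2 <- tryCatch(ks_normality(y, alpha), pw_degenerate_sample = function(e) {
    list(normal = FALSE, p_value = NA_real_, statistic = NA_real_)
  })
  both_normal <- isTRUE(norm1$normal) && isTRUE(norm2$normal)
  if (both_normal) {
    res <- student_t(x, y, welch = welch)
    test_used <- "student_t"; statistic <- res$t
  } else {
    res <- mann_whitney_u(x, y)
    test_used <- "mann_whitney_u"; statistic <- res$U
  }
  structure(list(
    variable = variable, n1 = length(x), n2 = length(y),
    normal = c(group1 = isTRUE(norm1$normal), group2 = isTRUE(norm2$normal)),
    normality_p = c(group1 = norm1$p_value, group2 = norm2$p_value),
    test_used = test_used, statistic = statistic, p_value = res$p_value,
    significant = res$p_value < alpha,
    descriptives = c(group1 = describe_sample(x, both_normal),
                     group2 = describe_sample(y, both_normal))),
    class = "pw_comparison")
}

#' @export
print.pw_comparison <- function(x, ...) {
  cat(sprintf("<comparison> %s (n %d vs %d)\n", x$variable, x$n1, x$n2))
  if (x$test_used == "skipped") {
    cat("  skipped:", x$skip_reason, "\n")
  } else {
    cat(sprintf("  %s: statistic %.4g, p = %.4g%s\n", x$test_used,
                x$statistic, x$p_value, if (isTRUE(x$significant)) " *" else ""))
    cat(sprintf("  group1 %s | group2 %s\n",
                x$descriptives[1], x$descriptives[2]))
  }
  invisible(x)
}
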