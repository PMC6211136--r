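#' Univariate logistic confirmation of a binary risk indicator
#'
#' Fits `y ~ indicator` by logistic regression and reports the odds ratio
#' with a 95% confidence interval and p-value.  For a binary indicator the
#' fitted odds ratio equals the 2x2 cross-product ratio; the default CI and
#' p-value are Wald, with a profile-likelihood CI available.  A zero cell
#' in the implied 2x2 table (quasi-separation) is an error directing the
#' user to an exact method.
#'
#' @param y binary outcome.
#' @param indicator binary exposure/implicant indicator.
#' @param ci `"wald"` (default) or `"profile"` (requires MASS).
#' @return list of class `lf_confirm`: `odds_ratio`, `ci_low`, `ci_high`,
#'   `p_value`, `prev_cases`, `prev_controls`, `method`.
#' @export
fit_logistic_univariate <- function(y, indicator, ci = c("wald", "profile")) {
  ci <- match.arg(ci)
  y <- as.integer(y)
  indicator <- as.integer(indicator)
  .check_binary(y, "outcome y")
  .check_binary(indicator, "indicator")
  if (length(unique(indicator)) < 2) stop("indicator is constant")
  if (length(unique(y)) < 2) stop("both outcome classes must be present")
  cells <- table(factor(indicator, 0:1), factor(y, 0:1))
  if (any(cells == 0))
    stop("zero cell in the 2x2 table; use an exact or penalised method")
  fit <- glm(y ~ indicator, family = binomial())
  beta <- coef(fit)[["indicator"]]
  se <- sqrt(diag(stats::vcov(fit)))[["indicator"]]
  if (ci == "wald") {
    lo <- beta - qnorm(0.975) * se
    hi <- beta + qnorm(0.975) * se
  } else {
    if (!requireNamespace("MASS", quietly = TRUE))
      stop("profile CI requires the MASS package")
    cint <- suppressMessages(stats::confint(fit, "indicator", level = 0.95))
    lo <- cint[[1]]; hi <- cint[[2]]
  }
  structure(list(
    odds_ratio = exp(beta), ci_low = exp(lo), ci_high = exp(hi),
    p_value = 2 * pnorm(-abs(beta / se)),
    prev_cases = mean(indicator[y == 1]),
    prev_controls = mean(indicator[y == 0]),
    method = paste0("logistic/", ci)), class = "lf_confirm")
}

#' @export
print.lf_confirm <- function(x, ...) {
  cat(sprintf("OR %.3f (95%% CI %.3f, %.3f), p = %.4g [%s]\n",
              x$odds_ratio, x$ci_low, x$ci_high, x$p_value, x$method))
  cat(sprintf("  indicator prevalence: cases %.3f, controls %.3f\n",
              x$prev_cases, x$prev_controls))
  invisible(x)
}

#' Confirmation table for a set of prime implicants
#'
#' Builds the per-implicant indicator over the dataset and fits the
#' univariate logistic model for each, producing a summary-table-style
#' data.frame (effect rendering, prevalences, OR, CI, p).  Implicants whose
#' indicator is constant or yields a zero cell are reported with `NA`
#' estimates and a note rather than an error.
#'
#' @param data an [lf_data()].
#' @param terms list of prime implicants (signed integer vectors or keys).
#' @param ci CI flavor, see [fit_logistic_univariate()].
#' @return data.frame of class `lf_confirm_table`.
#' @export
confirm_pis <- function(data, terms, ci = "wald") {
  stopifnot(inherits(data, "lf_data"))
  rows <- lapply(terms, function(t) {
    key <- if (is.character(t)) t else pi_key(t)
    ind <- pi_indicator(data, key)
    rec <- tryCatch(fit_logistic_univariate(data$y, ind, ci = ci),
                    error = function(e) e)
    if (inherits(rec, "error"))
      data.frame(pi = key, label = pi_render(key, data$descriptors),
                 prev_cases = mean(ind[data$y == 1]),
                 prev_controls = mean(ind[data$y == 0]),
                 odds_ratio = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, p_value = NA_real_,
                 note = conditionMessage(rec), stringsAsFactors = FALSE)
    else
      data.frame(pi = key, label = pi_render(key, data$descriptors),
                 prev_cases = rec$prev_cases,
                 prev_controls = rec$prev_controls,
                 odds_ratio = rec$odds_ratio, ci_low = rec$ci_low,
                 ci_high = rec$ci_high, p_value = rec$p_value,
                 note = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("lf_confirm_table", "data.frame")
  out
}

#' 2x2 chi-square test with continuity correction
#'
#' Pearson chi-square on a 2x2 table, Yates-corrected by default (the
#' |ad - bc| reduction by n/2, floored at zero), 1 df.  Without correction
#' the statistic is exactly n(ad - bc)^2 / (product of margins).
#'
#' @param tab 2x2 matrix of non-negative counts with positive margins.
#' @param correct apply the Yates continuity correction (default TRUE).
#' @return list with `statistic`, `p_value`, `correct`.
#' @export
chi_square_2x2 <- function(tab, correct = TRUE) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in 2x2 table")
  ht <- suppressWarnings(chisq.test(tab, correct = correct))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       correct = correct)
}

#' Two-sample t-test from summary statistics
#'
#' Pooled-variance two-sample t-test (default) or Welch's test computed
#' from group means, standard deviations and sizes, two-sided.
#'
#' @param mean1,sd1,n1 first group summaries.
#' @param mean2,sd2,n2 second group summaries.
#' @param pooled pooled variance (default) or Welch.
#' @return list with `statistic`, `df`, `p_value`, `method`.
#' @export
t_test_from_summaries <- function(mean1, sd1, n1, mean2, sd2, n2,
                                  pooled = TRUE) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 > 0, sd2 > 0)
  if (pooled) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  stat <- (mean1 - mean2) / se
  list(statistic = stat, df = df, p_value = 2 * pt(-abs(stat), df),
       method = if (pooled) "pooled" else "welch")
}
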