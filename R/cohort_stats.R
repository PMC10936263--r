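#' Lilliefors-corrected Kolmogorov-Smirnov normality check
#'
#' One-sample KS test against a normal distribution with mean and SD
#' estimated from the data, using Lilliefors small-sample corrected
#' p-values (via [nortest::lillie.test()]); the naive KS test with
#' estimated parameters is anticonservative.
#'
#' @param values numeric vector, n >= 5.
#' @param alpha decision level (default 0.05).
#' @return list with `statistic`, `p_value`, `is_normal`
#'   (`p_value >= alpha`).
#' @export
ks_normality <- function(values, alpha = 0.05) {
  stopifnot(is.numeric(values), alpha > 0, alpha < 1)
  values <- values[!is.na(values)]
  if (length(values) < 5L) {
    stop("normality check requires at least 5 values", call. = FALSE)
  }
  if (stats::sd(values) == 0) {
    warning("zero variance: normality undefined, treated as non-normal",
            call. = FALSE)
    return(list(statistic = NA_real_, p_value = NA_real_,
                is_normal = FALSE))
  }
  kt <- nortest::lillie.test(values)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       is_normal = kt$p.value >= alpha)
}

#' Paired-samples t-test
#'
#' Two-sided t-test on the paired differences `with_ - without`.
#'
#' @param without,with_ paired numeric vectors of equal length (n >= 2).
#' @return list with `statistic` (t), `df`, `p_value`.
#' @export
paired_t <- function(without, with_) {
  d <- pair_diffs(without, with_)
  if (stats::sd(d) == 0) {
    stop("zero-variance differences: paired t-test undefined",
         call. = FALSE)
  }
  n <- length(d)
  t_stat <- mean(d) / (stats::sd(d) / sqrt(n))
  list(statistic = t_stat, df = n - 1L,
       p_value = 2 * stats::pt(-abs(t_stat), df = n - 1L))
}

pair_diffs <- function(without, with_, min_n = 2L) {
  stopifnot(is.numeric(without), is.numeric(with_))
  if (length(without) != length(with_)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  keep <- !(is.na(without) | is.na(with_))
  d <- with_[keep] - without[keep]
  if (length(d) < min_n) {
    stop("need at least ", min_n, " complete pairs", call. = FALSE)
  }
  d
}

#' Wilcoxon signed-rank test with exact small-sample p-values
#'
#' Zero differences are dropped (signed-rank convention) and ties share
#' midranks. For n <= 15 nonzero differences the two-sided p-value is exact,
#' from the full distribution of the positive-rank sum over all 2^n sign
#' assignments of the observed ranks; for larger n a normal approximation
#' with tie correction and continuity correction is used.
#'
#' @param without,with_ paired numeric vectors; differences are
#'   `with_ - without`.
#' @return list with `statistic` (W, positive-rank sum), `p_value`,
#'   `n` (nonzero pairs), `method` (`"exact"` or `"normal_approx"`).
#' @export
wilcoxon_signed_rank <- function(without, with_) {
  d <- pair_diffs(without, with_, min_n = 1L)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    stop("all differences are zero: signed-rank test undefined",
         call. = FALSE)
  }
  if (n < 5L) {
    stop("need at least 5 nonzero differences", call. = FALSE)
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- sum(r) / 2
  if (n <= 15L) {
    p <- signed_rank_exact_p(r, w)
    method <- "exact"
  } else {
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- w - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal_approx"
  }
  list(statistic = w, p_value = min(1, p), n = n, method = method)
}

# Exact two-sided p for the positive-rank sum by dynamic programming over
# the 2^n equally likely sign assignments. Ranks are doubled to integers so
# midranks (ties) enumerate exactly.
signed_rank_exact_p <- function(ranks, w_obs) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  counts <- numeric(total + 1L)  # counts[s + 1] = #assignments with 2W = s
  counts[1L] <- 1
  for (v in r2) {
    shifted <- c(numeric(v), counts[seq_len(total + 1L - v)])
    counts <- counts + shifted
  }
  s <- 0:total
  mu2 <- total / 2
  extreme <- abs(s - mu2) >= abs(2 * w_obs - mu2) - 1e-9
  sum(counts[extreme]) / 2^length(r2)
}

#' Cohen's d for paired data
#'
#' Default is the paired-design effect size d_z: the absolute mean of the
#' differences divided by their sample standard deviation. The signed mean
#' difference carries the direction; d reports magnitude. Labels follow the
#' conventional 0.20 / 0.50 / 0.80 cut-points.
#'
#' @param without,with_ paired numeric vectors.
#' @param pooled if `TRUE`, divide by the pooled SD of the two conditions
#'   instead of the SD of the differences.
#' @return list with `d`, `label`.
#' @export
cohens_d_paired <- function(without, with_, pooled = FALSE) {
  d <- pair_diffs(without, with_)
  denom <- if (pooled) {
    keep <- !(is.na(without) | is.na(with_))
    sqrt((stats::var(without[keep]) + stats::var(with_[keep])) / 2)
  } else {
    stats::sd(d)
  }
  if (denom == 0) {
    stop("zero variance: effect size undefined", call. = FALSE)
  }
  dval <- abs(mean(d)) / denom
  list(d = dval, label = effect_label(dval))
}

effect_label <- function(d) {
  if (d >= 0.8) "large" else if (d >= 0.5) "medium"
  else if (d >= 0.2) "small" else "negligible"
}

#' t-based confidence interval on a mean
#'
#' @param values numeric vector, n >= 2.
#' @param level confidence level in \[0, 1) (default 0.95); level 0 gives a
#'   degenerate interval at the mean.
#' @return numeric vector `c(low, high)`.
#' @export
mean_ci <- function(values, level = 0.95) {
  values <- values[!is.na(values)]
  n <- length(values)
  stopifnot(n >= 2L, level >= 0, level < 1)
  m <- mean(values)
  if (level == 0 || stats::sd(values) == 0) return(c(low = m, high = m))
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1L) *
    stats::sd(values) / sqrt(n)
  c(low = m - half, high = m + half)
}

#' Paired with/without-exoskeleton comparison of one dependent variable
#'
#' Assesses normality of the paired differences with the Lilliefors KS
#' check, then dispatches a paired t-test (normal) or Wilcoxon signed-rank
#' test (non-normal), and assembles the mean difference, Cohen's d and its
#' 95% confidence interval.
#'
#' @param without,with_ per-process values, paired by position (n >= 5).
#' @param alpha significance/normality level (default 0.05).
#' @param variable name carried on the result.
#' @param ci_level confidence level for the mean-difference interval.
#' @return object of class `comparison_result`.
#' @export
compare_variable <- function(without, with_, alpha = 0.05,
                             variable = "variable", ci_level = 0.95) {
  d <- pair_diffs(without, with_, min_n = 5L)
  norm <- ks_normality(d, alpha = alpha)
  if (isTRUE(norm$is_normal)) {
    test <- paired_t(without, with_)
    test_used <- "paired_t"
    statistic <- test$statistic
  } else {
    test <- wilcoxon_signed_rank(without, with_)
    test_used <- "wilcoxon"
    statistic <- test$statistic
  }
  es <- cohens_d_paired(without, with_)
  structure(
    list(
      variable = variable,
      n = length(d),
      delta = mean(d),
      test_used = test_used,
      statistic = statistic,
      p_value = test$p_value,
      significant = test$p_value < alpha,
      cohens_d = es$d,
      d_label = es$label,
      ci95 = mean_ci(d, level = ci_level),
      normality = norm
    ),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "<comparison_result> %s (n=%d): delta=%+.2f [%.2f, %.2f], %s p=%.4g%s, d=%.2f (%s)\n",
    x$variable, x$n, x$delta, x$ci95[["low"]], x$ci95[["high"]],
    x$test_used, x$p_value, if (x$significant) " *" else "",
    x$cohens_d, x$d_label))
  invisible(x)
}

#' @export
as.data.frame.comparison_result <- function(x, ...) {
  data.frame(
    variable = x$variable, n = x$n, delta = x$delta, test = x$test_used,
    statistic = x$statistic, p = x$p_value, significant = x$significant,
    d = x$cohens_d, d_label = x$d_label,
    ci_low = x$ci95[["low"]], ci_high = x$ci95[["high"]],
    normal = isTRUE(x$normality$is_normal),
    stringsAsFactors = FALSE
  )
}

#' Aggregate visual analog scale (VAS) survey responses
#'
#' Usability responses on a -1 (difficult/uncomfortable/no) to 0 (neutral)
#' to +1 (easy/comfortable/yes) visual analog scale are summarized per
#' question as the mean response and the number of respondents.
#'
#' @param responses data.frame: one row per respondent, one numeric column
#'   per question (an id column named `respondent` is ignored). All values
#'   must lie in \[-1, 1\]; `NA` allowed.
#' @return data.frame with columns `question`, `mean`, `n`; questions with
#'   no responses are omitted with a warning.
#' @export
aggregate_survey <- function(responses) {
  stopifnot(is.data.frame(responses))
  qs <- setdiff(names(responses), "respondent")
  if (!length(qs)) stop("no question columns", call. = FALSE)
  out <- lapply(qs, function(q) {
    v <- responses[[q]]
    if (!is.numeric(v)) {
      stop("question '", q, "' is not numeric", call. = FALSE)
    }
    if (any(!is.na(v) & (v < -1 | v > 1))) {
      stop("question '", q, "' has responses outside [-1, 1]",
           call. = FALSE)
    }
    v <- v[!is.na(v)]
    if (!length(v)) {
      warning("question '", q, "' has no responses; omitted",
              call. = FALSE)
      return(NULL)
    }
    data.frame(question = q, mean = mean(v), n = length(v),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
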