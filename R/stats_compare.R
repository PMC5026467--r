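#' Test for equality of two proportions
#'
#' Pooled chi-square test of two binomial proportions without continuity
#' correction: `chi2 = (p1 - p2)^2 / (pbar (1 - pbar) (1/n1 + 1/n2))`,
#' with `pbar` the pooled proportion and p from the chi-square distribution
#' with 1 df. Backed by [stats::prop.test()] with `correct = FALSE`.
#'
#' @param k1,n1 Successes and total of group 1.
#' @param k2,n2 Successes and total of group 2.
#' @return List with `chi2`, `df` (1), `p_value`, `p1`, `p2`.
#' @export
prop_chi2 <- function(k1, n1, k2, n2) {
  stopifnot(k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2, n1 >= 1, n2 >= 1)
  pooled <- (k1 + k2) / (n1 + n2)
  if (pooled <= 0 || pooled >= 1)
    stop("pooled proportion is 0 or 1; statistic undefined")
  ht <- suppressWarnings(
    stats::prop.test(c(k1, k2), c(n1, n2), correct = FALSE))
  list(chi2 = unname(ht$statistic), df = 1L, p_value = ht$p.value,
       p1 = k1 / n1, p2 = k2 / n2)
}

#' Pearson chi-square test on a contingency table
#'
#' `sum((O - E)^2 / E)` with expected counts from the margins, no
#' continuity correction; df = (r - 1)(c - 1). Backed by
#' [stats::chisq.test()].
#'
#' @param table Matrix of counts.
#' @return List with `chi2`, `df`, `p_value`, `expected`.
#' @export
pearson_chi2 <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin in contingency table")
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, expected = ht$expected)
}

#' Marascuillo procedure for multiple proportions
#'
#' Simultaneous pairwise comparison of m proportions: pair (i, j) differs
#' significantly when `|p_i - p_j|` exceeds the critical range
#' `sqrt(chi2[1 - alpha, m - 1]) * sqrt(p_i (1 - p_i) / n_i +
#' p_j (1 - p_j) / n_j)`.
#'
#' @param k Vector of successes (length m >= 3).
#' @param n Vector of totals (recycled to length m).
#' @param alpha Family-wise significance level (default 0.05).
#' @param labels Optional group labels.
#' @return Data frame with one row per pair: `group1`, `group2`, `diff`,
#'   `critical`, `significant`.
#' @export
marascuillo <- function(k, n, alpha = 0.05, labels = NULL) {
  m <- length(k)
  if (m < 3) stop("Marascuillo procedure needs at least 3 proportions")
  n <- rep_len(n, m)
  stopifnot(all(k >= 0), all(k <= n))
  if (is.null(labels)) labels <- as.character(seq_len(m))
  p <- k / n
  crit_base <- sqrt(stats::qchisq(1 - alpha, df = m - 1))
  rows <- list()
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      r_ij <- crit_base * sqrt(p[i] * (1 - p[i]) / n[i] +
                                 p[j] * (1 - p[j]) / n[j])
      rows[[length(rows) + 1L]] <- data.frame(
        group1 = labels[i], group2 = labels[j],
        diff = abs(p[i] - p[j]), critical = r_ij,
        significant = abs(p[i] - p[j]) > r_ij)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-sample Student t-test
#'
#' Pooled-variance t-test with df = n1 + n2 - 2 (or a paired t-test),
#' matching the df convention of the reported comparisons. Backed by
#' [stats::t.test()].
#'
#' @param x,y Numeric samples (>= 2 values each).
#' @param paired Paired test (default FALSE).
#' @return List with `t`, `df`, `p_value`.
#' @export
two_sample_t <- function(x, y, paired = FALSE) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (!paired && stats::var(c(x - mean(x), y - mean(y))) == 0)
    stop("zero pooled variance")
  ht <- stats::t.test(x, y, paired = paired, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Recompute the published equality-of-proportions statistics
#'
#' Re-derives, from the responder counts reported for the untrained
#' (n = 135) and trained (n = 118) populations, the eight equality-of-
#' proportions chi-square statistics comparing the two conditions: the four
#' per-cue responder prevalences, taste-selective prevalence, taste-only
#' and taste-and-cue fractions among taste-selective neurons, and the
#' inhibited fraction among first-modulation cue responses.
#'
#' @return Data frame with `comparison`, `k1`, `n1`, `k2`, `n2`,
#'   `chi2` (computed), `printed` (reported value), `abs_diff`, `p_value`.
#' @export
reproduce_printed_stats <- function() {
  counts <- data.frame(
    comparison = c("odor", "air_puff", "tone", "light",
                   "taste_selective", "taste_only", "taste_and_cue",
                   "inhibited"),
    k1 = c(22, 21, 6, 5, 87, 61, 29, 16),
    n1 = c(135, 135, 135, 135, 135, 87, 87, 54),
    k2 = c(39, 41, 19, 14, 68, 27, 41, 54),
    n2 = c(118, 118, 118, 118, 118, 68, 68, 113),
    printed = c(9.65, 12.53, 9.60, 6.03, 1.23, 14.38, 11.20, 4.94)
  )
  res <- mapply(function(k1, n1, k2, n2) {
    r <- prop_chi2(k1, n1, k2, n2)
    c(r$chi2, r$p_value)
  }, counts$k1, counts$n1, counts$k2, counts$n2)
  counts$chi2 <- res[1, ]
  counts$p_value <- res[2, ]
  counts$abs_diff <- abs(counts$chi2 - counts$printed)
  counts[, c("comparison", "k1", "n1", "k2", "n2", "chi2", "printed",
             "abs_diff", "p_value")]
}
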