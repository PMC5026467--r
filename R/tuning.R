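#' Taste selectivity by two-way ANOVA
#'
#' A neuron responsive to at least one taste is taste selective when its
#' response differs across the four tastants in magnitude or time course:
#' a two-factor fixed-effects ANOVA (taste identity x time bin) is run on
#' per-trial per-bin firing rates over the post-delivery bins, and the
#' neuron is selective if either the taste main effect or the taste x time
#' interaction is significant.
#'
#' @param psths List of [bin_spikes()] objects, one per taste (>= 2 tastes,
#'   >= 2 trials each).
#' @param alpha Significance level (default 0.05).
#' @param windows An [analysis_windows()] object; post-delivery bins are
#'   the complete 200 ms bins in (0, 2.5\] s, i.e. 0-2.4 s.
#' @return List with `selective` (logical), `p_taste`, `p_interaction`.
#' @export
taste_selective <- function(psths, alpha = 0.05,
                            windows = analysis_windows()) {
  stopifnot(length(psths) >= 2)
  long <- list()
  for (p in psths) {
    stopifnot(inherits(p, "psth"))
    if (nrow(p$rate_hz) < 2) stop("need >= 2 trials per taste")
    mid <- p$bin_edges_s[-length(p$bin_edges_s)] + windows$bin_width_s / 2
    post <- which(mid > 0)
    r <- p$rate_hz[, post, drop = FALSE]
    long[[length(long) + 1L]] <- data.frame(
      rate = as.vector(r),
      taste = p$stimulus,
      bin = rep(post, each = nrow(r)))
  }
  d <- do.call(rbind, long)
  d$taste <- factor(d$taste)
  d$bin <- factor(d$bin)
  if (stats::var(d$rate) == 0)
    stop("zero variance everywhere; taste selectivity indeterminate")
  fit <- stats::lm(rate ~ taste * bin, data = d)
  a <- car::Anova(fit, type = 2)
  p_taste <- a[["Pr(>F)"]][rownames(a) == "taste"]
  p_int <- a[["Pr(>F)"]][rownames(a) == "taste:bin"]
  list(selective = isTRUE(p_taste < alpha) || isTRUE(p_int < alpha),
       p_taste = p_taste, p_interaction = p_int)
}

#' Sharpness (breadth-of-tuning) index
#'
#' `(n - sum(FR_i / FR_best)) / (n - 1)` over the mean post-stimulus firing
#' rates of the `n = 8` stimuli (four tastes, four cross-modal), where
#' `FR_best` is the largest rate. 1 means the neuron responds to a single
#' stimulus; 0 means equal responses to all stimuli.
#'
#' @param rates_hz Numeric vector of non-negative mean firing rates, one
#'   per stimulus.
#' @return Sharpness index in \[0, 1\].
#' @export
sharpness <- function(rates_hz) {
  stopifnot(is.numeric(rates_hz), all(rates_hz >= 0))
  n <- length(rates_hz)
  if (n < 2) stop("need at least two stimuli")
  fr_best <- max(rates_hz)
  if (fr_best == 0) stop("all rates are zero; sharpness undefined")
  (n - sum(rates_hz / fr_best)) / (n - 1)
}

#' Convergence counts from a responsiveness matrix
#'
#' Cross-tabulates how many stimuli each neuron responds to. For the
#' cross-modal columns it counts neurons modulated by 0, 1, ..., 4 of the
#' cues; given a `taste_selective` flag it also splits taste-selective
#' neurons into "taste only" vs "taste & k cues".
#'
#' @param responsive Logical matrix, neurons x stimuli, with column names
#'   from [ALL_STIMULI].
#' @param taste_selective Optional logical vector (one per neuron).
#' @return List with `n_neurons`, `by_n_cues` (named integer vector,
#'   counts of neurons responding to 0..4 cues), `cue_responders`
#'   (responding to >= 1 cue) and, when `taste_selective` is given,
#'   `taste_by_n_cues` (taste-selective neurons by number of cues) and
#'   `n_taste_selective`.
#' @export
convergence_counts <- function(responsive, taste_selective = NULL) {
  stopifnot(is.matrix(responsive), is.logical(responsive))
  cues <- intersect(CROSSMODAL_STIMULI, colnames(responsive))
  n_cues <- rowSums(responsive[, cues, drop = FALSE])
  by_n <- vapply(0:4, function(k) sum(n_cues == k), integer(1))
  names(by_n) <- as.character(0:4)
  out <- list(n_neurons = nrow(responsive), by_n_cues = by_n,
              cue_responders = sum(n_cues >= 1))
  if (!is.null(taste_selective)) {
    stopifnot(length(taste_selective) == nrow(responsive))
    tk <- vapply(0:4, function(k) sum(taste_selective & n_cues == k),
                 integer(1))
    names(tk) <- as.character(0:4)
    out$taste_by_n_cues <- tk
    out$n_taste_selective <- sum(taste_selective)
  }
  out
}

#' Bootstrap test of response-convergence independence
#'
#' Tests whether an observed convergence count (e.g. the number of neurons
#' responding to two or more cues, or the number that are both taste
#' selective and cue responsive) differs from what independent responses
#' would produce. Each simulation draws independent Bernoulli responses per
#' neuron and per stimulus with the experimentally observed marginal
#' probabilities and evaluates the statistic on the simulated matrix. The
#' p-value is the two-sided tail fraction (doubled smaller tail) of
#' simulated statistics at least as extreme as the observed one, with
#' ties counted half and smoothing so the p-value is never 0 — the mid-p
#' convention that keeps null p-values uniform despite the statistic being
#' integer-valued; the interval is the central 95% of the simulated
#' distribution.
#'
#' @param n_neurons Number of neurons simulated per run.
#' @param probs Named numeric vector of per-stimulus marginal response
#'   probabilities (columns of the simulated matrix).
#' @param observed Observed value of the statistic.
#' @param statistic Function mapping a logical `n_neurons x length(probs)`
#'   matrix to a scalar, or one of `"multi_cue"` (neurons responding to
#'   >= `k` columns) and `"all_true"` (neurons with every column TRUE).
#' @param k Threshold for `"multi_cue"` (default 2).
#' @param n_sims Number of simulations (>= 100; default 10000).
#' @param seed Optional integer seed.
#' @return List with `p_value`, `ci` (2.5/97.5 percentiles of the simulated
#'   statistic), `observed`, and `sims` (the simulated values).
#' @export
independence_bootstrap <- function(n_neurons, probs, observed,
                                   statistic = "multi_cue", k = 2,
                                   n_sims = 10000L, seed = NULL) {
  if (n_sims < 100) stop("n_sims < 100 refused")
  stopifnot(all(probs >= 0 & probs <= 1))
  if (!is.null(seed)) set.seed(seed)
  stat_fun <- if (is.function(statistic)) {
    statistic
  } else {
    switch(match.arg(statistic, c("multi_cue", "all_true")),
      multi_cue = function(m) sum(rowSums(m) >= k),
      all_true = function(m) sum(rowSums(m) == ncol(m)))
  }
  s <- length(probs)
  sims <- vapply(seq_len(n_sims), function(i) {
    m <- matrix(stats::runif(n_neurons * s) <
                  rep(probs, each = n_neurons), n_neurons, s)
    stat_fun(m)
  }, numeric(1))
  ties <- sum(sims == observed)
  p_hi <- (sum(sims > observed) + 0.5 * ties + 0.5) / (n_sims + 1)
  p_lo <- (sum(sims < observed) + 0.5 * ties + 0.5) / (n_sims + 1)
  list(p_value = min(1, 2 * min(p_hi, p_lo)),
       ci = stats::quantile(sims, c(0.025, 0.975), names = FALSE),
       observed = observed, sims = sims)
}
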