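#' Build a pseudo-population tensor from spike sessions
#'
#' Collects units recorded in different sessions into a surrogate
#' simultaneous population. Only units with at least `min_trials` trials
#' for each of the four cross-modal stimuli are included; every included
#' unit's trials are shuffled independently (seeded) and truncated to the
#' common trial count K (the minimum over included units and stimuli), so
#' that pseudo-trial k pairs each unit's k-th shuffled trial.
#'
#' @param sessions A [spike_session()] or list of them.
#' @param min_trials Minimum trials per cross-modal stimulus (default 8).
#' @param seed Optional integer seed for the within-unit trial shuffles.
#' @param bin_edges_s Bin edges of the rate grid; default 200 ms bins over
#'   `[-1, 2.8)` s so that both the stimulus period and the post-offset
#'   delay are covered.
#' @param normalize Z-score each unit's rates across all bins, trials and
#'   stimuli (default FALSE: the classifier works on raw firing rates).
#' @return Object of class `pseudo_population`: list with `rates` (array
#'   `R neurons x C bins x K pseudo-trials x 4 stimuli`, Hz), `stimuli`
#'   (cue labels, 4), `bin_start_s` (C), `neuron_ids` (R) and `k` (K).
#' @export
build_pseudopopulation <- function(sessions, min_trials = 8L, seed = NULL,
                                   bin_edges_s = seq(-1, 2.8, by = 0.2),
                                   normalize = FALSE) {
  if (inherits(sessions, "spike_session")) sessions <- list(sessions)
  if (!is.null(seed)) set.seed(seed)
  bw <- diff(bin_edges_s)[1]
  n_bins <- length(bin_edges_s) - 1L
  cues <- CROSSMODAL_STIMULI

  units <- list() # per unit: list(counts per stimulus: trials x bins)
  for (s in sessions) {
    trial_ids <- lapply(cues, function(st) stimulus_trials(s, st))
    names(trial_ids) <- cues
    for (nr in s$neurons) {
      n_tr <- vapply(trial_ids, length, integer(1))
      if (any(n_tr < min_trials)) next
      sp <- s$spikes[s$spikes$neuron_id == nr, ]
      per_stim <- lapply(cues, function(st) {
        ids <- trial_ids[[st]]
        m <- matrix(0L, length(ids), n_bins)
        for (i in seq_along(ids)) {
          tt <- sp$time_s[sp$trial_id == ids[i]]
          tt <- tt[tt >= bin_edges_s[1] & tt < bin_edges_s[n_bins + 1L]]
          if (length(tt))
            m[i, ] <- tabulate(floor((tt - bin_edges_s[1]) / bw) + 1L,
                               nbins = n_bins)
        }
        m
      })
      names(per_stim) <- cues
      units[[paste(s$session_id, nr, sep = "/")]] <- per_stim
    }
  }
  if (!length(units)) stop("no units with >= ", min_trials,
                           " trials per cross-modal stimulus")
  k <- min(vapply(units, function(u)
    min(vapply(u, nrow, integer(1))), integer(1)))
  rates <- array(NA_real_,
                 dim = c(length(units), n_bins, k, length(cues)),
                 dimnames = list(names(units), NULL, NULL, cues))
  for (i in seq_along(units)) {
    for (j in seq_along(cues)) {
      m <- units[[i]][[j]]
      ord <- sample.int(nrow(m))[seq_len(k)]
      rates[i, , , j] <- t(m[ord, , drop = FALSE]) / bw
    }
    if (normalize) {
      mu <- mean(rates[i, , , ])
      sd_i <- stats::sd(rates[i, , , ])
      if (sd_i > 0) rates[i, , , ] <- (rates[i, , , ] - mu) / sd_i
    }
  }
  structure(
    list(rates = rates, stimuli = cues,
         bin_start_s = bin_edges_s[-length(bin_edges_s)],
         neuron_ids = names(units), k = k),
    class = "pseudo_population"
  )
}

#' @export
print.pseudo_population <- function(x, ...) {
  d <- dim(x$rates)
  cat("<pseudo_population> ", d[1], " neurons x ", d[2], " bins x ",
      d[3], " pseudo-trials x ", d[4], " stimuli\n", sep = "")
  invisible(x)
}

#' Nearest-template classification of one time bin
#'
#' Leave-one-pseudo-trial-out classification of the four cross-modal
#' stimuli from the population rate vector of a single 200 ms bin. For
#' each held-out pseudo-trial the per-stimulus templates are the mean rate
#' vectors over the remaining pseudo-trials, and the predicted label is
#' the template at the smallest Euclidean distance; distance ties are
#' broken uniformly at random using the current RNG state.
#'
#' Pseudo-trial j spans all four stimuli (it pairs each unit's j-th
#' shuffled trial), so holding it out removes index j from every class's
#' template. This keeps all templates at k - 1 trials and makes the
#' classifier exactly symmetric across classes: on label-free data the
#' expected accuracy is the 1/4 chance level, with no leave-one-out bias.
#'
#' @param pop A [build_pseudopopulation()] object (or a bare array
#'   `R x C x K x 4`).
#' @param bin Bin index (column of the tensor).
#' @param neuron_idx Optional subset of neuron indices (used by the
#'   bootstrap; indices may repeat).
#' @return List with `accuracy` (fraction of the 4K held-out trials
#'   correctly classified) and `confusion` (4 x 4 matrix of row-normalized
#'   proportions, rows = true stimulus).
#' @export
decode_bin <- function(pop, bin, neuron_idx = NULL) {
  rates <- if (is.array(pop)) pop else pop$rates
  k <- dim(rates)[3]
  if (k < 2) stop("need K >= 2 pseudo-trials")
  n_stim <- dim(rates)[4]
  x <- rates[, bin, , , drop = FALSE] # R x 1 x K x S
  x <- array(x, dim = dim(rates)[c(1, 3, 4)]) # R x K x S
  if (!is.null(neuron_idx)) x <- x[neuron_idx, , , drop = FALSE]
  r <- dim(x)[1]
  sums <- apply(x, c(1, 3), sum) # R x S totals over pseudo-trials
  conf <- matrix(0L, n_stim, n_stim)
  for (s in seq_len(n_stim)) {
    for (j in seq_len(k)) {
      held <- x[, j, s]
      d2 <- numeric(n_stim)
      for (s2 in seq_len(n_stim)) {
        tmpl <- (sums[, s2] - x[, j, s2]) / (k - 1)
        d2[s2] <- sum((held - tmpl)^2)
      }
      best <- which(d2 == min(d2))
      pred <- if (length(best) == 1L) best else best[sample.int(length(best), 1L)]
      conf[s, pred] <- conf[s, pred] + 1L
    }
  }
  list(accuracy = sum(diag(conf)) / (n_stim * k), confusion = conf / k)
}

#' Decoding time course over all bins
#'
#' @param pop A [build_pseudopopulation()] object.
#' @param seed Optional integer seed (tie-breaking).
#' @return Object of class `decoding_result`: list with `accuracy` (per
#'   bin), `confusion` (bins x 4 x 4 array), `bin_start_s`, and `stimuli`.
#' @export
decode_timecourse <- function(pop, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_bins <- dim(pop$rates)[2]
  acc <- numeric(n_bins)
  conf <- array(NA_real_, dim = c(n_bins, 4, 4),
                dimnames = list(NULL, pop$stimuli, pop$stimuli))
  for (b in seq_len(n_bins)) {
    d <- decode_bin(pop, b)
    acc[b] <- d$accuracy
    conf[b, , ] <- d$confusion
  }
  structure(list(accuracy = acc, confusion = conf,
                 bin_start_s = pop$bin_start_s, stimuli = pop$stimuli),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat("<decoding_result> ", length(x$accuracy), " bins; mean accuracy ",
      round(mean(x$accuracy), 3), ", peak ",
      round(max(x$accuracy), 3), " at ",
      x$bin_start_s[which.max(x$accuracy)], " s\n", sep = "")
  invisible(x)
}

#' Bootstrap confidence band for the decoding time course
#'
#' Each bootstrap run samples with replacement 80% of the neurons and
#' re-runs the per-bin classifier; the band is the 2.5/97.5 percentile of
#' the per-bin accuracies. Decoding in a bin is significant when the lower
#' bound exceeds the 1/4 chance level.
#'
#' @param pop A [build_pseudopopulation()] object.
#' @param n_boot Number of bootstrap runs (>= 20; default 100).
#' @param frac Fraction of neurons sampled per run (default 0.8).
#' @param seed Optional integer seed.
#' @param chance Chance level used for the significance flag (default 0.25).
#' @return Data frame with `bin_start_s`, `lo`, `hi`, `significant`.
#' @export
bootstrap_band <- function(pop, n_boot = 100L, frac = 0.8, seed = NULL,
                           chance = 0.25) {
  if (n_boot < 20) stop("n_boot < 20 refused")
  if (!is.null(seed)) set.seed(seed)
  r <- dim(pop$rates)[1]
  n_bins <- dim(pop$rates)[2]
  n_pick <- ceiling(frac * r)
  acc <- matrix(NA_real_, n_boot, n_bins)
  for (run in seq_len(n_boot)) {
    idx <- sample.int(r, n_pick, replace = TRUE)
    for (b in seq_len(n_bins))
      acc[run, b] <- decode_bin(pop, b, neuron_idx = idx)$accuracy
  }
  lo <- apply(acc, 2, stats::quantile, probs = 0.025, names = FALSE)
  hi <- apply(acc, 2, stats::quantile, probs = 0.975, names = FALSE)
  data.frame(bin_start_s = pop$bin_start_s, lo = lo, hi = hi,
             significant = lo > chance)
}

#' Correct-hit / false-hit analysis of the confusion time course
#'
#' Averages the per-bin confusion matrices over the bins of each analysis
#' window (a bin belongs to a window when its midpoint does). Per stimulus,
#' the correct hit is the diagonal proportion and the false hit is the
#' largest off-diagonal proportion of the stimulus' row. Correct and false
#' hits are compared across the four stimuli with a pooled-variance
#' two-sample t-test (df = 6).
#'
#' @param result A [decode_timecourse()] object.
#' @param windows Named list of `c(start, end)` windows, default the
#'   post-onset (`[0, 0.2)` s) and post-offset (`[2.5, 2.7)` s) windows.
#' @return Named list (one element per window) with `confusion` (averaged),
#'   `correct` and `false` (per-stimulus), and `t_test` (from
#'   [two_sample_t()]).
#' @export
hits_analysis <- function(result,
                          windows = list(onset = c(0, 0.2),
                                         offset = c(2.5, 2.7))) {
  stopifnot(inherits(result, "decoding_result"))
  mids <- result$bin_start_s + 0.1
  out <- list()
  for (w in names(windows)) {
    win <- windows[[w]]
    bins <- which(mids >= win[1] & mids < win[2])
    if (!length(bins)) stop("no bins inside window ", w)
    conf <- apply(result$confusion[bins, , , drop = FALSE], c(2, 3), mean)
    correct <- diag(conf)
    false_hit <- vapply(seq_len(nrow(conf)), function(i)
      max(conf[i, -i]), numeric(1))
    names(false_hit) <- rownames(conf)
    tt <- tryCatch(two_sample_t(correct, false_hit),
                   error = function(e)
                     list(t = NA_real_, df = 6, p_value = NA_real_))
    out[[w]] <- list(confusion = conf, correct = correct,
                     false = false_hit, t_test = tt)
  }
  out
}
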