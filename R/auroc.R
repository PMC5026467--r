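#' Area under the ROC curve for one bin vs baseline
#'
#' Normalizes a response bin against baseline firing by the probability
#' that an evoked per-trial spike count exceeds a baseline count, ties
#' counted half (the Mann-Whitney statistic divided by the number of
#' pairs). 0.5 means no change from baseline; values above (below) 0.5 mean
#' firing above (below) baseline.
#'
#' @param evoked Per-trial spike counts (or rates) in the response bin.
#' @param baseline Baseline per-trial-per-bin counts, pooled over baseline
#'   bins and trials.
#' @return auROC value in \[0, 1\].
#' @export
auroc_bin <- function(evoked, baseline) {
  if (!length(evoked) || !length(baseline)) stop("empty sample")
  ne <- length(evoked)
  nb <- length(baseline)
  r <- rank(c(evoked, baseline))
  (sum(r[seq_len(ne)]) - ne * (ne + 1) / 2) / (ne * nb)
}

#' auROC-normalized response trajectory
#'
#' Converts a peristimulus histogram into a per-bin auROC trajectory: each
#' post-stimulus bin's per-trial counts are compared against the pooled
#' baseline distribution (per-trial counts in the five 200 ms baseline
#' bins).
#'
#' @param psth A [bin_spikes()] object.
#' @param windows An [analysis_windows()] object.
#' @return Object of class `auroc_profile`: list with `neuron_id`,
#'   `stimulus`, `bin_start_s` (post bins) and `auroc` (same length,
#'   values in \[0, 1\]).
#' @export
auroc_profile <- function(psth, windows = analysis_windows()) {
  stopifnot(inherits(psth, "psth"))
  starts <- psth$bin_edges_s[-length(psth$bin_edges_s)]
  base_bins <- which(starts < 0)
  post_bins <- which(starts >= 0)
  baseline <- as.vector(psth$counts[, base_bins])
  vals <- vapply(post_bins,
                 function(b) auroc_bin(psth$counts[, b], baseline),
                 numeric(1))
  structure(
    list(neuron_id = psth$neuron_id, stimulus = psth$stimulus,
         bin_start_s = starts[post_bins], auroc = vals),
    class = "auroc_profile"
  )
}

#' Cue-similarity index from one neuron-bin quadruple
#'
#' Compares how similarly a neuron responds to cues of similar vs different
#' associability. With auROC-normalized responses O (odor), S (air puff),
#' T (tone), L (light):
#' `|R|_similar = 0.5 (|ln O/S| + |ln T/L|)`,
#' `|R|_dissimilar = 0.25 (|ln O/T| + |ln O/L| + |ln S/T| + |ln S/L|)`,
#' and `CI = |R|_dissimilar - |R|_similar`. Positive values mean responses
#' to similarly associable cues (odor/air puff; tone/light) resemble each
#' other more than responses across the pairs. Values are clipped to
#' `[eps, 1 - eps]` before taking logs.
#'
#' @param quad Numeric vector of length 4 with names or order
#'   `c(odor, air_puff, tone, light)` of auROC values.
#' @param pairing Which pairing counts as "similar": the default `"OS_TL"`
#'   (odor/air puff and tone/light) or the two shuffled alternatives
#'   `"OT_SL"`, `"OL_ST"` used for the null band.
#' @param eps Clipping bound (default 0.001).
#' @return The cue-similarity index (scalar).
#' @export
cue_similarity <- function(quad, pairing = c("OS_TL", "OT_SL", "OL_ST"),
                           eps = 0.001) {
  pairing <- match.arg(pairing)
  stopifnot(length(quad) == 4)
  q <- pmin(pmax(as.numeric(quad), eps), 1 - eps)
  names(q) <- c("O", "S", "T", "L")
  pairs <- switch(pairing,
    OS_TL = list(sim = list(c("O", "S"), c("T", "L"))),
    OT_SL = list(sim = list(c("O", "T"), c("S", "L"))),
    OL_ST = list(sim = list(c("O", "L"), c("S", "T"))))
  sim <- pairs$sim
  all_pairs <- utils::combn(names(q), 2, simplify = FALSE)
  is_sim <- vapply(all_pairs, function(p)
    any(vapply(sim, function(s) setequal(p, s), logical(1))), logical(1))
  lr <- vapply(all_pairs, function(p) abs(log(q[p[1]] / q[p[2]])), numeric(1))
  mean(lr[!is_sim]) - mean(lr[is_sim])
}

#' Cue-similarity time course with shuffled-pairing null band
#'
#' For each 200 ms bin, averages the cue-similarity index over neurons, and
#' builds a null distribution by resampling neurons with replacement and
#' recomputing the index under the two shuffled pairings (odor/tone +
#' air puff/light, and odor/light + air puff/tone), pooled. Bins whose
#' observed index exceeds the null band's upper bound are flagged
#' significant.
#'
#' @param profiles Named list (one element per neuron) of lists of
#'   [auroc_profile()] objects covering all four cues; or a 3-d array
#'   `neurons x bins x 4` with cue order odor, air_puff, tone, light.
#' @param n_boot Bootstrap resamples per alternative pairing (default 1000).
#' @param seed Optional integer seed.
#' @param eps Clipping bound passed to [cue_similarity()].
#' @return Object of class `similarity_result`: data frame with
#'   `bin_start_s`, `observed_ci`, `null_lo`, `null_hi`, `significant`.
#' @export
similarity_timecourse <- function(profiles, n_boot = 1000L, seed = NULL,
                                  eps = 0.001) {
  arr <- if (is.array(profiles)) profiles else similarity_array(profiles)
  n_neurons <- dim(arr)[1]
  if (n_neurons < 5) stop("fewer than 5 neurons; refused")
  n_bins <- dim(arr)[2]
  if (!is.null(seed)) set.seed(seed)

  # per-neuron-per-bin CI under each pairing (vectorized form of
  # cue_similarity); the bootstrap then only resamples neuron rows
  l <- log(pmin(pmax(arr, eps), 1 - eps))
  d <- function(i, j) abs(l[, , i, drop = FALSE] - l[, , j, drop = FALSE])
  O <- 1L; S <- 2L; T_ <- 3L; L_ <- 4L
  ci_per <- function(sim1, sim2) {
    others <- setdiff(list(c(O, S), c(O, T_), c(O, L_), c(S, T_),
                           c(S, L_), c(T_, L_)), list(sim1, sim2))
    dis <- Reduce(`+`, lapply(others, function(p) d(p[1], p[2]))) / 4
    sim <- (d(sim1[1], sim1[2]) + d(sim2[1], sim2[2])) / 2
    matrix(dis - sim, n_neurons, n_bins)
  }
  per <- list(OS_TL = ci_per(c(O, S), c(T_, L_)),
              OT_SL = ci_per(c(O, T_), c(S, L_)),
              OL_ST = ci_per(c(O, L_), c(S, T_)))
  observed <- colMeans(per$OS_TL)
  null_vals <- matrix(NA_real_, nrow = 2L * n_boot, ncol = n_bins)
  for (r in seq_len(n_boot)) {
    idx <- sample.int(n_neurons, n_neurons, replace = TRUE)
    null_vals[2L * r - 1L, ] <- colMeans(per$OT_SL[idx, , drop = FALSE])
    null_vals[2L * r, ] <- colMeans(per$OL_ST[idx, , drop = FALSE])
  }
  lo <- apply(null_vals, 2, stats::quantile, probs = 0.025, names = FALSE)
  hi <- apply(null_vals, 2, stats::quantile, probs = 0.975, names = FALSE)
  bin_start <- attr(arr, "bin_start_s")
  if (is.null(bin_start)) bin_start <- seq_len(n_bins)
  structure(
    data.frame(bin_start_s = bin_start, observed_ci = observed,
               null_lo = lo, null_hi = hi, significant = observed > hi),
    class = c("similarity_result", "data.frame")
  )
}

# Stack per-neuron auroc_profile lists into a neurons x bins x 4 array
# (cue order odor, air_puff, tone, light), keeping only bins common to all.
similarity_array <- function(profiles) {
  cue_order <- c("odor", "air_puff", "tone", "light")
  first <- profiles[[1]]
  stim_of <- function(pl) vapply(pl, `[[`, character(1), "stimulus")
  bins <- first[[match(cue_order[1], stim_of(first))]]$bin_start_s
  arr <- array(NA_real_, dim = c(length(profiles), length(bins), 4L))
  for (i in seq_along(profiles)) {
    pl <- profiles[[i]]
    stims <- stim_of(pl)
    for (j in seq_along(cue_order)) {
      k <- match(cue_order[j], stims)
      if (is.na(k)) stop("neuron ", i, " lacks a profile for ", cue_order[j])
      v <- pl[[k]]$auroc[seq_along(bins)]
      arr[i, , j] <- v
    }
  }
  attr(arr, "bin_start_s") <- bins
  arr
}
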