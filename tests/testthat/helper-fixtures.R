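# Small in-code fixtures shared across test files.

# A minimal hand-built session: one neuron, one trial per stimulus subset.
toy_session <- function(spike_times = c(0.05, 0.5, 1.0),
                        stimulus = "odor") {
  trials <- data.frame(trial_id = 1L, stimulus = stimulus, day = 1L,
                       cue_label = NA_character_)
  spikes <- data.frame(neuron_id = "n1", trial_id = 1L,
                       time_s = spike_times)
  spike_session("toy", "untrained", trials, spikes)
}

# Constant-rate pooled spike train: `rate` Hz x n_trials trials over window.
constant_pooled <- function(rate, n_trials, window = c(-1, 2)) {
  n <- stats::rpois(1, rate * n_trials * diff(window))
  tt <- sort(stats::runif(n, window[1], window[2]))
  attr(tt, "n_trials") <- n_trials
  tt
}

# Step-rate pooled train: rate1 before t0, rate2 after, over window.
step_pooled <- function(rate1, rate2, t0, n_trials, window = c(-1, 2)) {
  n1 <- stats::rpois(1, rate1 * n_trials * (t0 - window[1]))
  n2 <- stats::rpois(1, rate2 * n_trials * (window[2] - t0))
  tt <- sort(c(stats::runif(n1, window[1], t0),
               stats::runif(n2, t0, window[2])))
  attr(tt, "n_trials") <- n_trials
  tt
}

# psth stub with given per-bin Poisson rate (Hz), 17 bins over [-1, 2.4).
psth_stub <- function(rate_hz, stimulus, n_trials = 10,
                      edges = seq(-1, 2.4, by = 0.2)) {
  nb <- length(edges) - 1L
  counts <- matrix(stats::rpois(n_trials * nb, rate_hz * 0.2), n_trials, nb)
  structure(list(neuron_id = "stub", stimulus = stimulus,
                 bin_edges_s = edges, rate_hz = counts / 0.2,
                 counts = counts),
            class = "psth")
}

# Fast generator config for tests.
quick_config <- function(condition = "untrained", n_neurons = 10,
                         seed = 1, ...) {
  generator_config(condition, n_neurons = n_neurons,
                   trials_per_stimulus = 8L, seed = seed, ...)
}

zero_probs <- c(sucrose = 0, NaCl = 0, citric_acid = 0, quinine = 0,
                air_puff = 0, odor = 0, tone = 0, light = 0)

# Brute-force leave-one-pseudo-trial-out nearest-centroid oracle:
# explicit loops and explicit template means, no shared code with decode_bin.
oracle_decode <- function(x) { # x: R x K x S
  r <- dim(x)[1]; k <- dim(x)[2]; s <- dim(x)[3]
  correct <- 0L
  conf <- matrix(0, s, s)
  for (si in seq_len(s)) {
    for (j in seq_len(k)) {
      held <- x[, j, si, drop = FALSE]
      dists <- rep(NA_real_, s)
      for (sj in seq_len(s)) {
        tmpl <- rowMeans(x[, setdiff(seq_len(k), j), sj, drop = FALSE])
        dists[sj] <- sqrt(sum((held - tmpl)^2))
      }
      pred <- which.min(dists)
      conf[si, pred] <- conf[si, pred] + 1
      if (pred == si) correct <- correct + 1L
    }
  }
  list(accuracy = correct / (s * k), confusion = conf / k)
}
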