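test_that("the generator is deterministic under a fixed seed", {
  g1 <- generate_session(quick_config(n_neurons = 5, seed = 41))
  g2 <- generate_session(quick_config(n_neurons = 5, seed = 41))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_generated(g1, d1)
  write_generated(g2, d2)
  for (f in c("spikes.tsv", "trials.tsv", "ground_truth.json",
              "manifest.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("adding neurons does not perturb existing substreams", {
  g5 <- generate_session(quick_config(n_neurons = 5, seed = 42))
  g8 <- generate_session(quick_config(n_neurons = 8, seed = 42))
  s5 <- g5$session$spikes
  s8 <- g8$session$spikes[g8$session$spikes$neuron_id %in% unique(s5$neuron_id), ]
  rownames(s8) <- NULL
  expect_equal(s5, s8)
})

test_that("realized odor responders fall in the binomial band of the configured probability", {
  gen <- generate_session(generator_config("untrained", seed = 43))
  n_odor <- gen$manifest$realized_responders$odor
  band <- qbinom(c(0.025, 0.975), 135, 0.16)
  expect_gte(n_odor, band[1])
  expect_lte(n_odor, band[2])
})

test_that("spike counts on constant segments are Poisson (variance ~ mean)", {
  gen <- generate_session(quick_config(
    n_neurons = 1, seed = 44, response_probs = zero_probs,
    baseline_log_sd = 0))
  s <- gen$session
  counts <- unlist(lapply(stimulus_trials(s, "odor"), function(id)
    sum(s$spikes$trial_id == id)))
  # dispersion test: (n-1) s^2 / xbar ~ chi-square(n-1) under Poisson
  n <- length(counts)
  disp <- (n - 1) * var(counts) / mean(counts)
  expect_gt(disp, qchisq(0.005, n - 1))
  expect_lt(disp, qchisq(0.995, n - 1))
})

test_that("an all-zero-probability config yields ~alpha responsiveness", {
  gen <- generate_session(quick_config(n_neurons = 25, seed = 45,
                                       response_probs = zero_probs))
  pr <- response_profiles(gen$session,
                          stimuli = c("odor", "air_puff", "sucrose"))
  expect_lte(mean(pr$responsive), 0.10)
})

test_that("null sessions have exchangeable labels for the decoder", {
  s <- generate_null_session(quick_config(n_neurons = 20, seed = 46))
  pop <- build_pseudopopulation(s, seed = 1)
  set.seed(2)
  acc <- mean(decode_timecourse(pop)$accuracy)
  expect_lt(abs(acc - 0.25), 0.12) # single session; wide Monte-Carlo band
})

test_that("similarity coupling raises the cue-similarity index", {
  mk <- function(coupling, seed) {
    g <- generate_session(generator_config(
      "trained", n_neurons = 30, trials_per_stimulus = 10L,
      seed = seed, similarity_coupling = coupling))
    sess <- g$session
    m <- response_matrix(response_profiles(sess,
                                           stimuli = CROSSMODAL_STIMULI))
    keep <- rownames(m)[rowSums(m) >= 1]
    profs <- lapply(keep, function(nr)
      lapply(CROSSMODAL_STIMULI, function(st)
        auroc_profile(bin_spikes(sess, nr, st))))
    mean(similarity_timecourse(profs, n_boot = 100,
                               seed = seed + 1)$observed_ci)
  }
  expect_gt(mk(0.8, 47), mk(0, 48))
})

test_that("orofacial traces start naive and end conditioned", {
  tr <- generate_orofacial(seed = 49)
  es <- function(d, cue) {
    sub <- tr[tr$day == d & tr$cue == cue, ]
    per <- vapply(split(sub, sub$trial_id), function(x)
      unlist(epoch_stats(x$t_s, x$delta_intensity)["cue"]), numeric(1))
    sp <- vapply(split(sub, sub$trial_id), function(x)
      unlist(epoch_stats(x$t_s, x$delta_intensity)["spontaneous"]),
      numeric(1))
    c(cue = mean(per), spont = mean(sp))
  }
  d1 <- es(1, "odor")
  expect_lt(abs(d1["cue"] - d1["spont"]), 0.02)
  d14 <- vapply(c("air_puff", "odor", "tone", "light"),
                function(cue) es(14, cue)[["cue"]], numeric(1))
  expect_true(all(d14 > 0.2))
  # all four cues reach similar final amplitude
  expect_lt(diff(range(d14)), 0.15)
})
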