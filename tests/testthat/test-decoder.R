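test_that("pseudo-population construction enforces the trial rules", {
  mk_sess <- function(id, n_trials_by_cue) {
    trials <- do.call(rbind, mapply(function(st, n, off) {
      data.frame(trial_id = off + seq_len(n), stimulus = st, day = 1L)
    }, CROSSMODAL_STIMULI, n_trials_by_cue,
    c(0, cumsum(n_trials_by_cue))[1:4], SIMPLIFY = FALSE))
    spikes <- data.frame(neuron_id = "u1",
                         trial_id = trials$trial_id,
                         time_s = 0.1)
    spike_session(id, "untrained", trials, spikes)
  }
  # all cues at 8+: kept; one cue at 7: excluded
  s_ok <- mk_sess("a", c(8, 9, 14, 10))
  s_bad <- mk_sess("b", c(8, 8, 7, 8))
  pop <- build_pseudopopulation(list(s_ok), seed = 1)
  expect_equal(pop$k, 8)
  expect_error(build_pseudopopulation(list(s_bad), seed = 1),
               "no units")
  # K is the minimum over included units and stimuli
  g <- generate_session(generator_config("untrained", n_neurons = 3,
                                         trials_per_stimulus = 8:14,
                                         seed = 71))
  pop2 <- build_pseudopopulation(g$session, seed = 2)
  counts <- table(g$session$trials$stimulus)[CROSSMODAL_STIMULI]
  expect_equal(pop2$k, min(counts))
  # determinism
  pop3 <- build_pseudopopulation(g$session, seed = 2)
  expect_identical(pop2$rates, pop3$rates)
  # optional z-scoring centers each unit
  popz <- build_pseudopopulation(g$session, seed = 2, normalize = TRUE)
  expect_equal(mean(popz$rates[1, , , ]), 0, tolerance = 1e-12)
  expect_equal(sd(popz$rates[1, , , ]), 1, tolerance = 1e-12)
})

test_that("decode_bin matches the brute-force oracle on toy tensors", {
  set.seed(72)
  for (case in 1:100) {
    r <- sample(1:3, 1); k <- sample(2:4, 1)
    x <- array(runif(r * 1 * k * 4, 0, 10), dim = c(r, 1, k, 4))
    got <- decode_bin(x, 1)
    want <- oracle_decode(array(x, dim = c(r, k, 4)))
    expect_equal(got$accuracy, want$accuracy)
    expect_equal(unname(got$confusion), unname(want$confusion))
  }
})

test_that("disjoint noiseless patterns decode perfectly", {
  x <- array(0, dim = c(4, 1, 3, 4))
  for (s in 1:4) x[s, 1, , s] <- 50 # one indicator neuron per stimulus
  expect_equal(decode_bin(x, 1)$accuracy, 1.0)
})

test_that("accuracy is equivariant under stimulus relabeling", {
  set.seed(73)
  x <- array(runif(5 * 2 * 4 * 4, 0, 10), dim = c(5, 2, 4, 4))
  perm <- c(3, 1, 4, 2)
  a <- decode_bin(x, 2)
  b <- decode_bin(x[, , , perm, drop = FALSE], 2)
  expect_equal(b$accuracy, a$accuracy)
  expect_equal(unname(b$confusion), unname(a$confusion[perm, perm]))
})

test_that("an uninformative neuron degrades accuracy only within noise", {
  set.seed(74)
  base <- array(rep(c(10, 2, 2, 2, 2, 10, 2, 2), each = 1),
                dim = c(2, 1, 1, 4))
  accs <- replicate(30, {
    x <- array(rpois(3 * 1 * 8 * 4, 2), dim = c(3, 1, 8, 4))
    for (s in 1:2) x[s, 1, , s] <- rpois(8, 12)
    with3 <- decode_bin(x, 1)$accuracy
    with2 <- decode_bin(x[1:2, , , , drop = FALSE], 1)$accuracy
    c(with2, with3)
  })
  expect_lt(mean(accs[1, ]) - mean(accs[2, ]), 0.1)
})

test_that("bootstrap bands behave on null and informative populations", {
  set.seed(75)
  null_x <- array(rpois(20 * 3 * 8 * 4, 1.5), dim = c(20, 3, 8, 4))
  pop <- structure(list(rates = null_x, stimuli = CROSSMODAL_STIMULI,
                        bin_start_s = c(0, 0.2, 0.4), k = 8,
                        neuron_ids = paste0("u", 1:20)),
                   class = "pseudo_population")
  band <- bootstrap_band(pop, n_boot = 60, seed = 76)
  expect_gte(mean(band$lo <= 0.25 & band$hi >= 0.25), 0.9)
  expect_error(bootstrap_band(pop, n_boot = 10), "refused")

  # every neuron is informative so resampling cannot drop the signal
  info_x <- null_x
  for (i in 1:20) info_x[i, , , (i %% 4) + 1] <- info_x[i, , , (i %% 4) + 1] + 8
  pop$rates <- info_x
  band2 <- bootstrap_band(pop, n_boot = 60, seed = 77)
  expect_true(all(band2$lo > 0.25))
})

test_that("hits analysis reduces confusions to correct and false hits", {
  mk_result <- function(conf) {
    structure(list(
      accuracy = rep(mean(diag(conf)), 19),
      confusion = aperm(array(conf, dim = c(4, 4, 19),
                              dimnames = list(CROSSMODAL_STIMULI,
                                              CROSSMODAL_STIMULI, NULL)),
                        c(3, 1, 2)),
      bin_start_s = seq(-1, 2.6, by = 0.2),
      stimuli = CROSSMODAL_STIMULI), class = "decoding_result")
  }
  ident <- mk_result(diag(4))
  h <- hits_analysis(ident)
  expect_equal(unname(h$onset$correct), rep(1, 4))
  expect_equal(unname(h$onset$false), rep(0, 4))

  unif <- mk_result(matrix(0.25, 4, 4))
  h2 <- hits_analysis(unif)
  expect_equal(unname(h2$offset$correct), rep(0.25, 4))
  expect_equal(unname(h2$offset$false), rep(0.25, 4))
  expect_error(hits_analysis(unif, windows = list(bad = c(9, 10))),
               "no bins")
})

test_that("paired-cue confusions dominate after similarity coupling", {
  g <- generate_session(generator_config(
    "trained", n_neurons = 40, trials_per_stimulus = 8L, seed = 78,
    similarity_coupling = 0.9,
    response_probs = c(sucrose = 0, NaCl = 0, citric_acid = 0,
                       quinine = 0, air_puff = 0.6, odor = 0.6,
                       tone = 0.6, light = 0.6)))
  pop <- build_pseudopopulation(g$session, seed = 79)
  set.seed(80)
  tc <- decode_timecourse(pop)
  h <- hits_analysis(tc, windows = list(stim = c(0.5, 2)))
  conf <- h$stim$confusion
  paired <- conf["odor", "air_puff"] + conf["air_puff", "odor"] +
    conf["tone", "light"] + conf["light", "tone"]
  unpaired <- sum(conf) - sum(diag(conf)) - paired
  expect_gt(paired, unpaired)
})
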