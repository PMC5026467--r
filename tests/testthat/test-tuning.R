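test_that("sharpness evaluates the analytic cases exactly", {
  expect_identical(sharpness(c(5, 0, 0, 0, 0, 0, 0, 0)), 1)
  expect_identical(sharpness(rep(3, 8)), 0)
  expect_equal(sharpness(c(4, 2, 2, 2, 2, 2, 2, 2)), 0.5)
  expect_error(sharpness(rep(0, 8)), "undefined")
})

test_that("sharpness is scale-invariant and pins its extremes", {
  set.seed(51)
  for (i in 1:20) {
    fr <- runif(8, 0, 20)
    expect_equal(sharpness(fr), sharpness(3.7 * fr))
  }
  one_hot <- replace(rep(0, 8), sample(8, 1), runif(1, 1, 10))
  expect_equal(sharpness(one_hot), 1)
})

test_that("taste selectivity has near-nominal false-positive rate and high power", {
  set.seed(52)
  fp <- mean(replicate(40, {
    ps <- lapply(TASTE_STIMULI, function(st) psth_stub(5, st))
    taste_selective(ps)$selective
  }))
  expect_lte(fp, 0.2) # two alpha = 0.05 chances; nominal ~ 0.05-0.10
  pw <- mean(replicate(20, {
    ps <- c(lapply(TASTE_STIMULI[1:3], function(st) psth_stub(5, st)),
            list(psth_stub(13, "quinine")))
    taste_selective(ps)$selective
  }))
  expect_gt(pw, 0.9)
})

test_that("taste selectivity rejects degenerate input", {
  ps <- lapply(TASTE_STIMULI, function(st) psth_stub(0, st))
  ps <- lapply(ps, function(p) { p$counts[] <- 0; p$rate_hz[] <- 0; p })
  expect_error(taste_selective(ps), "indeterminate")
  expect_error(taste_selective(list(psth_stub(5, "sucrose"))), "length")
})

test_that("convergence counts partition the population", {
  m <- matrix(FALSE, 3, 8,
              dimnames = list(NULL, c(TASTE_STIMULI, CROSSMODAL_STIMULI)))
  m[1, "odor"] <- TRUE
  cc <- convergence_counts(m)
  expect_equal(unname(cc$by_n_cues), c(2, 1, 0, 0, 0))
  expect_equal(cc$cue_responders, 1)
  expect_equal(sum(cc$by_n_cues), cc$n_neurons)

  all_false <- matrix(FALSE, 4, 8,
                      dimnames = list(NULL, c(TASTE_STIMULI,
                                              CROSSMODAL_STIMULI)))
  expect_equal(unname(convergence_counts(all_false)$by_n_cues),
               c(4, 0, 0, 0, 0))

  # a matrix built to match the untrained convergence pie: 38/5/2 of 45
  m2 <- matrix(FALSE, 45, 4, dimnames = list(NULL, CROSSMODAL_STIMULI))
  for (i in 1:38) m2[i, sample(4, 1)] <- TRUE
  for (i in 39:43) m2[i, sample(4, 2)] <- TRUE
  for (i in 44:45) m2[i, sample(4, 3)] <- TRUE
  cc2 <- convergence_counts(m2)
  expect_equal(unname(cc2$by_n_cues[c("1", "2", "3")]), c(38, 5, 2))
})

test_that("independence bootstrap handles degenerate and null cases", {
  # all probabilities 1: the simulated count is degenerate at n, p = 1
  r <- independence_bootstrap(20, rep(1, 4), observed = 20,
                              n_sims = 500, seed = 53)
  expect_equal(r$p_value, 1)
  expect_equal(r$ci, c(20, 20))
  expect_error(independence_bootstrap(20, rep(0.5, 4), 5, n_sims = 50),
               "refused")
})

test_that("observed convergence under independent marginals is not flagged", {
  # the untrained population: 7 multi-cue neurons among 135
  r <- independence_bootstrap(
    135, c(air_puff = 0.15, odor = 0.16, tone = 0.04, light = 0.03),
    observed = 7, statistic = "multi_cue", n_sims = 2000, seed = 54)
  expect_gt(r$p_value, 0.05)
})

test_that("forced convergence is detected with good power", {
  set.seed(55)
  hits <- replicate(10, {
    g <- generate_session(generator_config(
      "untrained", n_neurons = 100, trials_per_stimulus = 8L,
      seed = sample.int(1e6, 1), similarity_coupling = 0.9,
      response_probs = c(sucrose = 0, NaCl = 0, citric_acid = 0,
                         quinine = 0, air_puff = 0.15, odor = 0.15,
                         tone = 0.15, light = 0.15)))
    truth <- vapply(g$ground_truth, function(gt)
      vapply(CROSSMODAL_STIMULI, function(st)
        gt$profiles[[st]]$responds, logical(1)), logical(4))
    m <- t(truth)
    obs <- sum(rowSums(m) >= 2)
    independence_bootstrap(100, colMeans(m), obs,
                           n_sims = 1000)$p_value < 0.05
  })
  expect_gte(mean(hits), 0.8)
})
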