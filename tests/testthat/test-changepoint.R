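test_that("cumulative_counts builds the pooled step function", {
  cc <- cumulative_counts(c(0.2, 0.1), c(-1, 2))
  expect_equal(cc$times, c(0.1, 0.2))
  expect_equal(cc$counts, c(1, 2))
  empty <- cumulative_counts(numeric(0), c(-1, 2))
  expect_length(empty$times, 0)
  expect_error(cumulative_counts(1, c(2, -1)), "degenerate")
})

test_that("a Poisson train's CDF stays near the linear ramp", {
  set.seed(31)
  tt <- sort(runif(1000, -1, 2))
  cc <- cumulative_counts(tt, c(-1, 2))
  ramp <- 1000 * (cc$times + 1) / 3
  # Kolmogorov bound: sup deviation ~ O(sqrt(n)); 1.63 sqrt(n) is the 1% point
  expect_lt(max(abs(cc$counts - ramp)), 1.63 * sqrt(1000))
})

test_that("detected change points are ordered, in-window, and empty for no spikes", {
  expect_equal(nrow(detect_change_points(numeric(0), c(-1, 2))), 0)
  set.seed(32)
  tt <- step_pooled(5, 25, 0.8, 10)
  cps <- detect_change_points(tt, c(-1, 2))
  expect_true(all(diff(cps$time_s) > 0))
  expect_true(all(cps$time_s >= -1 & cps$time_s <= 2))
  expect_true(all(cps$p_value >= 0 & cps$p_value <= 1))
})

test_that("change-point detection is translation-equivariant and pooling-order-free", {
  set.seed(33)
  tt <- step_pooled(5, 20, 0.5, 10)
  a <- detect_change_points(tt, c(-1, 2))
  b <- detect_change_points(as.numeric(tt) + 2.5, c(1.5, 4.5))
  expect_equal(b$time_s, a$time_s + 2.5, tolerance = 1e-12)
  expect_equal(b$p_value, a$p_value)
  # pooled times are a set: permuting input order changes nothing
  perm <- sample(as.numeric(tt))
  c <- detect_change_points(perm, c(-1, 2))
  expect_equal(c, a)
})

test_that("a step response yields an accurate first change point", {
  set.seed(34)
  hits <- replicate(100, {
    tt <- step_pooled(5, 20, 0.5, 10)
    cps <- detect_change_points(tt, c(-1, 2))
    post <- cps[cps$time_s > 0, ]
    nrow(post) > 0 && abs(post$time_s[1] - 0.5) <= 0.1 &&
      post$direction[1] == "increase"
  })
  expect_gte(mean(hits), 0.9)
})

test_that("detection power increases with step size", {
  set.seed(35)
  power_at <- function(rate2) {
    mean(replicate(60, {
      tt <- step_pooled(5, rate2, 0.5, 10)
      any(detect_change_points(tt, c(-1, 2))$time_s > 0)
    }))
  }
  p <- c(power_at(7), power_at(10), power_at(20))
  expect_true(all(diff(p) >= 0) || (p[3] > p[1]))
  expect_gt(p[3], 0.9)
})

test_that("classify_response assigns sign and modulation count", {
  # no post-onset CP
  none <- classify_response(
    data.frame(time_s = numeric(0), p_value = numeric(0),
               direction = character(0)),
    c(-0.5, 0.3), c(-1, 2), n_trials = 1)
  expect_false(none$responsive)
  expect_equal(none$sign, "none")
  expect_equal(none$n_modulations, 0L)

  # step up at 0.3 s
  set.seed(36)
  up <- step_pooled(4, 20, 0.3, 10)
  cps <- detect_change_points(up, c(-1, 2))
  cl <- classify_response(cps, up, c(-1, 2))
  expect_true(cl$responsive)
  expect_equal(cl$sign, "excited")
  expect_gte(cl$n_modulations, 1L)

  # up at 0.3, back down at 1.2: excited with two modulations
  set.seed(37)
  n_trials <- 12
  tt <- sort(c(runif(rpois(1, 4 * n_trials * 1.3), -1, 0.3),
               runif(rpois(1, 25 * n_trials * 0.9), 0.3, 1.2),
               runif(rpois(1, 4 * n_trials * 0.8), 1.2, 2)))
  attr(tt, "n_trials") <- n_trials
  cps <- detect_change_points(tt, c(-1, 2))
  cl <- classify_response(cps, tt, c(-1, 2))
  expect_true(cl$responsive)
  expect_equal(cl$sign, "excited")
  expect_equal(cl$n_modulations, 2L)

  # inhibition: drop from 20 to 2 Hz
  set.seed(38)
  dn <- step_pooled(20, 2, 0.4, 10)
  cps <- detect_change_points(dn, c(-1, 2))
  cl <- classify_response(cps, dn, c(-1, 2))
  expect_equal(cl$sign, "inhibited")
})

test_that("response_profiles marks ground-truth responders in a session", {
  # well-driven neurons (8 Hz baseline, excitatory-only) so that detection
  # power, not response magnitude, is what the test exercises
  gen <- generate_session(generator_config(
    "untrained", n_neurons = 6, trials_per_stimulus = 12L, seed = 39,
    response_probs = c(sucrose = 1, NaCl = 0, citric_acid = 0, quinine = 0,
                       air_puff = 1, odor = 0, tone = 0, light = 0),
    p_taste_selective = 1, frac_inhibited = 0,
    baseline_log_median = 8, baseline_log_sd = 0.3))
  pr <- response_profiles(gen$session,
                          stimuli = c("sucrose", "air_puff", "tone"))
  hit <- pr[pr$stimulus %in% c("sucrose", "air_puff"), ]
  expect_gt(mean(hit$responsive), 0.8)
  # tone responses exist only at the false-positive level
  expect_lte(sum(pr$responsive[pr$stimulus == "tone"]), 2)
})
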