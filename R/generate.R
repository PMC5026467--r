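#' Generator configuration
#'
#' Defaults reproduce the statistical structure of the two recorded
#' populations: 135 untrained / 118 trained neurons, 8-14 trials per
#' stimulus, the observed marginal response probabilities per stimulus,
#' the observed taste-selective fraction, the observed inhibited fraction
#' among cue responses, and the observed mean number of firing-rate
#' modulations per response (1.22 untrained, 1.44 trained). Baseline rates
#' are log-normal (median 4 Hz, sigma_log 0.6); evoked modulations move the
#' rate by 50-200% of baseline.
#'
#' @param condition `"untrained"` or `"trained"`.
#' @param n_neurons Number of neurons (default 135 / 118 by condition).
#' @param trials_per_stimulus Integer range of trials per stimulus,
#'   default `8:14`.
#' @param response_probs Named per-stimulus marginal response
#'   probabilities; defaults to the observed values by condition.
#' @param p_taste_selective Fraction of neurons that are taste selective
#'   (default 0.64 / 0.57).
#' @param frac_inhibited Fraction of responses whose first modulation is
#'   inhibitory (default 0.296 / 0.477).
#' @param mean_modulations Mean modulations per response (default
#'   1.22 / 1.44); drawn as 1 + Poisson(mean - 1).
#' @param similarity_coupling Weight in \[0, 1\] tying the odor/air-puff
#'   and tone/light response profiles (and responsiveness) together;
#'   default 0, i.e. independent responses as observed in the convergence
#'   analysis.
#' @param baseline_log_median,baseline_log_sd Log-normal baseline-rate
#'   parameters (Hz).
#' @param seed Integer seed (mandatory).
#' @return Object of class `generator_config` (a list).
#' @export
generator_config <- function(condition = c("untrained", "trained"),
                             n_neurons = NULL,
                             trials_per_stimulus = 8:14,
                             response_probs = NULL,
                             p_taste_selective = NULL,
                             frac_inhibited = NULL,
                             mean_modulations = NULL,
                             similarity_coupling = 0,
                             baseline_log_median = 4,
                             baseline_log_sd = 0.6,
                             seed) {
  condition <- match.arg(condition)
  if (missing(seed)) stop("seed is mandatory")
  untrained <- condition == "untrained"
  if (is.null(n_neurons)) n_neurons <- if (untrained) 135L else 118L
  if (is.null(response_probs)) {
    response_probs <- if (untrained) {
      c(sucrose = 0.385, NaCl = 0.414, citric_acid = 0.414,
        quinine = 0.385, air_puff = 0.15, odor = 0.16,
        tone = 0.04, light = 0.03)
    } else {
      c(sucrose = 0.385, NaCl = 0.414, citric_acid = 0.414,
        quinine = 0.385, air_puff = 0.34, odor = 0.33,
        tone = 0.16, light = 0.11)
    }
  }
  if (is.null(p_taste_selective))
    p_taste_selective <- if (untrained) 0.64 else 0.57
  if (is.null(frac_inhibited))
    frac_inhibited <- if (untrained) 0.296 else 0.477
  if (is.null(mean_modulations))
    mean_modulations <- if (untrained) 1.22 else 1.44
  stopifnot(all(response_probs >= 0 & response_probs <= 1),
            p_taste_selective >= 0, p_taste_selective <= 1,
            frac_inhibited >= 0, frac_inhibited <= 1,
            mean_modulations >= 1,
            similarity_coupling >= 0, similarity_coupling <= 1)
  structure(
    list(condition = condition, n_neurons = as.integer(n_neurons),
         trials_per_stimulus = as.integer(trials_per_stimulus),
         response_probs = response_probs,
         p_taste_selective = p_taste_selective,
         frac_inhibited = frac_inhibited,
         mean_modulations = mean_modulations,
         similarity_coupling = similarity_coupling,
         baseline_log_median = baseline_log_median,
         baseline_log_sd = baseline_log_sd,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

# Deterministic per-neuron substream seed so adding neurons does not
# perturb existing ones.
substream_seed <- function(seed, i) {
  as.integer(((seed %% 100000L) * 20011 + i * 7919) %% (2^31 - 1))
}

#' Generate a synthetic spike session with ground truth
#'
#' Each neuron is an inhomogeneous Poisson process with a piecewise-
#' constant rate: baseline before stimulus onset, then one level per
#' modulation at its ground-truth change times. Responses per stimulus are
#' drawn independently with the configured marginal probabilities; neurons
#' that respond to a taste but are not taste selective respond to all four
#' tastants with one shared profile. A positive `similarity_coupling`
#' makes the odor/air-puff and tone/light cue pairs share responsiveness
#' and response profiles with that probability.
#'
#' @param config A [generator_config()].
#' @param windows An [analysis_windows()] object.
#' @return List with `session` (a [spike_session()]), `ground_truth` (one
#'   list per neuron) and `manifest` (config echo plus realized responder
#'   counts per stimulus).
#' @export
generate_session <- function(config, windows = analysis_windows()) {
  stopifnot(inherits(config, "generator_config"))
  stimuli <- c(TASTE_STIMULI, CROSSMODAL_STIMULI)
  if (config$condition == "trained") stimuli <- c(stimuli, "expected_sucrose")

  set.seed(config$seed)
  n_trials <- config$trials_per_stimulus[sample.int(
    length(config$trials_per_stimulus), length(stimuli), replace = TRUE)]
  names(n_trials) <- stimuli
  trials <- data.frame(
    trial_id = integer(0), stimulus = character(0), day = integer(0),
    cue_label = character(0))
  tid <- 0L
  for (st in stimuli) {
    ids <- tid + seq_len(n_trials[[st]])
    tid <- tid + n_trials[[st]]
    cue <- if (st == "expected_sucrose") {
      sample(CROSSMODAL_STIMULI, n_trials[[st]], replace = TRUE)
    } else NA_character_
    trials <- rbind(trials, data.frame(
      trial_id = ids, stimulus = st, day = 1L, cue_label = cue))
  }

  ground_truth <- vector("list", config$n_neurons)
  spike_rows <- vector("list", config$n_neurons)
  for (i in seq_len(config$n_neurons)) {
    set.seed(substream_seed(config$seed, i))
    gt <- draw_ground_truth(config, stimuli, windows)
    gt$neuron_id <- sprintf("n%03d", i)
    ground_truth[[i]] <- gt
    rows <- list()
    for (st in stimuli) {
      prof <- gt$profiles[[st]]
      w_end <- post_window_for(config$condition, resolve_stim(st), windows)
      ids <- trials$trial_id[trials$stimulus == st]
      for (id in ids) {
        tt <- sim_piecewise_poisson(gt$baseline_hz, prof, w_end)
        if (length(tt))
          rows[[length(rows) + 1L]] <- data.frame(
            neuron_id = gt$neuron_id, trial_id = id, time_s = tt)
      }
    }
    spike_rows[[i]] <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  spikes <- do.call(rbind, c(spike_rows, list(data.frame(
    neuron_id = character(0), trial_id = integer(0), time_s = numeric(0)))))

  session <- spike_session(
    session_id = sprintf("synthetic-%s-%d", config$condition, config$seed),
    condition = config$condition, trials = trials, spikes = spikes,
    neurons = vapply(ground_truth, `[[`, character(1), "neuron_id"))

  responders <- vapply(stimuli, function(st)
    sum(vapply(ground_truth, function(g) g$profiles[[st]]$responds,
               logical(1))), integer(1))
  manifest <- list(
    config = unclass(config),
    n_trials = as.list(n_trials),
    realized_responders = as.list(responders),
    n_spikes = nrow(spikes))
  list(session = session, ground_truth = ground_truth, manifest = manifest)
}

# expected_sucrose follows the taste windows of sucrose
resolve_stim <- function(st) if (st == "expected_sucrose") "sucrose" else st

# Draw one neuron's ground-truth response profile set.
draw_ground_truth <- function(config, stimuli, windows) {
  p <- config$response_probs
  baseline <- stats::rlnorm(1, log(config$baseline_log_median),
                            config$baseline_log_sd)
  responds <- stats::runif(8) < p[c(TASTE_STIMULI, CROSSMODAL_STIMULI)]
  names(responds) <- c(TASTE_STIMULI, CROSSMODAL_STIMULI)

  # non-selective taste responders respond to all tastes with one profile
  taste_selective <- FALSE
  share_taste <- FALSE
  if (any(responds[TASTE_STIMULI])) {
    p_any <- 1 - prod(1 - p[TASTE_STIMULI])
    p_sel <- min(1, config$p_taste_selective / p_any)
    taste_selective <- stats::runif(1) < p_sel
    if (!taste_selective) {
      responds[TASTE_STIMULI] <- TRUE
      share_taste <- TRUE
    }
  }

  # similarity coupling: a coupled pair shares responsiveness + profile
  couple <- c(odor_air = FALSE, tone_light = FALSE)
  w <- config$similarity_coupling
  if (w > 0) {
    if (stats::runif(1) < w && any(responds[c("odor", "air_puff")])) {
      responds[c("odor", "air_puff")] <- TRUE
      couple["odor_air"] <- TRUE
    }
    if (stats::runif(1) < w && any(responds[c("tone", "light")])) {
      responds[c("tone", "light")] <- TRUE
      couple["tone_light"] <- TRUE
    }
  }

  draw_profile <- function(st) {
    if (!responds[[st]]) {
      return(list(responds = FALSE, sign = "none",
                  change_times_s = numeric(0), levels_hz = numeric(0)))
    }
    w_end <- post_window_for(config$condition, st, windows)
    n_mod <- 1L + stats::rpois(1, config$mean_modulations - 1)
    times <- sort(stats::runif(n_mod, 0.05, w_end - 0.3))
    inhibited <- stats::runif(1) < config$frac_inhibited
    levels <- numeric(n_mod)
    levels[1] <- if (inhibited) {
      max(0.1, baseline * stats::runif(1, 0.1, 0.5))
    } else {
      baseline * (1 + stats::runif(1, 0.5, 2))
    }
    if (n_mod > 1) {
      for (j in 2:n_mod)
        levels[j] <- max(0.1, baseline * stats::runif(1, 0.3, 2.5))
    }
    list(responds = TRUE,
         sign = if (inhibited) "inhibited" else "excited",
         change_times_s = times, levels_hz = levels)
  }

  profiles <- list()
  for (st in c(TASTE_STIMULI, CROSSMODAL_STIMULI)) profiles[[st]] <- draw_profile(st)
  if (share_taste) {
    for (st in TASTE_STIMULI[-1]) profiles[[st]] <- profiles[[TASTE_STIMULI[1]]]
  }
  if (couple["odor_air"]) profiles[["air_puff"]] <- profiles[["odor"]]
  if (couple["tone_light"]) profiles[["light"]] <- profiles[["tone"]]
  if ("expected_sucrose" %in% stimuli)
    profiles[["expected_sucrose"]] <- profiles[["sucrose"]]

  list(baseline_hz = baseline, taste_selective = taste_selective,
       profiles = profiles)
}

# One trial of an inhomogeneous (piecewise-constant) Poisson process over
# [-1, 3] s: baseline until the first change time, then one level per
# modulation, the last level persisting to the end of the trial.
sim_piecewise_poisson <- function(baseline_hz, profile, w_end,
                                  t_range = c(-1, 3)) {
  breaks <- c(t_range[1], profile$change_times_s, t_range[2])
  rates <- c(baseline_hz, profile$levels_hz)
  if (!length(profile$change_times_s)) rates <- baseline_hz
  tt <- numeric(0)
  for (s in seq_along(rates)) {
    len <- breaks[s + 1] - breaks[s]
    n <- stats::rpois(1, rates[s] * len)
    if (n) tt <- c(tt, stats::runif(n, breaks[s], breaks[s + 1]))
  }
  sort(tt)
}

#' Generate a null session (labels carry no rate information)
#'
#' Every neuron is a homogeneous Poisson process with the same rate for
#' every stimulus, so stimulus labels are exchangeable; used for decoder
#' chance-level and type-I calibration.
#'
#' @inheritParams generate_session
#' @return A [spike_session()].
#' @export
generate_null_session <- function(config, windows = analysis_windows()) {
  probs <- config$response_probs
  probs[] <- 0
  null_cfg <- config
  null_cfg$response_probs <- probs
  null_cfg$p_taste_selective <- 0
  null_cfg$similarity_coupling <- 0
  generate_session(null_cfg, windows)$session
}

#' Write a generated session with its ground truth and manifest
#'
#' Emits the canonical `spikes.tsv`/`trials.tsv` pair plus
#' `ground_truth.json` and `manifest.json`.
#'
#' @param gen Return value of [generate_session()].
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_generated <- function(gen, path) {
  write_session(gen$session, path)
  jsonlite::write_json(gen$ground_truth,
                       file.path(path, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(gen$manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
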