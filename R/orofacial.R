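#' Mouth-movement trace from a stack of video frames
#'
#' Quantifies orofacial movement as the absolute difference of the mean
#' pixel intensity of a mouth region of interest across consecutive
#' frames, normalized to the mean background-ROI intensity of the earlier
#' frame (to cancel global illumination fluctuations).
#'
#' @param frames 3-d numeric array (`height x width x n_frames`) or list
#'   of matrices of grayscale intensities.
#' @param roi_mouth,roi_background Logical masks (same size as a frame) or
#'   two-column index matrices selecting disjoint pixel sets.
#' @return Numeric vector of length `n_frames - 1` of normalized
#'   delta-intensity samples.
#' @export
frame_delta <- function(frames, roi_mouth, roi_background) {
  if (is.list(frames)) frames <- simplify2array(frames)
  stopifnot(length(dim(frames)) == 3, dim(frames)[3] >= 2)
  if (is.logical(roi_mouth) && is.logical(roi_background) &&
      any(roi_mouth & roi_background))
    stop("mouth and background ROIs must be disjoint")
  n <- dim(frames)[3]
  mouth <- vapply(seq_len(n), function(t) mean(frames[, , t][roi_mouth]),
                  numeric(1))
  bg <- vapply(seq_len(n), function(t) mean(frames[, , t][roi_background]),
               numeric(1))
  if (any(bg[-n] == 0)) stop("zero background intensity")
  abs(diff(mouth)) / bg[-n]
}

#' Epoch statistics of a movement trace
#'
#' Mean normalized delta-intensity in the three behavioral epochs:
#' spontaneous (1 s before cue onset), cue (0.5-1.5 s after onset) and
#' taste (2.7-3.7 s after onset, i.e. after sucrose delivery).
#'
#' @param t_s Sample times (s) relative to cue onset.
#' @param value Delta-intensity samples (same length).
#' @return List with `spontaneous`, `cue`, `taste` epoch means.
#' @export
epoch_stats <- function(t_s, value) {
  stopifnot(length(t_s) == length(value))
  if (min(t_s) > -1 + 1e-6 || max(t_s) < 3.7 - 1e-6)
    stop("trace must cover [-1, 3.7] s")
  m <- function(a, b) mean(value[t_s >= a & t_s < b])
  list(spontaneous = m(-1, 0), cue = m(0.5, 1.5), taste = m(2.7, 3.7))
}

#' Normalize a trace to its taste-epoch maximum
#'
#' @inheritParams epoch_stats
#' @return `value / max(value in taste epoch)`.
#' @export
normalize_to_taste_max <- function(t_s, value) {
  peak <- max(value[t_s >= 2.7 & t_s < 3.7])
  if (peak <= 0) stop("taste-epoch maximum is zero; normalization refused")
  value / peak
}

#' Generate synthetic conditioning-session movement traces
#'
#' Emulates the growth of conditioned mouth movements over daily
#' cue-sucrose pairing sessions: the cue-epoch amplitude follows a sigmoid
#' in day centered on the cue's learning day (default day 3 for the
#' strongly associable odor and air-puff cues, day 7 for tone and light),
#' while the sucrose-evoked (taste-epoch) amplitude is constant across
#' days. Samples are 30 Hz normalized delta-intensity values with
#' multiplicative per-trial and additive per-sample noise.
#'
#' @param days Number of daily sessions (default 14).
#' @param trials_per_day Trials per cue per day (default 20).
#' @param learning_day Named numeric vector of learning days per cue.
#' @param seed Integer seed.
#' @param spontaneous_level Baseline movement level (default 0.05).
#' @param cue_amplitude Asymptotic conditioned-response amplitude added
#'   during the 2 s cue (default 0.3).
#' @param taste_amplitude Sucrose-evoked amplitude added during
#'   2.5-3.7 s (default 0.5).
#' @param sigmoid_scale Day-scale of the learning sigmoid (default 0.35).
#' @param trial_sd Log-scale SD of the per-trial gain (default 0.2).
#' @param sample_sd Additive per-sample noise SD (default 0.03).
#' @param fs Sampling rate (Hz, default 30).
#' @return Data frame (long format) with columns `trial_id`, `cue`, `day`,
#'   `t_s`, `delta_intensity`, `valid`.
#' @export
generate_orofacial <- function(days = 14L, trials_per_day = 20L,
                               learning_day = c(air_puff = 3, odor = 3,
                                                tone = 7, light = 7),
                               seed,
                               spontaneous_level = 0.05,
                               cue_amplitude = 0.3,
                               taste_amplitude = 0.5,
                               sigmoid_scale = 0.35,
                               trial_sd = 0.2,
                               sample_sd = 0.03,
                               fs = 30) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(all(learning_day >= 1), all(learning_day <= days))
  set.seed(as.integer(seed))
  t_s <- seq(-1, 3.7, by = 1 / fs)
  in_cue <- t_s >= 0 & t_s < 2
  in_taste <- t_s >= 2.5 & t_s <= 3.7
  out <- vector("list", length(learning_day) * days * trials_per_day)
  idx <- 0L
  trial_id <- 0L
  for (cue in names(learning_day)) {
    L <- learning_day[[cue]]
    for (d in seq_len(days)) {
      cr <- cue_amplitude * stats::plogis((d - L) / sigmoid_scale)
      level <- spontaneous_level +
        cr * in_cue + taste_amplitude * in_taste
      for (tr in seq_len(trials_per_day)) {
        trial_id <- trial_id + 1L
        g <- exp(stats::rnorm(1, 0, trial_sd))
        v <- pmax(0, g * level + stats::rnorm(length(t_s), 0, sample_sd))
        idx <- idx + 1L
        out[[idx]] <- data.frame(
          trial_id = trial_id, cue = cue, day = d, t_s = t_s,
          delta_intensity = v, valid = TRUE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Conditioning analysis: epoch ANOVA and first learned day per cue
#'
#' Computes per-trial epoch means, excludes invalid trials and trials in
#' which the mouth was already in motion (spontaneous mean above 3x the
#' session median), then per cue: a two-factor ANOVA (day x epoch) on
#' trial-level values, and a Tukey HSD on the day factor within the cue
#' epoch. The first learned day is the earliest day whose cue-epoch mean
#' exceeds day 1 with Tukey-corrected p < 0.05.
#'
#' @param traces Long-format data frame as from [generate_orofacial()]
#'   (columns `trial_id`, `cue`, `day`, `t_s`, `delta_intensity`, `valid`).
#' @param alpha Significance level (default 0.05).
#' @param motion_factor Exclusion threshold multiplier (default 3).
#' @return Named list per cue with `first_learned_day` (NA when no day is
#'   significant), `anova` (the day x epoch ANOVA table), `tukey` (day
#'   contrasts vs day 1 in the cue epoch) and `n_excluded`.
#' @export
learning_analysis <- function(traces, alpha = 0.05, motion_factor = 3) {
  req <- c("trial_id", "cue", "day", "t_s", "delta_intensity", "valid")
  missing_c <- setdiff(req, names(traces))
  if (length(missing_c))
    stop("traces is missing column(s): ", paste(missing_c, collapse = ", "))
  days_present <- sort(unique(traces$day))
  gaps <- setdiff(seq(min(days_present), max(days_present)), days_present)
  if (length(gaps))
    stop("missing day(s): ", paste(gaps, collapse = ", "))

  # per-trial epoch means
  per_trial <- do.call(rbind, lapply(
    split(traces, traces$trial_id), function(d) {
      es <- epoch_stats(d$t_s, d$delta_intensity)
      data.frame(trial_id = d$trial_id[1], cue = d$cue[1], day = d$day[1],
                 valid = all(d$valid),
                 spontaneous = es$spontaneous, cue_epoch = es$cue,
                 taste = es$taste)
    }))
  med_spont <- stats::median(per_trial$spontaneous)
  moving <- per_trial$spontaneous > motion_factor * med_spont
  excluded <- !per_trial$valid | moving
  if (any(excluded))
    message(sum(excluded), " trial(s) excluded (invalid or mouth already ",
            "in motion)")
  per_trial <- per_trial[!excluded, ]

  out <- list()
  for (cue in unique(per_trial$cue)) {
    d <- per_trial[per_trial$cue == cue, ]
    long <- data.frame(
      value = c(d$spontaneous, d$cue_epoch, d$taste),
      epoch = factor(rep(c("spontaneous", "cue", "taste"), each = nrow(d))),
      day = factor(rep(d$day, 3)))
    fit2 <- stats::lm(value ~ day * epoch, data = long)
    a2 <- car::Anova(fit2, type = 2)
    cue_fit <- stats::aov(cue_epoch ~ factor(day), data = d)
    tk <- stats::TukeyHSD(cue_fit)[["factor(day)"]]
    vs1 <- tk[grepl("-1$", rownames(tk)), , drop = FALSE]
    day_of <- as.integer(sub("-1$", "", rownames(vs1)))
    sig <- vs1[, "diff"] > 0 & vs1[, "p adj"] < alpha
    first <- if (any(sig)) min(day_of[sig]) else NA_integer_
    out[[cue]] <- list(first_learned_day = first, anova = a2,
                       tukey = vs1, n_excluded = sum(excluded))
  }
  out
}
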