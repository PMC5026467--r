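#' Stimulus label sets
#'
#' The eight stimuli used throughout the pipeline: four tastants delivered
#' intraorally and four cross-modal (non-gustatory) stimuli. Trained-animal
#' sessions may additionally contain `expected_sucrose` trials, i.e. sucrose
#' deliveries preceded by a conditioned cue.
#'
#' @format Character vectors of stimulus labels.
#' @name stimulus_sets
NULL

#' @rdname stimulus_sets
#' @export
TASTE_STIMULI <- c("sucrose", "NaCl", "citric_acid", "quinine")

#' @rdname stimulus_sets
#' @export
CROSSMODAL_STIMULI <- c("air_puff", "odor", "tone", "light")

#' @rdname stimulus_sets
#' @export
ALL_STIMULI <- c(TASTE_STIMULI, CROSSMODAL_STIMULI, "expected_sucrose")

#' Analysis windows and binning parameters
#'
#' Trials are aligned to stimulus onset (time 0). The baseline is the 1 s
#' preceding onset; the post-stimulus window extends 2 s for cross-modal
#' stimuli and 2.5 s for tastes. Binned analyses use 200 ms half-open bins
#' `[t, t + 0.2)`; a spike at exactly 0 s is post-stimulus. Because 2.5 s is
#' not a multiple of the bin width, binned taste analyses use the 12 complete
#' bins covering 0-2.4 s while continuous-time analyses (change points) use
#' the full 2.5 s.
#'
#' @param bin_width_s Bin width in seconds (default 0.2).
#' @return An object of class `analysis_windows`: a list with elements
#'   `baseline`, `post_crossmodal`, `post_taste` (each `c(start, end)` in
#'   seconds) and `bin_width_s`.
#' @export
analysis_windows <- function(bin_width_s = 0.2) {
  stopifnot(is.numeric(bin_width_s), length(bin_width_s) == 1L, bin_width_s > 0)
  structure(
    list(
      baseline = c(-1.0, 0.0),
      post_crossmodal = c(0.0, 2.0),
      post_taste = c(0.0, 2.5),
      bin_width_s = bin_width_s
    ),
    class = "analysis_windows"
  )
}

#' Post-stimulus window for a stimulus label
#'
#' @param stimulus Stimulus label.
#' @param windows An [analysis_windows()] object.
#' @return `c(start, end)` of the post-stimulus window in seconds.
#' @export
post_window <- function(stimulus, windows = analysis_windows()) {
  if (stimulus %in% c(TASTE_STIMULI, "expected_sucrose")) {
    windows$post_taste
  } else if (stimulus %in% CROSSMODAL_STIMULI) {
    windows$post_crossmodal
  } else {
    stop("unknown stimulus label: ", stimulus)
  }
}

#' Construct and validate a spike session
#'
#' A spike session bundles all sorted spikes of one recording session with
#' its trial and stimulus metadata. Spike times are stored relative to the
#' stimulus onset of their trial and must lie within \[-1, +3\] s.
#'
#' @param session_id Character scalar identifying the session.
#' @param condition `"untrained"` or `"trained"`.
#' @param trials Data frame with columns `trial_id` (integer), `stimulus`
#'   (one of [ALL_STIMULI]), `day` (integer >= 1) and optionally `cue_label`
#'   (the conditioned cue preceding an `expected_sucrose` delivery, `NA`
#'   otherwise).
#' @param spikes Data frame with columns `neuron_id` (character),
#'   `trial_id` (integer) and `time_s` (numeric, trial-relative seconds).
#' @param neurons Optional character vector of neuron ids; defaults to the
#'   ids appearing in `spikes`. Supplying it explicitly keeps silent neurons.
#' @return An object of class `spike_session`.
#' @export
spike_session <- function(session_id, condition, trials, spikes,
                          neurons = NULL) {
  condition <- match.arg(condition, c("untrained", "trained"))
  stopifnot(is.data.frame(trials), is.data.frame(spikes))
  req_t <- c("trial_id", "stimulus", "day")
  missing_t <- setdiff(req_t, names(trials))
  if (length(missing_t))
    stop("trials table is missing column(s): ", paste(missing_t, collapse = ", "))
  req_s <- c("neuron_id", "trial_id", "time_s")
  missing_s <- setdiff(req_s, names(spikes))
  if (length(missing_s))
    stop("spikes table is missing column(s): ", paste(missing_s, collapse = ", "))
  if (!"cue_label" %in% names(trials)) trials$cue_label <- NA_character_

  trials$trial_id <- as.integer(trials$trial_id)
  trials$stimulus <- as.character(trials$stimulus)
  trials$day <- as.integer(trials$day)
  trials$cue_label <- as.character(trials$cue_label)
  spikes$neuron_id <- as.character(spikes$neuron_id)
  spikes$trial_id <- as.integer(spikes$trial_id)
  spikes$time_s <- as.numeric(spikes$time_s)

  bad_stim <- !trials$stimulus %in% ALL_STIMULI
  if (any(bad_stim))
    stop("unknown stimulus label in trials row(s) ",
         paste(which(bad_stim), collapse = ", "), ": ",
         paste(unique(trials$stimulus[bad_stim]), collapse = ", "))
  if (anyDuplicated(trials$trial_id))
    stop("duplicate trial_id in trials table")
  if (condition == "untrained" && any(trials$stimulus == "expected_sucrose"))
    stop("expected_sucrose trials are only allowed in the trained condition")

  orphan <- !spikes$trial_id %in% trials$trial_id
  if (any(orphan))
    stop("spike row(s) ", paste(utils::head(which(orphan), 5L), collapse = ", "),
         " reference unknown trial_id(s): ",
         paste(unique(spikes$trial_id[orphan]), collapse = ", "))
  out_of_range <- spikes$time_s < -1.0 | spikes$time_s > 3.0
  if (any(out_of_range))
    stop("spike time outside [-1, 3] s at row(s) ",
         paste(utils::head(which(out_of_range), 5L), collapse = ", "))

  if (is.null(neurons)) neurons <- sort(unique(spikes$neuron_id))
  neurons <- as.character(neurons)
  if (!all(spikes$neuron_id %in% neurons))
    stop("spikes reference neuron_id(s) not listed in `neurons`")

  # canonical row order so writers are deterministic
  trials <- trials[order(trials$trial_id),
                   c("trial_id", "stimulus", "day", "cue_label"), drop = FALSE]
  spikes <- spikes[order(spikes$neuron_id, spikes$trial_id, spikes$time_s), ,
                   drop = FALSE]
  rownames(trials) <- rownames(spikes) <- NULL

  structure(
    list(session_id = as.character(session_id), condition = condition,
         neurons = neurons, trials = trials, spikes = spikes),
    class = "spike_session"
  )
}

#' @export
print.spike_session <- function(x, ...) {
  cat("<spike_session> ", x$session_id, " (", x$condition, ")\n", sep = "")
  cat("  neurons: ", length(x$neurons),
      "  trials: ", nrow(x$trials),
      "  spikes: ", nrow(x$spikes), "\n", sep = "")
  tab <- table(x$trials$stimulus)
  cat("  trials per stimulus: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read a spike session from tab-separated files
#'
#' Expects `spikes.tsv` (`neuron_id`, `trial_id`, `time_s`) and `trials.tsv`
#' (`trial_id`, `stimulus`, `day`, `condition`, `cue_label`) in `path`,
#' UTF-8 with LF endings and '.' decimal separator.
#'
#' @param path Directory containing `spikes.tsv` and `trials.tsv`.
#' @param session_id Session identifier; defaults to the directory name.
#' @return A [spike_session()].
#' @export
read_session <- function(path, session_id = basename(normalizePath(path))) {
  sp_file <- file.path(path, "spikes.tsv")
  tr_file <- file.path(path, "trials.tsv")
  for (f in c(sp_file, tr_file))
    if (!file.exists(f)) stop("file not found: ", f)
  trials <- utils::read.delim(tr_file, colClasses = c(
    trial_id = "integer", stimulus = "character", day = "integer",
    condition = "character", cue_label = "character"))
  spikes <- utils::read.delim(sp_file, colClasses = c(
    neuron_id = "character", trial_id = "integer", time_s = "numeric"))
  cond <- unique(trials$condition)
  if (length(cond) != 1L)
    stop("trials.tsv must contain a single condition, found: ",
         paste(cond, collapse = ", "))
  trials$cue_label[trials$cue_label == ""] <- NA_character_
  spike_session(session_id, cond, trials, spikes)
}

#' Write a spike session to tab-separated files
#'
#' Emits `spikes.tsv` and `trials.tsv` in the canonical dialect
#' (deterministic row order, LF endings) so that
#' `write_session()` then [read_session()] round-trips losslessly.
#'
#' @param session A [spike_session()].
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "spike_session"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  tr <- session$trials
  tr$condition <- session$condition
  tr <- tr[, c("trial_id", "stimulus", "day", "condition", "cue_label")]
  tr$cue_label[is.na(tr$cue_label)] <- ""
  sp <- session$spikes
  sp$time_s <- formatC(sp$time_s, format = "f", digits = 6)
  utils::write.table(tr, file.path(path, "trials.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, eol = "\n")
  utils::write.table(sp, file.path(path, "spikes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Extract trial ids for a stimulus
#' @param session A [spike_session()].
#' @param stimulus Stimulus label.
#' @return Integer vector of trial ids, ordered.
#' @export
stimulus_trials <- function(session, stimulus) {
  ids <- session$trials$trial_id[session$trials$stimulus == stimulus]
  sort(ids)
}

#' Pooled trial-relative spike times for one neuron and stimulus
#'
#' @inheritParams stimulus_trials
#' @param neuron Neuron id.
#' @return Numeric vector of spike times pooled across the stimulus' trials,
#'   sorted, with attribute `n_trials`.
#' @export
pooled_spike_times <- function(session, neuron, stimulus) {
  ids <- stimulus_trials(session, stimulus)
  if (!length(ids)) stop("no trials for stimulus ", stimulus)
  sp <- session$spikes
  keep <- sp$neuron_id == neuron & sp$trial_id %in% ids
  times <- sort(sp$time_s[keep])
  attr(times, "n_trials") <- length(ids)
  times
}

#' Bin spikes into a peristimulus time histogram
#'
#' Counts spikes of one neuron in 200 ms half-open bins `[t, t + 0.2)` for
#' every trial of a stimulus and converts to firing rate (Hz). The bin grid
#' starts at the baseline onset (-1 s) and covers the complete bins inside
#' the stimulus' post window.
#'
#' @param session A [spike_session()].
#' @param neuron Neuron id present in the session.
#' @param stimulus Stimulus label present in the session's trials.
#' @param windows An [analysis_windows()] object.
#' @return Object of class `psth`: list with `neuron_id`, `stimulus`,
#'   `bin_edges_s` (length B + 1), `rate_hz` (trials x B matrix, rownames =
#'   trial ids) and `counts` (same shape, raw spike counts).
#' @export
bin_spikes <- function(session, neuron, stimulus,
                       windows = analysis_windows()) {
  if (!neuron %in% session$neurons) stop("unknown neuron: ", neuron)
  ids <- stimulus_trials(session, stimulus)
  if (!length(ids)) stop("no trials for stimulus ", stimulus)
  w <- post_window(stimulus, windows)
  bw <- windows$bin_width_s
  n_bins <- floor((w[2] - windows$baseline[1]) / bw + 1e-9)
  edges <- windows$baseline[1] + bw * (0:n_bins)
  sp <- session$spikes[session$spikes$neuron_id == neuron, ]
  counts <- matrix(0L, nrow = length(ids), ncol = n_bins,
                   dimnames = list(ids, NULL))
  for (i in seq_along(ids)) {
    tt <- sp$time_s[sp$trial_id == ids[i]]
    tt <- tt[tt >= edges[1] & tt < edges[n_bins + 1L]]
    if (length(tt)) {
      idx <- floor((tt - edges[1]) / bw) + 1L
      tab <- tabulate(idx, nbins = n_bins)
      counts[i, ] <- tab
    }
  }
  structure(
    list(neuron_id = neuron, stimulus = stimulus, bin_edges_s = edges,
         rate_hz = counts / bw, counts = counts),
    class = "psth"
  )
}

#' @export
print.psth <- function(x, ...) {
  cat("<psth> neuron ", x$neuron_id, ", ", x$stimulus, ": ",
      nrow(x$counts), " trials x ", ncol(x$counts), " bins (",
      format(x$bin_edges_s[1]), " to ",
      format(x$bin_edges_s[length(x$bin_edges_s)]), " s)\n", sep = "")
  invisible(x)
}
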