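#' Responsiveness matrix from change-point profiles
#'
#' @param profiles Data frame from [response_profiles()].
#' @return Logical matrix neurons x stimuli.
#' @export
response_matrix <- function(profiles) {
  neurons <- unique(profiles$neuron_id)
  stimuli <- unique(profiles$stimulus)
  m <- matrix(FALSE, length(neurons), length(stimuli),
              dimnames = list(neurons, stimuli))
  m[cbind(match(profiles$neuron_id, neurons),
          match(profiles$stimulus, stimuli))] <- profiles$responsive
  m
}

#' Mean post-stimulus firing rates for the sharpness index
#'
#' Mean rate over the 2.5 s following onset for each of the 8 stimuli
#' (tastes and cross-modal alike), per neuron.
#'
#' @param session A [spike_session()].
#' @param neuron Neuron id.
#' @param stimuli Stimulus labels (default the 8 tastes + cues).
#' @param epoch_s Averaging epoch after onset (default 2.5 s).
#' @return Named numeric vector of mean rates (Hz).
#' @export
mean_post_rates <- function(session, neuron,
                            stimuli = c(TASTE_STIMULI, CROSSMODAL_STIMULI),
                            epoch_s = 2.5) {
  vapply(stimuli, function(st) {
    tt <- pooled_spike_times(session, neuron, st)
    sum(tt > 0 & tt <= epoch_s) / (attr(tt, "n_trials") * epoch_s)
  }, numeric(1))
}

#' Per-neuron session analysis
#'
#' Runs the change-point responsiveness analysis for every neuron and
#' stimulus, the taste-selectivity ANOVA for neurons responsive to at
#' least one taste, and the sharpness index.
#'
#' @param session A [spike_session()].
#' @param alpha Significance level for change points and the ANOVA.
#' @param windows An [analysis_windows()] object.
#' @return List with `profiles` (data frame), `responsive` (logical
#'   matrix), `taste_selective` (logical per neuron), `sharpness` (numeric
#'   per neuron, NA when all rates are zero) and `convergence`
#'   ([convergence_counts()] output).
#' @export
analyze_session <- function(session, alpha = 0.05,
                            windows = analysis_windows()) {
  profiles <- response_profiles(session, alpha = alpha, windows = windows)
  m <- response_matrix(profiles)
  neurons <- rownames(m)
  tastes <- intersect(TASTE_STIMULI, colnames(m))
  taste_resp <- rowSums(m[, tastes, drop = FALSE]) >= 1
  selective <- logical(length(neurons))
  names(selective) <- neurons
  for (nr in neurons[taste_resp]) {
    psths <- lapply(tastes, function(st)
      bin_spikes(session, nr, st, windows))
    res <- tryCatch(taste_selective(psths, alpha = alpha, windows = windows),
                    error = function(e) list(selective = FALSE))
    selective[nr] <- isTRUE(res$selective)
  }
  sharp <- vapply(neurons, function(nr) {
    r <- mean_post_rates(session, nr)
    if (max(r) == 0) NA_real_ else sharpness(r)
  }, numeric(1))
  list(profiles = profiles, responsive = m, taste_selective = selective,
       sharpness = sharp,
       convergence = convergence_counts(m, selective))
}

#' Pipeline configuration
#'
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param untrained,trained [generator_config()]s for the two conditions
#'   (defaults: the study's population parameters with seeds derived from
#'   `seed`).
#' @param n_boot_decode Bootstrap runs for the decoding band.
#' @param n_sims_independence Simulations for the convergence bootstrap.
#' @param out_dir Optional directory; when set, tables are written as TSV.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            untrained = NULL, trained = NULL,
                            n_boot_decode = 100L,
                            n_sims_independence = 10000L,
                            out_dir = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  seed <- as.integer(seed)
  if (is.null(untrained))
    untrained <- generator_config("untrained", seed = seed + 1L)
  if (is.null(trained))
    trained <- generator_config("trained", seed = seed + 2L)
  structure(list(seed = seed, untrained = untrained, trained = trained,
                 n_boot_decode = as.integer(n_boot_decode),
                 n_sims_independence = as.integer(n_sims_independence),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on synthetic sessions
#'
#' Generates one session per condition, runs change-point responsiveness,
#' taste selectivity, convergence counting with the independence
#' bootstrap, decoding with bootstrap bands, the cue-similarity time
#' course, the orofacial learning analysis, and the condition-comparison
#' proportion tests. Identical config and seed give identical output.
#'
#' @param config A [pipeline_config()].
#' @return List of stage outputs (see names); when `config$out_dir` is
#'   set the main tables are also written as TSV files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  conditions <- c("untrained", "trained")
  gen <- list(untrained = generate_session(config$untrained),
              trained = generate_session(config$trained))
  analysis <- lapply(gen, function(g) analyze_session(g$session))

  # responder fractions per stimulus and condition + comparison tests
  resp_tab <- do.call(rbind, lapply(conditions, function(cd) {
    m <- analysis[[cd]]$responsive
    data.frame(condition = cd, stimulus = colnames(m),
               n_responsive = colSums(m), n_neurons = nrow(m),
               fraction = colMeans(m), row.names = NULL)
  }))
  comparison <- do.call(rbind, lapply(CROSSMODAL_STIMULI, function(st) {
    u <- resp_tab[resp_tab$condition == "untrained" &
                    resp_tab$stimulus == st, ]
    t <- resp_tab[resp_tab$condition == "trained" &
                    resp_tab$stimulus == st, ]
    r <- prop_chi2(u$n_responsive, u$n_neurons, t$n_responsive, t$n_neurons)
    data.frame(stimulus = st, frac_untrained = u$fraction,
               frac_trained = t$fraction, chi2 = r$chi2,
               p_value = r$p_value)
  }))

  # sign / modulation summary for cue responses
  sign_tab <- do.call(rbind, lapply(conditions, function(cd) {
    p <- analysis[[cd]]$profiles
    p <- p[p$stimulus %in% CROSSMODAL_STIMULI & p$responsive, ]
    data.frame(condition = cd,
               n_responses = nrow(p),
               n_excited = sum(p$sign == "excited"),
               n_inhibited = sum(p$sign == "inhibited"),
               mean_modulations = mean(p$n_modulations))
  }))

  # convergence bootstrap per condition (neurons responding to >= 2 cues)
  set.seed(config$seed + 10L)
  independence <- lapply(conditions, function(cd) {
    m <- analysis[[cd]]$responsive[, CROSSMODAL_STIMULI]
    obs <- sum(rowSums(m) >= 2)
    independence_bootstrap(
      n_neurons = nrow(m), probs = colMeans(m), observed = obs,
      statistic = "multi_cue", n_sims = config$n_sims_independence)
  })
  names(independence) <- conditions

  # decoding
  decoding <- lapply(conditions, function(cd) {
    pop <- build_pseudopopulation(gen[[cd]]$session,
                                  seed = config$seed + 20L)
    set.seed(config$seed + 21L)
    tc <- decode_timecourse(pop)
    band <- bootstrap_band(pop, n_boot = config$n_boot_decode,
                           seed = config$seed + 22L)
    list(timecourse = tc, band = band, hits = hits_analysis(tc))
  })
  names(decoding) <- conditions

  # cue-similarity time course over cue-responsive neurons
  similarity <- lapply(conditions, function(cd) {
    m <- analysis[[cd]]$responsive[, CROSSMODAL_STIMULI]
    keep <- rownames(m)[rowSums(m) >= 1]
    if (length(keep) < 5) return(NULL)
    sess <- gen[[cd]]$session
    profs <- lapply(keep, function(nr)
      lapply(CROSSMODAL_STIMULI, function(st)
        auroc_profile(bin_spikes(sess, nr, st))))
    similarity_timecourse(profs, seed = config$seed + 30L)
  })
  names(similarity) <- conditions

  # behavior
  traces <- generate_orofacial(seed = config$seed + 40L)
  learning <- learning_analysis(traces)

  printed <- reproduce_printed_stats()

  out <- list(responsiveness = resp_tab, comparison = comparison,
              sign_modulations = sign_tab, independence = independence,
              decoding = decoding, similarity = similarity,
              learning = learning, printed_stats = printed,
              analysis = analysis)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(d, f) utils::write.table(
      d, file.path(config$out_dir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    wt(resp_tab, "responsiveness.tsv")
    wt(comparison, "comparison.tsv")
    wt(sign_tab, "sign_modulations.tsv")
    wt(printed, "printed_stats.tsv")
    for (cd in conditions) {
      tc <- decoding[[cd]]$timecourse
      wt(data.frame(bin_start_s = tc$bin_start_s, accuracy = tc$accuracy,
                    lo = decoding[[cd]]$band$lo,
                    hi = decoding[[cd]]$band$hi,
                    significant = decoding[[cd]]$band$significant),
         paste0("decoding_", cd, ".tsv"))
      if (!is.null(similarity[[cd]]))
        wt(similarity[[cd]], paste0("similarity_", cd, ".tsv"))
    }
  }
  out
}
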