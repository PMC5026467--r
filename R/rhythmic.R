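#' Flag units with 6-10 Hz rhythmic firing
#'
#' Single units whose spike-train power spectrum is dominated by a peak in
#' the 6-10 Hz band are treated as rhythmic ("somatosensory"-like, e.g.
#' whisking- or licking-locked) and excluded from stimulus analyses. The
#' spike train is binned at 10 ms and a Welch-type averaged periodogram
#' (Hann-windowed segments, 50% overlap) is computed; the unit is flagged
#' when the spectral maximum over 1-50 Hz falls inside \[6, 10\] Hz and
#' exceeds `peak_ratio` times the median power over 1-50 Hz.
#'
#' With fewer than `min_spikes` spikes and less than `min_duration_s` of
#' spiking the spectrum is too poorly estimated to decide: the unit is
#' retained (`rhythmic = NA`) with a warning.
#'
#' @param spike_times Numeric vector of spike times (s) on a common clock,
#'   e.g. concatenated across trials.
#' @param band Frequency band searched for the peak (Hz), default `c(6, 10)`.
#' @param search Band over which the maximum and median are taken, default
#'   `c(1, 50)` Hz.
#' @param peak_ratio Peak-to-median power ratio required to flag, default 2.
#' @param bin_s Spike-count bin width for the spectral estimate (s).
#' @param min_spikes,min_duration_s Minimum evidence required for a verdict.
#' @return List with `rhythmic` (TRUE/FALSE/NA), `peak_frequency_hz` and the
#'   `peak_ratio` observed.
#' @export
flag_rhythmic_unit <- function(spike_times, band = c(6, 10),
                               search = c(1, 50), peak_ratio = 2,
                               bin_s = 0.01, min_spikes = 500,
                               min_duration_s = 60) {
  spike_times <- sort(as.numeric(spike_times))
  dur <- if (length(spike_times)) diff(range(spike_times)) else 0
  if (length(spike_times) < min_spikes && dur < min_duration_s) {
    warning("too few spikes for a spectral verdict; unit retained")
    return(list(rhythmic = NA, peak_frequency_hz = NA_real_,
                peak_ratio = NA_real_))
  }
  t0 <- spike_times[1]
  n <- ceiling((dur + bin_s) / bin_s)
  x <- tabulate(pmin(floor((spike_times - t0) / bin_s) + 1L, n), nbins = n)
  spec <- welch_spectrum(x - mean(x), fs = 1 / bin_s)
  in_search <- spec$freq >= search[1] & spec$freq <= search[2]
  f <- spec$freq[in_search]
  p <- spec$power[in_search]
  i_max <- which.max(p)
  ratio <- p[i_max] / stats::median(p)
  list(
    rhythmic = f[i_max] >= band[1] && f[i_max] <= band[2] &&
      ratio >= peak_ratio,
    peak_frequency_hz = f[i_max],
    peak_ratio = ratio
  )
}

# Welch averaged periodogram: Hann window, 50% overlapping segments.
welch_spectrum <- function(x, fs, n_seg = 512L) {
  n <- length(x)
  n_seg <- min(n_seg, n)
  step <- max(1L, n_seg %/% 2L)
  starts <- seq(1L, n - n_seg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(n_seg) / (n_seg + 1)))
  norm <- sum(w^2)
  acc <- numeric(n_seg %/% 2L)
  for (s in starts) {
    seg <- x[s:(s + n_seg - 1L)]
    seg <- (seg - mean(seg)) * w
    ft <- stats::fft(seg)
    pxx <- Mod(ft[2:(n_seg %/% 2L + 1L)])^2 / (norm * fs)
    acc <- acc + pxx
  }
  list(freq = fs * seq_len(n_seg %/% 2L) / n_seg,
       power = acc / length(starts))
}
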