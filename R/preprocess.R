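#' Zero-phase band-pass filtering
#'
#' Filters every channel of every epoch with a 4th-order Butterworth
#' band-pass applied forward and backward (`signal::filtfilt`), so the net
#' response is zero-phase — phase distortion would bias the delay-embedded
#' synchronization estimates downstream.
#'
#' @param recording An [eeg_recording()].
#' @param band A [frequency_band()]; `f_hi` must be below the Nyquist
#'   frequency `fs/2`.
#' @param order Butterworth order of the one-way filter (default 4).
#' @return A filtered copy of `recording` with identical epoch shapes.
#' @examples
#' rec <- eeg_recording("s1", c("a", "b"), fs = 128,
#'                      epochs = list(matrix(rnorm(512), nrow = 2)))
#' filtered <- bandpass(rec, frequency_band("alpha", 8, 12))
#' @export
bandpass <- function(recording, band, order = 4) {
  if (!is_eeg_recording(recording)) {
    stop("`recording` must be an eeg_recording.", call. = FALSE)
  }
  if (!inherits(band, "frequency_band")) {
    stop("`band` must be a frequency_band.", call. = FALSE)
  }
  nyq <- recording$fs / 2
  if (band$f_hi >= nyq) {
    stop(sprintf(
      "Band edge f_hi = %g Hz must be below the Nyquist frequency %g Hz.",
      band$f_hi, nyq
    ), call. = FALSE)
  }
  flt <- signal::butter(order, c(band$f_lo, band$f_hi) / nyq, type = "pass")
  recording$epochs <- lapply(recording$epochs, function(ep) {
    out <- t(apply(ep, 1L, function(x) signal::filtfilt(flt, x)))
    rownames(out) <- rownames(ep)
    out
  })
  recording
}

# Welch spectral density of one series: Hann-windowed segments with 50%
# overlap, one-sided density in units^2/Hz. Returns list(freq, psd).
welch_psd <- function(x, fs, window_seconds = 2) {
  nwin <- round(window_seconds * fs)
  if (length(x) < nwin) {
    stop(sprintf(
      "Series of %d samples is shorter than one PSD window (%d samples).",
      length(x), nwin
    ), call. = FALSE)
  }
  step <- nwin %/% 2L
  starts <- seq(1L, length(x) - nwin + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nwin) / (nwin + 1)))  # Hann
  u <- sum(w^2)
  nfreq <- nwin %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nwin - 1L)]
    seg <- (seg - mean(seg)) * w
    spec <- abs(stats::fft(seg)[seq_len(nfreq)])^2
    acc <- acc + spec
  }
  psd <- acc / (length(starts) * fs * u)
  # one-sided: double everything except DC (and Nyquist when nwin even)
  dbl <- rep(2, nfreq)
  dbl[1] <- 1
  if (nwin %% 2L == 0L) dbl[nfreq] <- 1
  list(freq = (seq_len(nfreq) - 1L) * fs / nwin, psd = psd * dbl)
}

#' Power spectral density of a set of recordings
#'
#' Welch estimate (2-s Hann windows, 50% overlap) per channel, averaged
#' over each subject's epochs and then over subjects — the usual order for
#' cohort-level spectra. Absolute power is in signal-units^2/Hz; relative
#' power divides each channel's spectrum by its total power on the
#' frequency grid inside `band_limits`, so relative power sums to 1 per
#' channel over that grid.
#'
#' @param recordings A list of [eeg_recording()] objects (or a single one),
#'   all sharing `fs`; typically one group of a cohort.
#' @param band_limits A [frequency_band()] giving the normalization range
#'   (default broadband 0.5-45 Hz).
#' @param window_seconds Welch window length in seconds (default 2, i.e.
#'   0.5 Hz resolution).
#' @return A tibble with columns `channel`, `frequency` (Hz),
#'   `absolute_power` and `relative_power`, restricted to the grid inside
#'   `band_limits`.
#' @examples
#' rec <- eeg_recording("s1", c("a", "b"), fs = 128,
#'                      epochs = list(matrix(rnorm(512), nrow = 2)))
#' psd <- compute_psd(rec)
#' @export
compute_psd <- function(recordings, band_limits = eeg_band("broadband"),
                        window_seconds = 2) {
  if (is_eeg_recording(recordings)) recordings <- list(recordings)
  if (length(recordings) == 0L) stop("No recordings given.", call. = FALSE)
  fss <- vapply(recordings, function(r) r$fs, numeric(1))
  if (any(fss != fss[1])) {
    stop("All recordings must share the sampling frequency.", call. = FALSE)
  }
  labels <- recordings[[1]]$channel_labels
  per_subject <- lapply(recordings, function(rec) {
    per_epoch <- lapply(rec$epochs, function(ep) {
      t(apply(ep, 1L, function(x) welch_psd(x, rec$fs, window_seconds)$psd))
    })
    Reduce(`+`, per_epoch) / length(per_epoch)
  })
  mean_psd <- Reduce(`+`, per_subject) / length(per_subject)
  freq <- welch_psd(recordings[[1]]$epochs[[1]][1, ], fss[1],
                    window_seconds)$freq
  keep <- freq >= band_limits$f_lo & freq <= band_limits$f_hi
  freq <- freq[keep]
  mean_psd <- mean_psd[, keep, drop = FALSE]
  rel <- mean_psd / rowSums(mean_psd)
  tibble::tibble(
    channel = rep(labels, each = length(freq)),
    frequency = rep(freq, times = length(labels)),
    absolute_power = as.numeric(t(mean_psd)),
    relative_power = as.numeric(t(rel))
  )
}
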