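#' Synchronization-likelihood parameters
#'
#' SL measures generalized synchronization between two series from
#' coincident recurrences of their delay-embedded state vectors. Its
#' parameters are the embedding lag and dimension `m`, the Theiler window
#' `w1` excluding autocorrelated neighbours, the outer window `w2` bounding
#' the search range, and the reference recurrence probability `p_ref` to
#' which each reference point's critical distance is calibrated — under
#' independence SL then averages to `p_ref`.
#'
#' Defaults follow the frequency-adaptive prescription tied to the analysis
#' band: `lag = round(fs / (3 f_hi))`, `m = round(3 f_hi / f_lo) + 1` capped
#' at 16, `w1 = 2 lag (m - 1)`, `w2 = w1 + floor(10 / p_ref)`,
#' `p_ref = 0.05`. Every value can be overridden.
#'
#' @param fs Sampling frequency, Hz.
#' @param band A [frequency_band()] the data were filtered to.
#' @param lag Embedding lag in samples (>= 1).
#' @param m Embedding dimension (>= 2).
#' @param w1 Theiler window in samples.
#' @param w2 Outer window in samples, > `w1`.
#' @param p_ref Reference recurrence probability in (0, 1).
#' @return An object of class `sl_params`.
#' @examples
#' sl_params(fs = 512, band = eeg_band("broadband"))
#' @export
sl_params <- function(fs = 512, band = eeg_band("broadband"),
                      lag = NULL, m = NULL, w1 = NULL, w2 = NULL,
                      p_ref = 0.05) {
  if (is.null(lag)) lag <- max(1L, as.integer(round(fs / (3 * band$f_hi))))
  if (is.null(m)) m <- min(16L, as.integer(round(3 * band$f_hi / band$f_lo)) + 1L)
  if (is.null(w1)) w1 <- 2L * as.integer(lag) * (as.integer(m) - 1L)
  if (is.null(w2)) w2 <- as.integer(w1) + as.integer(floor(10 / p_ref))
  lag <- as.integer(lag); m <- as.integer(m)
  w1 <- as.integer(w1); w2 <- as.integer(w2)
  if (lag < 1L) stop("`lag` must be >= 1.", call. = FALSE)
  if (m < 2L) stop("`m` must be >= 2.", call. = FALSE)
  if (!(p_ref > 0 && p_ref < 1)) stop("`p_ref` must be in (0, 1).", call. = FALSE)
  if (w1 < 2L * lag * (m - 1L)) {
    stop("`w1` must be at least 2 * lag * (m - 1) to exclude autocorrelated neighbours.",
         call. = FALSE)
  }
  if (w2 <= w1) stop("`w2` must exceed `w1`.", call. = FALSE)
  structure(
    list(lag = lag, m = m, w1 = w1, w2 = w2, p_ref = p_ref),
    class = "sl_params"
  )
}

#' @export
print.sl_params <- function(x, ...) {
  cat(sprintf(
    "<sl_params> m = %d, lag = %d, w1 = %d, w2 = %d, p_ref = %g\n",
    x$m, x$lag, x$w1, x$w2, x$p_ref
  ))
  invisible(x)
}

check_epoch_length <- function(n_samples, params) {
  n_emb <- n_samples - (params$m - 1L) * params$lag
  if (n_emb < params$w2 + 1L) {
    stop(sprintf(
      paste0("Epoch of %d samples gives %d embedded vectors; need more than ",
             "w2 = %d. Use a longer epoch or smaller m/lag/w2."),
      n_samples, n_emb, params$w2
    ), call. = FALSE)
  }
  n_emb
}

#' Delay embedding of a time series
#'
#' State vector `t` has components `series[t + k * lag]`, `k = 0..m-1`;
#' there are `length(series) - (m - 1) * lag` vectors.
#'
#' @param series Numeric vector.
#' @param m Embedding dimension (`m = 1` returns the samples as 1-vectors).
#' @param lag Lag in samples.
#' @return Numeric matrix, one embedded vector per row.
#' @examples
#' embed_delay(1:5, m = 2, lag = 1)
#' @export
embed_delay <- function(series, m, lag) {
  n <- length(series)
  n_emb <- n - (m - 1L) * lag
  if (n_emb < 1L) {
    stop(sprintf(
      "Series of %d samples too short for m = %d, lag = %d; needs at least %d.",
      n, m, lag, (m - 1L) * lag + 1L
    ), call. = FALSE)
  }
  out <- matrix(0, nrow = n_emb, ncol = m)
  for (k in seq_len(m)) {
    out[, k] <- series[(1L + (k - 1L) * lag):(n_emb + (k - 1L) * lag)]
  }
  out
}

#' Per-reference critical distances
#'
#' For each embedded reference vector `i`, the distance `eps_i` below which
#' the fraction of eligible neighbours (`w1 < |i - j| <= w2`) is the nearest
#' achievable to `p_ref`. A zero-variance (constant) series yields all-zero
#' distances, reported with a saturation warning.
#'
#' @param embedded Matrix of embedded vectors (rows), as from
#'   [embed_delay()].
#' @param p_ref Target recurrence probability.
#' @param w1,w2 Theiler and outer windows, samples.
#' @return Numeric vector of critical (Euclidean) distances, one per
#'   reference row.
#' @export
critical_distance <- function(embedded, p_ref, w1, w2) {
  if (!(p_ref > 0 && p_ref < 1)) stop("`p_ref` must be in (0, 1).", call. = FALSE)
  if (w2 <= w1) stop("`w2` must exceed `w1`.", call. = FALSE)
  if (stats::var(as.numeric(embedded)) == 0) {
    warning("Embedded series has zero variance; critical distances saturate at 0.")
    return(rep(0, nrow(embedded)))
  }
  critical_distance_cpp(as.matrix(embedded), p_ref, as.integer(w1),
                        as.integer(w2))
}

new_connectivity_matrix <- function(values, channel_labels) {
  dimnames(values) <- list(channel_labels, channel_labels)
  structure(values, class = c("connectivity_matrix", "matrix", "array"))
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d channels; SL in [%.3f, %.3f]\n",
              nrow(x), min(x[upper.tri(x)]), max(x[upper.tri(x)])))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Synchronization-likelihood matrix of one epoch
#'
#' Computes SL between every channel pair: each channel is delay-embedded,
#' each reference time gets a critical distance calibrated so its recurrence
#' fraction equals `p_ref`, and SL(x, y) is the conditional probability that
#' y is recurrent where x is, averaged over reference times and symmetrized
#' by averaging the two directions. Entries lie in `[0, 1]`, the diagonal is
#' zero, and under independence SL averages to `p_ref`. Zero-variance
#' channels are flagged with a warning and assigned SL 0 against every other
#' channel.
#'
#' @param epoch Numeric channels-by-samples matrix.
#' @param params An [sl_params()].
#' @return A `connectivity_matrix`: symmetric numeric matrix with channel
#'   dimnames and attribute handling via [subject_connectivity()] for epoch
#'   averaging.
#' @export
sl_matrix <- function(epoch, params) {
  if (!is.matrix(epoch) || !is.numeric(epoch)) {
    stop("`epoch` must be a numeric channels x samples matrix.", call. = FALSE)
  }
  if (!inherits(params, "sl_params")) {
    stop("`params` must be an sl_params object.", call. = FALSE)
  }
  check_epoch_length(ncol(epoch), params)
  res <- sl_epoch_cpp(epoch, params$m, params$lag, params$w1, params$w2,
                      params$p_ref)
  if (any(res$saturated)) {
    labels <- rownames(epoch)
    if (is.null(labels)) labels <- as.character(seq_len(nrow(epoch)))
    warning("Zero-variance channel(s) saturated; SL set to 0 for: ",
            paste(labels[res$saturated], collapse = ", "))
  }
  labels <- rownames(epoch)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(epoch)))
  new_connectivity_matrix(res$W, labels)
}

#' Subject-level connectivity: epoch-averaged SL
#'
#' Computes the SL matrix of every epoch and averages them element-wise,
#' giving one functional network per subject. Averaging preserves symmetry,
#' the zero diagonal and the `[0, 1]` range.
#'
#' @param recording An [eeg_recording()].
#' @param params An [sl_params()]; defaults to the band-adaptive broadband
#'   parameters at the recording's sampling rate.
#' @return A `connectivity_matrix`.
#' @export
subject_connectivity <- function(recording,
                                 params = sl_params(fs = recording$fs)) {
  if (!is_eeg_recording(recording)) {
    stop("`recording` must be an eeg_recording.", call. = FALSE)
  }
  mats <- lapply(recording$epochs, sl_matrix, params = params)
  avg <- Reduce(`+`, lapply(mats, unclass)) / length(mats)
  new_connectivity_matrix(avg, recording$channel_labels)
}

#' Connectivity for every subject of a cohort
#'
#' Maps [subject_connectivity()] over the `recording` list-column of a
#' cohort tibble, optionally band-filtering first.
#'
#' @param cohort Tibble as returned by [generate_cohort()] (columns
#'   `subject_id`, `group`, `recording`).
#' @param params An [sl_params()].
#' @param band Optional [frequency_band()]; when given, recordings are
#'   zero-phase filtered to it before SL.
#' @return The cohort tibble with an added `connectivity` list-column.
#' @export
cohort_connectivity <- function(cohort, params = NULL, band = NULL) {
  stopifnot(is.data.frame(cohort), "recording" %in% names(cohort))
  recs <- cohort$recording
  if (!is.null(band)) recs <- purrr::map(recs, bandpass, band = band)
  if (is.null(params)) params <- sl_params(fs = recs[[1]]$fs)
  dplyr::mutate(
    cohort,
    connectivity = purrr::map(recs, subject_connectivity, params = params)
  )
}

#' Write / read a connectivity matrix as labelled CSV
#'
#' Square CSV with a header row of channel labels and the labels as the
#' first column.
#'
#' @param W A `connectivity_matrix` (or plain symmetric matrix).
#' @param path File path.
#' @return `write_connectivity_csv()` returns `path` invisibly;
#'   `read_connectivity_csv()` returns a `connectivity_matrix`.
#' @export
write_connectivity_csv <- function(W, path) {
  df <- as.data.frame(unclass(W))
  utils::write.csv(cbind(channel = rownames(W), df), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_connectivity_csv
#' @export
read_connectivity_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  labels <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  new_connectivity_matrix(unname(vals), labels)
}
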