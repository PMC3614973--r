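#' Multichannel epoched EEG recording
#'
#' Container for one subject's resting-state EEG: a set of equal-length,
#' artifact-free epochs, each a channels-by-samples numeric matrix, together
#' with channel labels and the sampling rate.
#'
#' @param subject_id Character scalar identifying the subject.
#' @param channel_labels Character vector of unique channel names.
#' @param fs Sampling frequency in Hz.
#' @param epochs List of numeric matrices, each `n_channels x n_samples`;
#'   all epochs must share dimensions.
#'
#' @return An object of class `eeg_recording`: a list with elements
#'   `subject_id`, `channel_labels`, `fs` and `epochs`.
#' @examples
#' rec <- eeg_recording("s1", c("C3", "C4"), fs = 128,
#'                      epochs = list(matrix(rnorm(256), nrow = 2)))
#' n_channels(rec)
#' @export
eeg_recording <- function(subject_id, channel_labels, fs, epochs) {
  if (!is.character(subject_id) || length(subject_id) != 1L || is.na(subject_id)) {
    stop("`subject_id` must be a single non-missing character string.", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number (Hz).", call. = FALSE)
  }
  channel_labels <- as.character(channel_labels)
  if (anyDuplicated(channel_labels)) {
    stop("`channel_labels` must be unique.", call. = FALSE)
  }
  if (!is.list(epochs) || length(epochs) == 0L) {
    stop("`epochs` must be a non-empty list of channel x sample matrices.", call. = FALSE)
  }
  dims <- vapply(epochs, function(e) {
    if (!is.matrix(e) || !is.numeric(e)) {
      stop("Every epoch must be a numeric matrix.", call. = FALSE)
    }
    dim(e)
  }, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("All epochs must share dimensions (n_channels x n_samples).", call. = FALSE)
  }
  if (dims[1, 1] != length(channel_labels)) {
    stop(sprintf(
      "Epochs have %d rows but %d channel labels were given.",
      dims[1, 1], length(channel_labels)
    ), call. = FALSE)
  }
  epochs <- lapply(epochs, function(e) {
    rownames(e) <- channel_labels
    e
  })
  structure(
    list(
      subject_id = subject_id,
      channel_labels = channel_labels,
      fs = fs,
      epochs = epochs
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> subject %s: %d channels, %d epoch(s) of %d samples @ %g Hz\n",
    x$subject_id, n_channels(x), length(x$epochs), n_samples(x), x$fs
  ))
  invisible(x)
}

#' @rdname eeg_recording
#' @param x An `eeg_recording`.
#' @export
n_channels <- function(x) length(x$channel_labels)

#' @rdname eeg_recording
#' @export
n_samples <- function(x) ncol(x$epochs[[1]])

is_eeg_recording <- function(x) inherits(x, "eeg_recording")
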