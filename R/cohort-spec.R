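#' Specification of a synthetic two-group EEG cohort
#'
#' Defines the recording geometry and the generative coupling structure of a
#' simulated case/control EEG study. Defaults mirror a routine pediatric
#' resting-state protocol: 17 scalp channels, 512 Hz sampling, four
#' artifact-free epochs of eight seconds per subject.
#'
#' Each channel is an alpha-band (~10 Hz) stochastic oscillator plus white
#' sensor noise. Dependence between channels comes from shared latent
#' drivers: a global driver mixed into every channel with amplitude
#' `base_coupling`, and a focal driver mixed into a contiguous block of
#' channels with amplitude `effect_size` in group "case" only (weight zero in
#' group "control"). `effect_size = 0` makes the two groups draws from the
#' identical generative law, which is the null cohort used for calibration.
#'
#' @param n_per_group Number of subjects per group (>= 2).
#' @param n_channels Number of EEG channels.
#' @param fs Sampling frequency, Hz.
#' @param epoch_seconds Epoch duration, seconds. `epoch_seconds * fs` must be
#'   an integer >= 64.
#' @param n_epochs Epochs per subject.
#' @param base_coupling Amplitude weight of the global shared driver, in
#'   `[0, 1)`.
#' @param effect_size Increment of the focal-driver amplitude in the case
#'   group, >= 0; `base_coupling + effect_size` must be < 1 so the mixed
#'   oscillator keeps unit variance.
#' @param noise_sd Standard deviation of additive white sensor noise, in
#'   units of the (unit-variance) oscillatory signal.
#' @param seed Integer master seed; every subject draws from a substream
#'   derived deterministically from it, so subject k's data do not change
#'   when `n_per_group` changes.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @examples
#' spec <- cohort_spec(n_per_group = 5, fs = 256, epoch_seconds = 2,
#'                     n_epochs = 2, seed = 1)
#' spec
#' @export
cohort_spec <- function(n_per_group,
                        n_channels = 17,
                        fs = 512,
                        epoch_seconds = 8,
                        n_epochs = 4,
                        base_coupling = 0.3,
                        effect_size = 0.5,
                        noise_sd = 0.5,
                        seed = 1L) {
  stop_spec <- function(msg) {
    stop("Invalid cohort_spec: ", msg, call. = FALSE)
  }
  if (!is.numeric(n_per_group) || n_per_group < 2) {
    stop_spec("`n_per_group` must be >= 2.")
  }
  if (!is.numeric(fs) || fs <= 0) stop_spec("`fs` must be > 0.")
  n_samp <- epoch_seconds * fs
  if (abs(n_samp - round(n_samp)) > 1e-8 || n_samp < 64) {
    stop_spec("`epoch_seconds * fs` must be an integer >= 64.")
  }
  if (n_channels < 2) stop_spec("`n_channels` must be >= 2.")
  if (n_epochs < 1) stop_spec("`n_epochs` must be >= 1.")
  if (base_coupling < 0 || base_coupling >= 1) {
    stop_spec("`base_coupling` must lie in [0, 1).")
  }
  if (effect_size < 0) stop_spec("`effect_size` must be >= 0.")
  if (base_coupling + effect_size >= 1) {
    stop_spec("`base_coupling + effect_size` must be < 1.")
  }
  if (noise_sd < 0) stop_spec("`noise_sd` must be >= 0.")
  structure(
    list(
      n_per_group = as.integer(n_per_group),
      n_channels = as.integer(n_channels),
      fs = fs,
      epoch_seconds = epoch_seconds,
      n_samples = as.integer(round(n_samp)),
      n_epochs = as.integer(n_epochs),
      base_coupling = base_coupling,
      effect_size = effect_size,
      noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<cohort_spec> %d + %d subjects, %d channels, %d x %g s @ %g Hz\n",
      "  base_coupling %g, effect_size %g, noise_sd %g, seed %d\n"
    ),
    x$n_per_group, x$n_per_group, x$n_channels, x$n_epochs,
    x$epoch_seconds, x$fs, x$base_coupling, x$effect_size, x$noise_sd, x$seed
  ))
  invisible(x)
}

#' Channels sharing the focal driver
#'
#' The focal driver is mixed into a fixed contiguous block comprising the
#' first third of the channels (at least two); the edges among those
#' channels form the designated subset whose coupling differs between
#' groups.
#'
#' @param spec A [cohort_spec()].
#' @return Integer vector of channel indices.
#' @export
focal_channels <- function(spec) {
  seq_len(max(2L, spec$n_channels %/% 3L))
}
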