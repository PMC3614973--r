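# Second-order autoregressive oscillator with spectral peak at f0 and pole
# radius r controlling bandwidth; innovations scaled so the stationary
# variance is 1 (variance computed from the Yule-Walker relations).
ar2_oscillator <- function(n, fs, f0 = 10, r = 0.97) {
  theta <- 2 * pi * f0 / fs
  a1 <- 2 * r * cos(theta)
  a2 <- -r^2
  # stationary variance of AR(2) with unit innovation variance
  v <- (1 - a2) / ((1 + a2) * ((1 - a2)^2 - a1^2))
  burn <- 500L
  innov <- stats::rnorm(n + burn, sd = sqrt(1 / v))
  x <- stats::filter(innov, c(a1, a2), method = "recursive")
  as.numeric(x[(burn + 1):(burn + n)])
}

# Deterministic per-subject substream: small-integer arithmetic kept far
# below 2^31 so set.seed() never overflows.
subject_seed <- function(master_seed, subject_index) {
  (abs(master_seed) %% 19997L) * 100003L + subject_index
}

generate_subject <- function(spec, subject_index, group, label_index = subject_index) {
  set.seed(subject_seed(spec$seed, subject_index))
  focal <- focal_channels(spec)
  b <- spec$base_coupling
  w <- if (identical(group, "case")) spec$effect_size else 0
  epochs <- vector("list", spec$n_epochs)
  for (e in seq_len(spec$n_epochs)) {
    driver_global <- ar2_oscillator(spec$n_samples, spec$fs)
    driver_focal <- ar2_oscillator(spec$n_samples, spec$fs)
    epoch <- matrix(0, nrow = spec$n_channels, ncol = spec$n_samples)
    for (ch in seq_len(spec$n_channels)) {
      w_ch <- if (ch %in% focal) w else 0
      private_amp <- sqrt(1 - b^2 - w_ch^2)
      epoch[ch, ] <- private_amp * ar2_oscillator(spec$n_samples, spec$fs) +
        b * driver_global +
        w_ch * driver_focal +
        spec$noise_sd * stats::rnorm(spec$n_samples)
    }
    epochs[[e]] <- epoch
  }
  eeg_recording(
    subject_id = sprintf("%s_%02d", group, label_index),
    channel_labels = paste0("ch", seq_len(spec$n_channels)),
    fs = spec$fs,
    epochs = epochs
  )
}

#' Generate a synthetic two-group EEG cohort
#'
#' Simulates `n_per_group` subjects per group under the shared-latent-driver
#' model described in [cohort_spec()]. Group "case" receives the focal
#' driver with amplitude `effect_size` on the [focal_channels()] block;
#' group "control" does not. With `effect_size = 0` the groups are
#' exchangeable.
#'
#' Generation is fully deterministic given `spec$seed`: each subject uses a
#' substream derived from the master seed and their index, so the same
#' subject is reproduced bit-for-bit when the cohort is regenerated, even
#' with a different `n_per_group`.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per subject and columns `subject_id`,
#'   `group` (factor with levels control/case) and `recording`
#'   (list-column of [eeg_recording()] objects).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_per_group = 3, fs = 128,
#'                                       epoch_seconds = 1, n_epochs = 1,
#'                                       n_channels = 4, seed = 42))
#' cohort
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    stop("`spec` must be created with cohort_spec().", call. = FALSE)
  }
  n <- spec$n_per_group
  groups <- rep(c("control", "case"), each = n)
  # case substreams live at a fixed offset so neither group's draws move
  # when n_per_group changes
  idx <- c(seq_len(n), 1000000L + seq_len(n))
  labels <- c(seq_len(n), seq_len(n))
  recs <- purrr::pmap(list(idx, groups, labels), function(i, g, l) {
    generate_subject(spec, i, g, l)
  })
  tibble::tibble(
    subject_id = purrr::map_chr(recs, "subject_id"),
    group = factor(groups, levels = c("control", "case")),
    recording = recs
  )
}
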