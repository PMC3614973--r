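#' Frequency bands
#'
#' `frequency_band()` builds a single band; `eeg_bands()` returns the
#' canonical set used throughout: broadband 0.5-45 Hz and the five clinical
#' sub-bands delta (0.5-4), theta (4-8), alpha (8-12), beta (12-30) and
#' gamma (30-45 Hz).
#'
#' @param name Band name.
#' @param f_lo,f_hi Band edges in Hz, `0 < f_lo < f_hi`.
#' @return `frequency_band()`: an object of class `frequency_band`;
#'   `eeg_bands()`: a tibble with columns `name`, `f_lo`, `f_hi`.
#' @examples
#' frequency_band("alpha", 8, 12)
#' eeg_bands()
#' @export
frequency_band <- function(name, f_lo, f_hi) {
  if (!(f_lo > 0 && f_lo < f_hi)) {
    stop("Band edges must satisfy 0 < f_lo < f_hi.", call. = FALSE)
  }
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi),
            class = "frequency_band")
}

#' @export
print.frequency_band <- function(x, ...) {
  cat(sprintf("<frequency_band> %s: %g-%g Hz\n", x$name, x$f_lo, x$f_hi))
  invisible(x)
}

#' @rdname frequency_band
#' @export
eeg_bands <- function() {
  tibble::tibble(
    name = c("broadband", "delta", "theta", "alpha", "beta", "gamma"),
    f_lo = c(0.5, 0.5, 4, 8, 12, 30),
    f_hi = c(45, 4, 8, 12, 30, 45)
  )
}

#' @rdname frequency_band
#' @param band_name One of the canonical names in `eeg_bands()`.
#' @export
eeg_band <- function(band_name) {
  bands <- eeg_bands()
  row <- bands[bands$name == band_name, ]
  if (nrow(row) != 1L) {
    stop("Unknown band '", band_name, "'; known: ",
         paste(bands$name, collapse = ", "), call. = FALSE)
  }
  frequency_band(row$name, row$f_lo, row$f_hi)
}
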