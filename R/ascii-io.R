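#' Write an epoched recording to plain-text epoch files
#'
#' One whitespace-separated text file per epoch, the interchange format used
#' when EEG review software exports selected epochs for network analysis.
#' Each file starts with a header line
#' `# subject <id> fs <Hz> channels <comma-separated labels>`, followed by
#' one row per time sample and one column per channel, numbers formatted
#' with `%.6g`.
#'
#' @param recording An [eeg_recording()].
#' @param directory Directory to write into; created if absent.
#' @return Character vector of file paths (one per epoch), invisibly
#'   ordered as the epochs.
#' @seealso [read_ascii_epoch()]
#' @export
write_ascii_epoch <- function(recording, directory) {
  if (!is_eeg_recording(recording)) {
    stop("`recording` must be an eeg_recording.", call. = FALSE)
  }
  if (length(recording$epochs) == 0L) {
    stop("Recording has no epochs; nothing to write.", call. = FALSE)
  }
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("Cannot create directory: ", directory, call. = FALSE)
  }
  header <- sprintf(
    "# subject %s fs %g channels %s",
    recording$subject_id, recording$fs,
    paste(recording$channel_labels, collapse = ",")
  )
  paths <- character(length(recording$epochs))
  for (e in seq_along(recording$epochs)) {
    path <- file.path(
      directory,
      sprintf("%s_epoch%02d.txt", recording$subject_id, e)
    )
    rows <- apply(t(recording$epochs[[e]]), 1L, function(r) {
      paste(sprintf("%.6g", r), collapse = " ")
    })
    con <- file(path, open = "wt")
    on.exit(close(con), add = TRUE)
    writeLines(c(header, rows), con)
    close(con)
    on.exit()  # already closed
    paths[e] <- path
  }
  invisible(paths)
}

parse_ascii_header <- function(line, path) {
  m <- regmatches(
    line,
    regexec("^# subject (\\S+) fs (\\S+) channels (\\S+)$", line)
  )[[1]]
  if (length(m) != 4L) {
    stop(sprintf("Malformed header in %s: %s", path, line), call. = FALSE)
  }
  list(
    subject_id = m[2],
    fs = as.numeric(m[3]),
    channel_labels = strsplit(m[4], ",", fixed = TRUE)[[1]]
  )
}

#' Read plain-text epoch files back into a recording
#'
#' Parses files written by [write_ascii_epoch()] (or any whitespace-separated
#' samples-by-channels text files with the same header). All files must
#' agree on subject, sampling rate and channel count; ragged rows or
#' non-numeric tokens raise an error naming the file and line.
#'
#' @param paths Character vector of epoch file paths, one per epoch.
#' @param channel_labels Optional channel labels overriding the header.
#' @param fs Optional sampling rate (Hz) overriding the header.
#' @return An [eeg_recording()].
#' @export
read_ascii_epoch <- function(paths, channel_labels = NULL, fs = NULL) {
  if (length(paths) == 0L) stop("No epoch files given.", call. = FALSE)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("Epoch file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  headers <- list()
  epochs <- vector("list", length(paths))
  for (k in seq_along(paths)) {
    lines <- readLines(paths[k])
    if (length(lines) < 2L) {
      stop(sprintf("File %s has no data rows.", paths[k]), call. = FALSE)
    }
    headers[[k]] <- parse_ascii_header(lines[1], paths[k])
    tokens <- strsplit(trimws(lines[-1]), "\\s+")
    ncols <- lengths(tokens)
    if (any(ncols != ncols[1])) {
      bad <- which(ncols != ncols[1])[1]
      stop(sprintf(
        "Ragged row in %s at line %d: expected %d columns, found %d.",
        paths[k], bad + 1L, ncols[1], ncols[bad]
      ), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(unlist(tokens)))
    if (anyNA(vals)) {
      flat_bad <- which(is.na(vals))[1]
      bad_line <- (flat_bad - 1L) %/% ncols[1] + 2L
      stop(sprintf(
        "Non-numeric token in %s at line %d.", paths[k], bad_line
      ), call. = FALSE)
    }
    # rows are time samples, columns channels; store channels x samples
    epochs[[k]] <- t(matrix(vals, ncol = ncols[1], byrow = TRUE))
  }
  ncols_all <- vapply(epochs, nrow, integer(1))
  if (any(ncols_all != ncols_all[1])) {
    stop("Epoch files disagree on channel count: ",
         paste(ncols_all, collapse = ", "), call. = FALSE)
  }
  hdr <- headers[[1]]
  labels <- if (is.null(channel_labels)) hdr$channel_labels else channel_labels
  if (length(labels) != ncols_all[1]) {
    stop(sprintf(
      "%d channel labels given for %d data columns.",
      length(labels), ncols_all[1]
    ), call. = FALSE)
  }
  eeg_recording(
    subject_id = hdr$subject_id,
    channel_labels = labels,
    fs = if (is.null(fs)) hdr$fs else fs,
    epochs = epochs
  )
}
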