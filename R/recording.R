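#' Multichannel EEG recording container
#'
#' A `microdyn_recording` holds a channels x samples voltage matrix in
#' microvolts together with its sampling rate, channel names, reference
#' state and an ordered processing history. All pipeline stages consume
#' and return this container.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz.
#' @param channel_names character vector, one unique name per channel.
#' @param reference reference state, `"original"` or `"average"`.
#' @param history character vector of processing steps already applied.
#' @return An object of class `microdyn_recording`.
#' @export
recording <- function(data, fs, channel_names = NULL,
                      reference = c("original", "average"),
                      history = character()) {
  reference <- match.arg(reference)
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("`data` must be a numeric matrix")
  if (any(!is.finite(data))) stop("`data` contains NaN/Inf values")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number")
  }
  if (is.null(channel_names)) {
    channel_names <- sprintf("SYN%03d", seq_len(nrow(data)))
  }
  channel_names <- as.character(channel_names)
  if (length(channel_names) != nrow(data)) {
    stop("`channel_names` length must equal the number of channels")
  }
  if (anyDuplicated(channel_names)) stop("`channel_names` must be unique")
  rownames(data) <- channel_names
  structure(
    list(data = data, fs = fs, channel_names = channel_names,
         reference = reference, history = as.character(history)),
    class = "microdyn_recording"
  )
}

#' @export
print.microdyn_recording <- function(x, ...) {
  cat(sprintf("<microdyn_recording> %d channels x %d samples @ %g Hz (%.1f s), %s reference\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs, x$reference))
  if (length(x$history)) cat("history:", paste(x$history, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.microdyn_recording <- function(x) dim(x$data)

#' Number of channels / samples in a recording
#'
#' @param rec a `microdyn_recording`.
#' @return an integer count.
#' @export
n_channels <- function(rec) nrow(rec$data)

#' @rdname n_channels
#' @export
n_samples <- function(rec) ncol(rec$data)

append_history <- function(rec, step) {
  rec$history <- c(rec$history, step)
  rec
}

assert_recording <- function(rec) {
  if (!inherits(rec, "microdyn_recording")) {
    stop("expected a `microdyn_recording` object")
  }
  invisible(rec)
}

#' Synthetic electrode montage on the unit disc
#'
#' Places `n_channels` electrodes quasi-uniformly on a unit disc with a
#' sunflower (golden-angle) layout. The y axis points anterior (front of
#' the head), x points to the subject's right. Region masks used by the
#' synthetic generator ("fronto-central", "fronto-temporal",
#' "posterior-occipital") are defined from these coordinates.
#'
#' @param n_channels number of electrodes (>= 8).
#' @return data.frame with columns `name`, `x`, `y`.
#' @export
disc_montage <- function(n_channels) {
  if (n_channels < 8) stop("`n_channels` must be at least 8")
  i <- seq_len(n_channels)
  golden <- pi * (3 - sqrt(5))
  r <- sqrt((i - 0.5) / n_channels)
  theta <- i * golden
  data.frame(
    name = sprintf("SYN%03d", i),
    x = r * cos(theta),
    y = r * sin(theta),
    stringsAsFactors = FALSE
  )
}

#' Region masks on a disc montage
#'
#' @param montage data.frame from [disc_montage()].
#' @param region one of `"fronto-central"`, `"fronto-temporal"`,
#'   `"posterior-occipital"`.
#' @return logical vector over channels.
#' @export
region_mask <- function(montage,
                        region = c("fronto-central", "fronto-temporal",
                                   "posterior-occipital")) {
  region <- match.arg(region)
  r <- sqrt(montage$x^2 + montage$y^2)
  switch(region,
    "fronto-central" = montage$y > 0.15 & r < 0.65,
    "fronto-temporal" = montage$y > 0.05 & abs(montage$x) > 0.55,
    "posterior-occipital" = montage$y < -0.55
  )
}

#' Write a recording in the plain matrix text format
#'
#' The format is a self-describing TSV: comment header lines
#' `# microdyn-recording v1`, `# fs: <Hz>`, `# reference: <state>`,
#' `# channels: <tab-separated names>`, then one row per sample with one
#' column per channel (microvolts).
#'
#' @param rec a `microdyn_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  assert_recording(rec)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# microdyn-recording v1",
    sprintf("# fs: %.10g", rec$fs),
    sprintf("# reference: %s", rec$reference),
    paste0("# channels: ", paste(rec$channel_names, collapse = "\t"))
  ), con)
  utils::write.table(t(rec$data), con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a recording from the plain matrix text format
#'
#' @param path file written by [write_recording()].
#' @return a `microdyn_recording`.
#' @export
read_recording <- function(path) {
  header <- readLines(path, n = 4L)
  if (!startsWith(header[1], "# microdyn-recording")) {
    stop("not a microdyn recording file: ", path)
  }
  fs <- as.numeric(sub("^# fs: ", "", header[2]))
  reference <- sub("^# reference: ", "", header[3])
  channels <- strsplit(sub("^# channels: ", "", header[4]), "\t")[[1]]
  body <- utils::read.table(path, sep = "\t", comment.char = "#")
  recording(t(as.matrix(body)), fs = fs, channel_names = channels,
            reference = reference)
}
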