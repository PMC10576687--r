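#' Preprocessing configuration
#'
#' @param band band-pass edges in Hz, default `c(1, 45)`.
#' @param fs_target resampling frequency in Hz, default 250.
#' @param exclude_channels channel names to drop before anything else
#'   (empty by default; for real high-density nets supply the lateral
#'   electrodes susceptible to movement artifact).
#' @param epoch_s epoch length for amplitude rejection, default 2 s.
#' @param reject_uV absolute-amplitude rejection threshold, default 100.
#' @param keep_s duration retained after rejection, default 120 s.
#' @return a `microdyn_preprocess_config`.
#' @export
preprocess_config <- function(band = c(1, 45), fs_target = 250,
                              exclude_channels = character(),
                              epoch_s = 2, reject_uV = 100, keep_s = 120) {
  if (length(band) != 2 || band[1] <= 0 || band[1] >= band[2]) {
    stop("`band` must be c(low, high) with 0 < low < high")
  }
  if (band[2] >= fs_target / 2) stop("band edge must be below fs_target/2")
  if (reject_uV <= 0) stop("`reject_uV` must be positive")
  structure(list(band = band, fs_target = fs_target,
                 exclude_channels = exclude_channels,
                 epoch_s = epoch_s, reject_uV = reject_uV, keep_s = keep_s),
            class = "microdyn_preprocess_config")
}

#' Drop named channels from a recording
#'
#' @param rec a `microdyn_recording`.
#' @param exclude character vector of channel names to remove; all must
#'   exist in the recording.
#' @return the recording with those channels removed, order preserved.
#' @export
select_channels <- function(rec, exclude) {
  assert_recording(rec)
  exclude <- as.character(exclude)
  missing <- setdiff(exclude, rec$channel_names)
  if (length(missing)) {
    stop("unknown channel name(s): ", paste(missing, collapse = ", "))
  }
  if (length(exclude) == 0) return(rec)
  keep <- !(rec$channel_names %in% exclude)
  out <- recording(rec$data[keep, , drop = FALSE], fs = rec$fs,
                   channel_names = rec$channel_names[keep],
                   reference = rec$reference, history = rec$history)
  append_history(out, sprintf("select_channels(-%d)", length(exclude)))
}

#' Average-reference a recording
#'
#' Subtracts the instantaneous mean across channels from every sample.
#' Idempotent.
#'
#' @param rec a `microdyn_recording`.
#' @return the re-referenced recording.
#' @export
average_reference <- function(rec) {
  assert_recording(rec)
  rec$data <- sweep(rec$data, 2, colMeans(rec$data))
  rec$reference <- "average"
  append_history(rec, "average_reference")
}

# Zero-phase FIR filtering: a linear-phase (symmetric) FIR applied once
# with exact group-delay compensation and anti-symmetric edge reflection.
.fir_zerophase <- function(x, b) {
  ord <- length(b) - 1L                 # even by construction
  half <- ord %/% 2L
  n <- length(x)
  left <- 2 * x[1] - x[(half + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - half)]
  y <- signal::fftfilt(b, c(left, x, right))
  y[(ord + 1):(ord + n)]
}

#' Band-pass filter, resample and average-reference
#'
#' Applies a zero-phase FIR band-pass (linear-phase kernel with exact
#' group-delay compensation) at the original sampling rate, then an
#' anti-aliased polyphase resample to the target rate, then the average
#' reference. Filtering before resampling avoids aliasing the upper band
#' edge; zero-phase filtering preserves microstate timing.
#'
#' @param rec a `microdyn_recording`.
#' @param cfg a [preprocess_config()].
#' @return the processed recording.
#' @export
filter_resample_reref <- function(rec, cfg = preprocess_config()) {
  assert_recording(rec)
  if (rec$fs < 2 * cfg$band[2]) {
    stop("band edge ", cfg$band[2], " Hz is outside Nyquist for fs = ", rec$fs)
  }
  # FIR order scaled to resolve the lower band edge, capped by the
  # recording length; forced even so the group delay is integral.
  ord <- min(max(round(3 * rec$fs / cfg$band[1]), 128), 4096,
             2 * floor((n_samples(rec) - 1) / 2))
  if (ord %% 2 == 1) ord <- ord - 1
  b <- signal::fir1(ord, cfg$band * 2 / rec$fs, type = "pass")
  filt <- t(apply(rec$data, 1, .fir_zerophase, b = b))
  rec$data <- filt
  rec <- append_history(rec, sprintf("bandpass(%g-%g Hz)", cfg$band[1], cfg$band[2]))
  if (abs(rec$fs - cfg$fs_target) > 1e-9) {
    frac <- .as_fraction(cfg$fs_target / rec$fs)
    res <- t(apply(rec$data, 1, function(x) signal::resample(x, frac[1], frac[2])))
    rec$data <- res
    rec$fs <- cfg$fs_target
    rec <- append_history(rec, sprintf("resample(%g Hz)", cfg$fs_target))
  }
  rownames(rec$data) <- rec$channel_names
  average_reference(rec)
}

.as_fraction <- function(ratio, max_den = 1000) {
  for (q in seq_len(max_den)) {
    p <- ratio * q
    if (abs(p - round(p)) < 1e-9) return(c(round(p), q))
  }
  stop("resampling ratio ", ratio, " is not a small rational number")
}

#' Amplitude-based epoch rejection and trimming
#'
#' Cuts the recording into contiguous non-overlapping epochs, rejects any
#' epoch in which any channel exceeds the absolute threshold anywhere,
#' concatenates the survivors in time order and truncates to the first
#' `keep_s` seconds.
#'
#' @param rec a `microdyn_recording`.
#' @param cfg a [preprocess_config()].
#' @return the cleaned, trimmed recording.
#' @export
reject_and_trim <- function(rec, cfg = preprocess_config()) {
  assert_recording(rec)
  win <- round(cfg$epoch_s * rec$fs)
  n_win <- floor(n_samples(rec) / win)
  if (n_win < 1) stop("recording shorter than one epoch")
  keep <- vapply(seq_len(n_win), function(w) {
    idx <- ((w - 1) * win + 1):(w * win)
    max(abs(rec$data[, idx])) <= cfg$reject_uV
  }, logical(1))
  if (!any(keep)) stop("all epochs rejected at ", cfg$reject_uV, " uV")
  idx <- unlist(lapply(which(keep), function(w) ((w - 1) * win + 1):(w * win)))
  rec$data <- rec$data[, idx, drop = FALSE]
  rec <- append_history(rec, sprintf("reject(%d/%d epochs kept)", sum(keep), n_win))
  want <- round(cfg$keep_s * rec$fs)
  if (n_samples(rec) < want) {
    warning(sprintf("only %.1f s survive rejection (requested %g s); proceeding",
                    n_samples(rec) / rec$fs, cfg$keep_s))
    want <- n_samples(rec)
  }
  rec$data <- rec$data[, seq_len(want), drop = FALSE]
  append_history(rec, sprintf("trim(%.1f s)", want / rec$fs))
}

#' Full deterministic preprocessing chain
#'
#' select -> band-pass -> resample -> average reference -> epoch
#' rejection -> trim, in that order. An optional `clean_hook` runs after
#' channel selection for users who apply external artifact cleaning; the
#' default is a no-op.
#'
#' @param rec a `microdyn_recording`.
#' @param cfg a [preprocess_config()].
#' @param clean_hook function `recording -> recording` applied after
#'   channel selection (external ocular/bad-channel cleaning slot).
#' @return the analysis-ready recording.
#' @export
preprocess <- function(rec, cfg = preprocess_config(), clean_hook = identity) {
  rec <- select_channels(rec, cfg$exclude_channels)
  rec <- clean_hook(rec)
  rec <- filter_resample_reref(rec, cfg)
  reject_and_trim(rec, cfg)
}
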