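#' Construct an epoched multichannel recording
#'
#' Container for one subject's raw signal block: a channels x samples x
#' epochs array plus its sampling rate and the number of pre-stimulus
#' samples at the head of every epoch.
#'
#' @param data numeric 3-d array, channels x samples x epochs.
#' @param fs sampling rate in Hz (> 0).
#' @param prestim_samples pre-stimulus samples to drop from each epoch.
#' @return an object of class `epoched_recording`.
#' @export
epoched_recording <- function(data, fs, prestim_samples = 0L) {
  if (length(dim(data)) != 3) {
    jdnet_stop("jdnet_bad_input", "data must be a channels x samples x epochs array")
  }
  if (dim(data)[1] < 2) jdnet_stop("jdnet_bad_input", "need at least 2 channels")
  if (dim(data)[3] < 1) jdnet_stop("jdnet_empty_input", "need at least 1 epoch")
  if (fs <= 0) jdnet_stop("jdnet_bad_input", "fs must be positive")
  structure(list(data = data, fs = fs,
                 prestim_samples = as.integer(prestim_samples)),
            class = "epoched_recording")
}

#' @export
print.epoched_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoched_recording> %d channels x %d samples x %d epochs @ %g Hz (%d pre-stimulus samples)\n",
              d[1], d[2], d[3], x$fs, x$prestim_samples))
  invisible(x)
}

#' Remove the pre-stimulus section of every epoch
#'
#' Drops the first `prestim_samples` samples of each epoch so that only
#' task-elicited activity remains (e.g. 0.2 s of a 1.40 s epoch at 256 Hz:
#' 51 of 358 samples under round-to-nearest).
#'
#' @param rec an [epoched_recording()].
#' @return the recording with shortened epochs and `prestim_samples = 0`.
#' @export
trim_prestimulus <- function(rec) {
  stopifnot(inherits(rec, "epoched_recording"))
  k <- rec$prestim_samples
  ns <- dim(rec$data)[2]
  if (k >= ns) {
    jdnet_stop("jdnet_invalid_trim", "prestim_samples (%d) >= epoch length (%d)", k, ns)
  }
  if (k == 0) return(rec)
  epoched_recording(rec$data[, (k + 1):ns, , drop = FALSE], rec$fs, 0L)
}

#' Average a recording across epochs
#'
#' Event-related average: each channel's sample i becomes the arithmetic
#' mean of sample i over the subject's epochs. Averaging attenuates
#' epoch-incoherent activity (noise, oscillations with random per-epoch
#' phase) roughly by the square root of the epoch count while preserving
#' phase-locked structure.
#'
#' @param rec an [epoched_recording()].
#' @return list with `data` (channels x samples matrix) and `fs`.
#' @export
average_epochs <- function(rec) {
  stopifnot(inherits(rec, "epoched_recording"))
  d <- rec$data
  out <- matrix(0, nrow = dim(d)[1], ncol = dim(d)[2])
  for (e in seq_len(dim(d)[3])) out <- out + d[, , e]
  list(data = out / dim(d)[3], fs = rec$fs)
}

#' Band filter specification
#'
#' The band-extraction cascade: a two-pass (zero-phase) high-pass
#' Butterworth, then a two-pass low-pass Butterworth. Orders are single-pass
#' design orders; the forward-backward application squares each stage's
#' magnitude response. Defaults (order 4 at 9 Hz, order 8 at 34 Hz) isolate
#' the band used for the network analysis; the half-power frequencies are
#' the Butterworth -3 dB points.
#'
#' @param hp_order,hp_hz high-pass design order and half-power frequency.
#' @param lp_order,lp_hz low-pass design order and half-power frequency.
#' @return a `filter_spec` list.
#' @export
filter_spec <- function(hp_order = 4L, hp_hz = 9, lp_order = 8L, lp_hz = 34) {
  if (!(hp_hz > 0 && hp_hz < lp_hz)) {
    jdnet_stop("jdnet_invalid_filter", "need 0 < hp_hz < lp_hz")
  }
  structure(list(hp_order = as.integer(hp_order), hp_hz = as.numeric(hp_hz),
                 lp_order = as.integer(lp_order), lp_hz = as.numeric(lp_hz)),
            class = "filter_spec")
}

# Forward-backward IIR filtering with odd-reflection padding of length
# 3 * filter order at each end to suppress edge transients; the pads are
# discarded. Net phase response is zero; magnitude is squared.
filtfilt_reflect <- function(b, a, x) {
  pad <- 3L * (max(length(a), length(b)) - 1L)
  n <- length(x)
  if (n <= pad) {
    jdnet_stop("jdnet_too_short", "series of length %d too short for padding length %d", n, pad)
  }
  xe <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- signal::filter(b, a, xe)
  y <- rev(signal::filter(b, a, rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Zero-phase Butterworth band extraction
#'
#' Applies the [filter_spec()] cascade to every channel of an
#' epoch-averaged recording: two-pass high-pass then two-pass low-pass
#' Butterworth IIR. Each stage is run forward and backward so the net phase
#' delay is zero (narrowband probes peak at lag 0 against the input) and
#' the amplitude response is the squared single-pass Butterworth magnitude.
#'
#' @param avg list with `data` (channels x samples) and `fs`, as returned
#'   by [average_epochs()].
#' @param spec a [filter_spec()].
#' @return list with filtered `data` and `fs`; lengths unchanged.
#' @export
bandpass_zero_phase <- function(avg, spec = filter_spec()) {
  stopifnot(is.matrix(avg$data), is.numeric(avg$fs))
  fs <- avg$fs
  if (spec$lp_hz >= fs / 2) {
    jdnet_stop("jdnet_invalid_filter", "low-pass cutoff %g Hz >= Nyquist %g Hz", spec$lp_hz, fs / 2)
  }
  hp <- signal::butter(spec$hp_order, spec$hp_hz / (fs / 2), type = "high")
  lp <- signal::butter(spec$lp_order, spec$lp_hz / (fs / 2), type = "low")
  out <- t(apply(avg$data, 1, function(u) {
    filtfilt_reflect(lp$b, lp$a, filtfilt_reflect(hp$b, hp$a, u))
  }))
  list(data = out, fs = fs)
}

#' Rescale a channel to the unit interval
#'
#' Affine map `(u - min(u)) / (max(u) - min(u))`: the channel's minimum
#' maps to 0 and its maximum to 1, removing per-channel gain and offset
#' before state-space embedding.
#'
#' @param u numeric vector with `max(u) > min(u)`.
#' @return numeric vector in [0, 1].
#' @export
rescale_channel <- function(u) {
  lo <- min(u)
  hi <- max(u)
  if (!(hi > lo)) {
    jdnet_stop("jdnet_degenerate_channel", "constant channel cannot be rescaled (min == max)")
  }
  (u - lo) / (hi - lo)
}

#' Full per-subject preprocessing
#'
#' Composes the preprocessing chain in its stated order: drop the
#' pre-stimulus section, average across epochs, extract the band with the
#' zero-phase Butterworth cascade, rescale each channel to [0, 1].
#'
#' @param rec an [epoched_recording()].
#' @param spec a [filter_spec()].
#' @return list with `data` (channels x samples matrix, every channel in
#'   [0, 1]) and `fs`; ready for [coupling_matrix()].
#' @export
preprocess_subject <- function(rec, spec = filter_spec()) {
  avg <- average_epochs(trim_prestimulus(rec))
  spans <- apply(avg$data, 1, function(u) diff(range(u)))
  if (any(spans == 0)) {
    jdnet_stop("jdnet_degenerate_channel", "channel %d is constant after epoch averaging",
               which(spans == 0)[1])
  }
  flt <- bandpass_zero_phase(avg, spec)
  for (c in seq_len(nrow(flt$data))) {
    u <- flt$data[c, ]
    if (!(max(u) > min(u))) {
      jdnet_stop("jdnet_degenerate_channel", "channel %d is constant after filtering", c)
    }
    flt$data[c, ] <- rescale_channel(u)
  }
  flt
}
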