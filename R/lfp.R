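#' Multichannel LFP recording
#'
#' Container for a multichannel local field potential time series. Samples
#' are stored channels x time so that a channel is a contiguous row.
#'
#' @param samples Numeric matrix, channels x time, in voltage units
#'   (arbitrary but consistent).
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param channel_ids Integer or character ids, one per row; must be unique.
#'   Defaults to \code{1:nrow(samples)}.
#' @param t0 Time of the first sample in seconds (default 0).
#' @return An object of class \code{lfp_recording}.
#' @export
lfp_recording <- function(samples, sample_rate, channel_ids = NULL, t0 = 0) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1L)
  stopifnot(is.matrix(samples), is.numeric(samples),
            is.numeric(sample_rate), length(sample_rate) == 1L,
            sample_rate > 0)
  if (is.null(channel_ids)) channel_ids <- seq_len(nrow(samples))
  if (length(channel_ids) != nrow(samples))
    stop("channel_ids must have one entry per channel")
  if (anyDuplicated(channel_ids))
    stop("channel_ids must be unique")
  structure(list(samples = samples, sample_rate = sample_rate,
                 channel_ids = channel_ids, t0 = t0),
            class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf(
    "<lfp_recording> %d channel(s), %d samples at %.4g Hz (%.1f s), t0 = %g s\n",
    nrow(x$samples), ncol(x$samples), x$sample_rate,
    ncol(x$samples) / x$sample_rate, x$t0))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An \code{lfp_recording}.
#' @return Length in seconds.
#' @export
lfp_duration <- function(rec) ncol(rec$samples) / rec$sample_rate

# Resolve a channel selection against the recording. `channels = NULL` means
# the deep-channel default: ids 13..16 when present, otherwise all channels.
resolve_channels <- function(rec, channels = NULL) {
  ids <- rec$channel_ids
  if (is.null(channels)) {
    deep <- intersect(13:16, ids)
    channels <- if (length(deep) > 0) deep else ids
  }
  idx <- match(channels, ids)
  if (anyNA(idx))
    stop("requested channel(s) not present: ",
         paste(channels[is.na(idx)], collapse = ", "))
  if (length(idx) == 0L) stop("empty channel subset")
  idx
}

#' Ground-truth state labels for a simulated recording
#'
#' @param intervals Data frame with columns \code{start_s}, \code{end_s},
#'   \code{state}; intervals must be contiguous, non-overlapping and cover
#'   the full duration, with alternating states.
#' @param sample_rate LFP sampling rate the per-sample track is aligned to.
#' @param n_samples Number of LFP samples the track must cover.
#' @return An object of class \code{ground_truth} with elements
#'   \code{intervals} and \code{labels} (per-sample character track).
#' @export
ground_truth <- function(intervals, sample_rate, n_samples) {
  stopifnot(is.data.frame(intervals),
            all(c("start_s", "end_s", "state") %in% names(intervals)))
  if (nrow(intervals) > 1L) {
    if (any(abs(intervals$end_s[-nrow(intervals)] - intervals$start_s[-1]) > 1e-9))
      stop("ground-truth intervals must be contiguous")
    if (any(intervals$state[-1] == intervals$state[-nrow(intervals)]))
      stop("ground-truth states must alternate")
  }
  if (any(intervals$end_s <= intervals$start_s))
    stop("intervals must have positive duration")
  t <- (seq_len(n_samples) - 1L) / sample_rate
  labels <- state_at_time(intervals, t)
  structure(list(intervals = intervals, labels = labels,
                 sample_rate = sample_rate),
            class = "ground_truth")
}

#' Look up the reference state at given times
#'
#' @param truth A \code{ground_truth} object or its intervals data frame.
#' @param times Numeric vector of times in seconds.
#' @return Character vector of states (NA outside the covered span).
#' @export
state_at_time <- function(truth, times) {
  iv <- if (inherits(truth, "ground_truth")) truth$intervals else truth
  idx <- findInterval(times, iv$start_s)
  out <- rep(NA_character_, length(times))
  ok <- idx >= 1L & times < iv$end_s[pmax(idx, 1L)] + 1e-9
  out[ok] <- iv$state[idx[ok]]
  out
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d interval(s) covering %.1f s, %d sample labels\n",
              nrow(x$intervals), max(x$intervals$end_s), length(x$labels)))
  invisible(x)
}
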