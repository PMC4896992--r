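#' Sliding-window index ranges
#'
#' Computes the sample-index ranges of a moving window over a series.
#' Consecutive starts differ by \code{round(step_s * rate)} samples; a
#' trailing partial window is dropped so the last window lies fully inside
#' the series.
#'
#' @param n_samples Number of samples available.
#' @param rate Sampling rate in Hz.
#' @param scheme A [window_scheme()].
#' @return A data frame with columns \code{start}, \code{end} (1-based,
#'   inclusive; each window spans \code{round(window_s * rate)} samples) and
#'   \code{time} (window start time in seconds, relative to the first sample).
#' @examples
#' nrow(window_slices(100 * 1000, 1000, window_scheme(10, 1)))  # 91
#' @export
window_slices <- function(n_samples, rate, scheme) {
  stopifnot(inherits(scheme, "window_scheme"), rate > 0)
  win <- round(scheme$window_s * rate)
  step <- max(1L, round(scheme$step_s * rate))
  if (n_samples < win)
    stop("series shorter than one window (", win, " samples needed, ",
         n_samples, " available)")
  starts <- seq.int(1L, n_samples - win + 1L, by = step)
  data.frame(start = starts, end = starts + win - 1L,
             time = (starts - 1L) / rate)
}

#' Band power time series from an LFP recording
#'
#' Applies an FFT to each analysis window of each selected channel and sums
#' the magnitude-squared power over the bins falling in each EEG band
#' (inclusive edges: \code{lo_hz <= f <= hi_hz}; positive and negative
#' frequency bins both counted, per-bin power \eqn{|X_k|^2 / N} so the total
#' over all bins equals the windowed signal energy). In the default
#' \code{"relative"} mode each channel's band powers are divided by that
#' channel's total power over the full analysed range (min lo to max hi,
#' 0.5--80 Hz for the default bands) before channels are averaged, making the
#' features invariant to overall amplitude scaling. \code{"raw"} mode skips
#' the normalisation (band powers then scale with the square of the signal
#' amplitude).
#'
#' @param rec An [lfp_recording()].
#' @param scheme A [window_scheme()]; default 10 s / 1 s classification.
#' @param bands Band definitions as from [eeg_bands()]; must lie below the
#'   Nyquist frequency.
#' @param channels Channel ids to use; \code{NULL} selects channels 13--16
#'   when present (the deep electrode sites), otherwise all channels.
#' @param normalisation \code{"relative"} (default) or \code{"raw"}.
#' @param taper \code{"rectangular"} (default; plain FFT) or \code{"hann"}.
#' @param fast If \code{TRUE} (default) the FFT is zero-padded to the next
#'   highly composite length when the window sample count has large prime
#'   factors, exactly as \code{stats::spectrum(fast = TRUE)} does; padding
#'   preserves the windowed energy (Parseval) and refines the bin grid
#'   without changing the spectral content. Set \code{FALSE} to transform at
#'   the exact window length regardless of cost.
#' @return An object of class \code{band_power_series}: list with
#'   \code{times} (window start seconds), \code{powers} (windows x bands
#'   matrix, band order delta, theta, alpha, beta, gamma), \code{scheme},
#'   \code{bands}, \code{channels_used}, \code{normalisation}, \code{taper}.
#' @export
band_powers <- function(rec, scheme = window_scheme(), bands = eeg_bands(),
                        channels = NULL,
                        normalisation = c("relative", "raw"),
                        taper = c("rectangular", "hann"),
                        fast = TRUE) {
  stopifnot(inherits(rec, "lfp_recording"))
  normalisation <- match.arg(normalisation)
  taper <- match.arg(taper)
  bands <- validate_bands(bands)
  nyq <- rec$sample_rate / 2
  if (any(bands$hi_hz > nyq))
    stop("band upper edge exceeds the Nyquist frequency (", nyq, " Hz)")
  ch_idx <- resolve_channels(rec, channels)
  sl <- window_slices(ncol(rec$samples), rec$sample_rate, scheme)
  win <- sl$end[1] - sl$start[1] + 1L
  nfft <- if (fast) stats::nextn(win) else win

  f <- pmin(0:(nfft - 1L), nfft - (0:(nfft - 1L))) * rec$sample_rate / nfft
  band_mask <- lapply(seq_len(nrow(bands)), function(b)
    f >= bands$lo_hz[b] & f <= bands$hi_hz[b])
  total_mask <- f >= min(bands$lo_hz) & f <= max(bands$hi_hz)
  w <- if (taper == "hann") {
    0.5 - 0.5 * cos(2 * pi * (0:(win - 1L)) / (win - 1L))
  } else rep(1, win)

  nw <- nrow(sl)
  acc <- matrix(0, nrow = nw, ncol = nrow(bands))
  for (ci in ch_idx) {
    # windows as columns, one multi-column FFT per channel
    segm <- matrix(0, nrow = nfft, ncol = nw)
    for (j in seq_len(nw))
      segm[seq_len(win), j] <- rec$samples[ci, sl$start[j]:sl$end[j]] * w
    P <- Mod(stats::mvfft(segm))^2 / nfft
    bp <- vapply(band_mask, function(m) colSums(P[m, , drop = FALSE]),
                 numeric(nw))
    if (normalisation == "relative") {
      tot <- colSums(P[total_mask, , drop = FALSE])
      tot[tot == 0] <- 1
      bp <- bp / tot
    }
    acc <- acc + bp
  }
  powers <- acc / length(ch_idx)
  colnames(powers) <- bands$name
  structure(list(times = sl$time + rec$t0, powers = powers, scheme = scheme,
                 bands = bands, channels_used = rec$channel_ids[ch_idx],
                 normalisation = normalisation, taper = taper,
                 sample_rate = rec$sample_rate),
            class = "band_power_series")
}

#' @export
print.band_power_series <- function(x, ...) {
  cat(sprintf(
    "<band_power_series> %d windows x %d bands (%g s window / %g s step, %s power, channels %s)\n",
    nrow(x$powers), ncol(x$powers), x$scheme$window_s, x$scheme$step_s,
    x$normalisation, paste(x$channels_used, collapse = ",")))
  invisible(x)
}

#' Frequency bin spacing of a window scheme
#'
#' The FFT frequency resolution of an analysis window: 1 / window length.
#' A 10 s window gives 0.1 Hz; a 4 s window gives 0.25 Hz.
#' @param scheme A [window_scheme()].
#' @return Bin spacing in Hz.
#' @export
frequency_resolution <- function(scheme) 1 / scheme$window_s
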