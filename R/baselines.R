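#' Windowed RMS amplitude of an LFP recording
#'
#' For each analysis window and channel: square every sample, take the mean,
#' take the square root; channel RMS values are then averaged. Computed on
#' the raw (broadband) LFP.
#'
#' @param rec An [lfp_recording()].
#' @param scheme A [window_scheme()]; default 10 s window, 1 s step.
#' @param channels Channel ids; \code{NULL} selects channels 13--16 when
#'   present, otherwise all.
#' @return Data frame with columns \code{time} (window start, s) and
#'   \code{rms} (voltage units), with the scheme attached.
#' @export
rms_windows <- function(rec, scheme = window_scheme(), channels = NULL) {
  stopifnot(inherits(rec, "lfp_recording"))
  ch_idx <- resolve_channels(rec, channels)
  sl <- window_slices(ncol(rec$samples), rec$sample_rate, scheme)
  nw <- nrow(sl)
  acc <- numeric(nw)
  for (ci in ch_idx) {
    x2 <- rec$samples[ci, ]^2
    cs <- c(0, cumsum(x2))
    acc <- acc + sqrt((cs[sl$end + 1L] - cs[sl$start]) / (sl$end - sl$start + 1L))
  }
  out <- data.frame(time = sl$time + rec$t0, rms = acc / length(ch_idx))
  attr(out, "scheme") <- scheme
  out
}

#' Power-threshold state classification
#'
#' The comparison baseline: the threshold is the mean of all windowed RMS
#' values of the experiment (so it is recomputed for every recording — it
#' depends on absolute power and never transfers between experiments).
#' Windows with RMS above the threshold are synchronised, below it
#' desynchronised; a window exactly at the threshold is labelled
#' synchronised. Every window receives a label. Because the threshold is a
#' plain amplitude mean, a DC offset or uneven time in the two states shifts
#' it and degrades accuracy; a degenerate all-equal input triggers a
#' warning.
#'
#' @param rms Data frame from [rms_windows()].
#' @return A \code{state_segmentation} with the threshold attached as
#'   attribute \code{"threshold"}.
#' @export
power_threshold_classify <- function(rms) {
  if (nrow(rms) == 0L) stop("empty RMS series")
  thr <- mean(rms$rms)
  if (all(rms$rms == rms$rms[1L]))
    warning("all RMS windows equal the threshold; labels follow the tie rule",
            call. = FALSE)
  labels <- ifelse(rms$rms >= thr, "synchronised", "desynchronised")
  seg <- state_segmentation(rms$time, labels, scheme = attr(rms, "scheme"),
                            method = "power_threshold")
  attr(seg, "threshold") <- thr
  seg
}
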