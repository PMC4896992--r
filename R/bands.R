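#' Classical EEG frequency bands
#'
#' Returns the five-band decomposition used throughout the package:
#' delta 0.5--3 Hz, theta 4--7 Hz, alpha 8--12 Hz, beta 13--30 Hz and
#' gamma 31--80 Hz. The small gaps between published band edges
#' (e.g. 3--4 Hz) are deliberately unassigned: a frequency bin belongs to a
#' band only if \code{lo_hz <= f <= hi_hz}.
#'
#' @return A data frame with columns \code{name}, \code{lo_hz}, \code{hi_hz},
#'   one row per band in fixed order (delta, theta, alpha, beta, gamma).
#' @examples
#' eeg_bands()
#' @export
eeg_bands <- function() {
  data.frame(
    name  = c("delta", "theta", "alpha", "beta", "gamma"),
    lo_hz = c(0.5, 4, 8, 13, 31),
    hi_hz = c(3, 7, 12, 30, 80),
    stringsAsFactors = FALSE
  )
}

#' The two cortical states recognised by the default classifier
#' @return Character vector \code{c("synchronised", "desynchronised")}.
#' @export
cortical_states <- function() c("synchronised", "desynchronised")

validate_bands <- function(bands) {
  stopifnot(is.data.frame(bands),
            all(c("name", "lo_hz", "hi_hz") %in% names(bands)))
  if (anyDuplicated(bands$name))
    stop("band names must be unique")
  if (any(bands$lo_hz <= 0) || any(bands$lo_hz >= bands$hi_hz))
    stop("bands require 0 < lo_hz < hi_hz")
  bands
}

#' Sliding-window analysis scheme
#'
#' Window length and step in seconds. The defaults mirror the two roles the
#' classifier uses: a 10 s window stepped by 1 s for classification, and a
#' finer 4 s window stepped by 0.4 s for model initialisation (both steps are
#' one tenth of the window).
#'
#' @param window_s Window length in seconds (> 0).
#' @param step_s Step between consecutive window starts in seconds
#'   (0 < step_s <= window_s).
#' @param role Either \code{"classification"} or \code{"initialisation"};
#'   informational, recorded in downstream objects.
#' @return An object of class \code{window_scheme}.
#' @examples
#' window_scheme()                    # 10 s / 1 s
#' window_scheme(4, 0.4, "initialisation")
#' @export
window_scheme <- function(window_s = 10, step_s = window_s / 10,
                          role = c("classification", "initialisation")) {
  role <- match.arg(role)
  stopifnot(is.numeric(window_s), length(window_s) == 1L, window_s > 0,
            is.numeric(step_s), length(step_s) == 1L, step_s > 0)
  if (step_s > window_s)
    stop("step_s must not exceed window_s")
  structure(list(window_s = window_s, step_s = step_s, role = role),
            class = "window_scheme")
}

#' @export
print.window_scheme <- function(x, ...) {
  cat(sprintf("<window_scheme> %g s window, %g s step (%s)\n",
              x$window_s, x$step_s, x$role))
  invisible(x)
}

#' Default initialisation scheme (4 s window, 0.4 s step)
#' @return A \code{window_scheme}.
#' @export
init_scheme <- function() window_scheme(4, 0.4, "initialisation")
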