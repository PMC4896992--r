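#' Canonical band-pair order
#'
#' The 10 unordered pairs of the five EEG bands in the fixed canonical order
#' used by every coded vector: delta-theta, delta-alpha, delta-beta,
#' delta-gamma, theta-alpha, theta-beta, theta-gamma, alpha-beta,
#' alpha-gamma, beta-gamma. Each band is compared to every other exactly
#' once (combinations, not permutations), so model files are portable.
#'
#' @param band_names Band names in canonical band order.
#' @return A 2 x 10 integer matrix of band indices, with column names
#'   \code{"<band_i>-<band_j>"}.
#' @export
band_pairs <- function(band_names = eeg_bands()$name) {
  cmb <- utils::combn(length(band_names), 2L)
  colnames(cmb) <- paste(band_names[cmb[1L, ]], band_names[cmb[2L, ]],
                         sep = "-")
  cmb
}

#' Absolute pairwise band-power differences
#'
#' Reduces the five band-power series to ten relational series: for each
#' window, the absolute difference of every unordered pair of band powers in
#' canonical order. The absolute value removes the dependence on the order
#' of subtraction, leaving a measure of how each band relates to the others
#' rather than of absolute power.
#'
#' @param bp A \code{band_power_series} (or a windows x 5 numeric matrix).
#' @return A windows x 10 nonnegative matrix, columns named by band pair.
#' @examples
#' m <- matrix(c(1, 2, 3, 4, 5), nrow = 1)  # constant band powers
#' sort(as.vector(pairwise_differences(m)))  # {1,1,1,1,2,2,2,3,3,4}
#' @export
pairwise_differences <- function(bp) {
  p <- if (inherits(bp, "band_power_series")) bp$powers else as.matrix(bp)
  if (ncol(p) != 5L)
    stop("expected 5 band-power columns, got ", ncol(p))
  pr <- band_pairs(colnames(p) %||% eeg_bands()$name)
  err <- abs(p[, pr[1L, ], drop = FALSE] - p[, pr[2L, ], drop = FALSE])
  colnames(err) <- colnames(pr)
  err
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Automatic upper and lower coding bounds
#'
#' From the pairwise-difference series of the lower-variance training state,
#' the upper bound is the mean over the ten pair series of the absolute
#' time-mean of each series, rounded to \code{rounding_precision} decimal
#' places; the lower bound is exactly half the (rounded) upper bound and is
#' not independently rounded. Bounds are set once per trained model: coded
#' vectors are only comparable under a single, fixed pair of bounds.
#'
#' @param err Windows x 10 matrix from [pairwise_differences()].
#' @param rounding_precision Decimal places for the upper bound (default 1).
#' @param source_state Name of the state the bounds were derived from
#'   (metadata).
#' @return An object of class \code{absc_bounds}: list with \code{ub},
#'   \code{lb} (= ub / 2), \code{source_state}, \code{rounding_precision}.
#' @export
compute_bounds <- function(err, rounding_precision = 1L,
                           source_state = "desynchronised") {
  err <- as.matrix(err)
  if (nrow(err) == 0L) stop("empty pairwise-difference series")
  ub <- round(mean(abs(colMeans(err))), rounding_precision)
  structure(list(ub = ub, lb = 0.5 * ub, source_state = source_state,
                 rounding_precision = as.integer(rounding_precision)),
            class = "absc_bounds")
}

#' @export
print.absc_bounds <- function(x, ...) {
  cat(sprintf("<absc_bounds> UB = %g, LB = %g (from %s state, %d dp)\n",
              x$ub, x$lb, x$source_state, x$rounding_precision))
  invisible(x)
}

#' Code pairwise differences against the bounds
#'
#' Each pairwise difference is replaced by one of three integer codes:
#' values below the lower bound become \code{codes[1]}, values between the
#' bounds inclusive become \code{codes[2]}, and values above the upper bound
#' become \code{codes[3]}. Both boundaries belong to the middle code. Any
#' integer-separated coding works identically; the default is (2, 3, 4).
#'
#' @param err Windows x 10 matrix from [pairwise_differences()].
#' @param bounds An [compute_bounds()] result.
#' @param codes Integer codes for the three cases, default \code{c(2, 3, 4)}.
#' @return Windows x 10 integer matrix of coded vectors.
#' @export
encode_vectors <- function(err, bounds, codes = c(2L, 3L, 4L)) {
  stopifnot(inherits(bounds, "absc_bounds"), length(codes) == 3L)
  err <- as.matrix(err)
  out <- matrix(codes[2L], nrow = nrow(err), ncol = ncol(err))
  out[err < bounds$lb] <- codes[1L]
  out[err > bounds$ub] <- codes[3L]
  colnames(out) <- colnames(err)
  out
}

# key a coded-vector matrix row-wise for counting
vector_keys <- function(codes) apply(codes, 1L, paste, collapse = " ")

#' Train the coded-vector state classifier
#'
#' From state-labelled training band powers, derives the coding bounds from
#' the state with the smaller pairwise-difference variance (normally the
#' desynchronised state), codes every training window, and keeps the
#' \code{l} most frequently occurring distinct coded vectors of each state
#' as that state's model vectors. The fraction of a state's training windows
#' matching one of its model vectors is reported as the coverage
#' ("variance explained") for that state; coded vectors are categorical, so
#' occurrence coverage is the operative notion of explained variance.
#'
#' @param train Named list of \code{band_power_series} (or windows x 5
#'   matrices), one element per state; names must be the state names and
#'   both states must be present.
#' @param l Number of model vectors per state (default 5).
#' @param bounds_state \code{"auto"} (default: the state whose pairwise
#'   differences have the smaller mean per-pair variance) or an explicit
#'   state name.
#' @param rounding_precision Decimal places for the upper bound (default 1).
#' @param codes Three integer codes, default \code{c(2, 3, 4)}.
#' @return An object of class \code{absc_model}: bounds, per-state model
#'   vector matrices with occurrence counts, coverage per state, and the
#'   frozen feature configuration (bands, scheme, normalisation, channels)
#'   when the input carried one.
#' @export
define_model_vectors <- function(train, l = 5L, bounds_state = "auto",
                                 rounding_precision = 1L,
                                 codes = c(2L, 3L, 4L)) {
  states <- names(train)
  if (length(states) < 2L)
    stop("training data must contain both states")
  if (!all(cortical_states() %in% states))
    stop("training data must be named with states: ",
         paste(cortical_states(), collapse = ", "))
  err <- lapply(train, pairwise_differences)

  if (identical(bounds_state, "auto")) {
    v <- vapply(err, function(e) mean(apply(e, 2L, stats::var)), numeric(1))
    bounds_state <- names(which.min(v))
  }
  if (!bounds_state %in% states) stop("unknown bounds_state")
  bounds <- compute_bounds(err[[bounds_state]], rounding_precision,
                           source_state = bounds_state)

  vectors <- list(); counts <- list(); coverage <- numeric(0)
  for (st in cortical_states()) {
    cd <- encode_vectors(err[[st]], bounds, codes)
    keys <- vector_keys(cd)
    tab <- sort(table(keys), decreasing = TRUE)
    if (length(tab) < l)
      stop(sprintf("state '%s' has only %d distinct coded vectors (l = %d)",
                   st, length(tab), l))
    top <- names(tab)[seq_len(l)]
    m <- do.call(rbind, lapply(strsplit(top, " "), as.integer))
    colnames(m) <- colnames(cd)
    vectors[[st]] <- m
    counts[[st]] <- as.integer(tab[seq_len(l)])
    coverage[st] <- sum(tab[seq_len(l)]) / length(keys)
  }

  feat <- if (inherits(train[[1L]], "band_power_series")) {
    x <- train[[1L]]
    list(bands = x$bands, scheme = x$scheme, normalisation = x$normalisation,
         taper = x$taper, channels = x$channels_used)
  } else NULL

  n_train <- vapply(err, nrow, integer(1))[cortical_states()]
  structure(list(vectors = vectors, counts = counts, l = as.integer(l),
                 bounds = bounds, codes = as.integer(codes),
                 variance_explained = coverage, n_train = n_train,
                 features = feat),
            class = "absc_model")
}

#' @export
print.absc_model <- function(x, ...) {
  cat(sprintf("<absc_model> %d model vectors per state (%d total)\n",
              x$l, 2L * x$l))
  cat(sprintf("  bounds: UB = %g, LB = %g (set in %s state)\n",
              x$bounds$ub, x$bounds$lb, x$bounds$source_state))
  for (st in names(x$vectors))
    cat(sprintf("  %s: coverage %.1f%% of %s training windows\n",
                st, 100 * x$variance_explained[st],
                if (!is.null(x$n_train)) x$n_train[st] else "the"))
  invisible(x)
}

# Per-row L1 distances of coded vectors to each state's model vectors;
# returns list(dist = windows x states matrix of per-state minima).
state_distances <- function(codes, model) {
  states <- names(model$vectors)
  d <- vapply(states, function(st) {
    M <- model$vectors[[st]]
    per_vec <- vapply(seq_len(nrow(M)), function(i)
      rowSums(abs(sweep(codes, 2L, M[i, ]))), numeric(nrow(codes)))
    if (nrow(codes) == 1L) per_vec <- matrix(per_vec, nrow = 1L)
    apply(per_vec, 1L, min)
  }, numeric(nrow(codes)))
  if (nrow(codes) == 1L) d <- matrix(d, nrow = 1L, dimnames = list(NULL, states))
  d
}

# Assign states from a windows x states distance matrix with the temporal
# tie rule: ties keep the previous label; a tie on the first window goes to
# `first_tie`.
assign_states <- function(dist, first_tie = "synchronised") {
  states <- colnames(dist)
  labels <- character(nrow(dist))
  prev <- first_tie
  for (j in seq_len(nrow(dist))) {
    best <- which(dist[j, ] == min(dist[j, ]))
    labels[j] <- if (length(best) == 1L) states[best] else
      if (prev %in% states[best]) prev else states[best[1L]]
    prev <- labels[j]
  }
  labels
}

#' Classify windows against a trained model
#'
#' Codes every window of a band-power series with the model's frozen bounds
#' and assigns each window the state of the nearest model vector in L1
#' distance (the minimum over both states' vectors). Every window receives a
#' label: there is no unclassifiable case. A distance tie between the two
#' states keeps the previous window's label (temporal continuity); a tie on
#' the very first window defaults to synchronised.
#'
#' @param bp A \code{band_power_series} produced under the model's feature
#'   configuration (checked when both carry one), or a windows x 5 matrix.
#' @param model An [define_model_vectors()] result.
#' @return A \code{state_segmentation}: data frame with columns \code{time},
#'   \code{state}, and one distance column per state
#'   (\code{dist_synchronised}, \code{dist_desynchronised}).
#' @export
classify_states <- function(bp, model) {
  stopifnot(inherits(model, "absc_model"))
  if (inherits(bp, "band_power_series") && !is.null(model$features)) {
    if (!identical(bp$normalisation, model$features$normalisation))
      stop("feature configuration mismatch: model was trained with ",
           model$features$normalisation, " power normalisation")
    if (!identical(bp$bands, model$features$bands))
      stop("feature configuration mismatch: band definitions differ")
  }
  err <- pairwise_differences(bp)
  codes <- encode_vectors(err, model$bounds, model$codes)
  dist <- state_distances(codes, model)
  labels <- assign_states(dist)
  times <- if (inherits(bp, "band_power_series")) bp$times
           else seq_len(nrow(codes)) - 1
  scheme <- if (inherits(bp, "band_power_series")) bp$scheme else NULL
  state_segmentation(times, labels, dist = dist, scheme = scheme,
                     method = "absc")
}

#' State segmentation container
#'
#' @param times Window start times in seconds, strictly increasing.
#' @param states Character state per window (NA = unclassified).
#' @param dist Optional windows x states matrix of best-match distances.
#' @param scheme Optional [window_scheme()] the windows came from.
#' @param method Classifier name (metadata).
#' @return A data frame of class \code{state_segmentation}.
#' @export
state_segmentation <- function(times, states, dist = NULL, scheme = NULL,
                               method = "manual") {
  stopifnot(length(times) == length(states))
  out <- data.frame(time = times, state = states, stringsAsFactors = FALSE)
  if (!is.null(dist)) {
    colnames(dist) <- paste0("dist_", colnames(dist))
    out <- cbind(out, as.data.frame(dist))
  }
  attr(out, "scheme") <- scheme
  attr(out, "method") <- method
  class(out) <- c("state_segmentation", "data.frame")
  out
}

#' Convert a segmentation to labelled intervals
#'
#' Maximal runs of identical labels become intervals
#' \code{[first window start, last window start + step]}.
#' @param seg A \code{state_segmentation}.
#' @param step_s Window step; taken from the attached scheme if missing.
#' @return Data frame with \code{start_s}, \code{end_s}, \code{state},
#'   \code{duration_s}, \code{n_windows}.
#' @export
segmentation_intervals <- function(seg, step_s = NULL) {
  if (is.null(step_s)) {
    sch <- attr(seg, "scheme")
    step_s <- if (!is.null(sch)) sch$step_s else
      if (nrow(seg) > 1L) stats::median(diff(seg$time)) else 1
  }
  r <- rle(seg$state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start_s = seg$time[starts],
             end_s = seg$time[ends] + step_s,
             state = r$values,
             duration_s = seg$time[ends] + step_s - seg$time[starts],
             n_windows = r$lengths,
             stringsAsFactors = FALSE)
}

#' Drop windows that fall inside stimulation periods
#'
#' Removes from a segmentation (or band-power series times) every window
#' whose start time lies inside \code{[onset - exclusion[1], onset +
#' exclusion[2]]} for any trial. Windows are indexed by their start time
#' throughout the package, so exclusion is keyed to that time stamp;
#' pre-stimulus windows (start before onset) always survive.
#'
#' @param seg A \code{state_segmentation}.
#' @param trials A \code{trial_set}.
#' @param exclusion Seconds before / after onset to exclude, default
#'   \code{c(0.001, 16.432)} for 16 s stimulation.
#' @return The segmentation with excluded windows removed.
#' @export
exclude_stimulation <- function(seg, trials, exclusion = c(0.001, 16.432)) {
  keep <- rep(TRUE, nrow(seg))
  for (onset in trials$onset_s)
    keep <- keep & !(seg$time >= onset - exclusion[1L] &
                       seg$time <= onset + exclusion[2L])
  out <- seg[keep, , drop = FALSE]
  attributes(out)[c("scheme", "method")] <- attributes(seg)[c("scheme", "method")]
  class(out) <- class(seg)
  out
}

#' Classify stimulation trials from their pre-stimulus windows
#'
#' Labels each trial with the majority state of the classified windows whose
#' start time falls in \code{[onset - prestim_window_s, onset)}. Windows
#' starting inside the stimulation exclusion span are never used. A majority
#' tie is resolved in favour of the window nearest the stimulus onset.
#'
#' @param seg A \code{state_segmentation} of the recording.
#' @param trials A \code{trial_set}.
#' @param prestim_window_s Length of the pre-stimulus period used, seconds
#'   (typically 1, 5 or 10).
#' @param exclusion Stimulation exclusion span, as in
#'   [exclude_stimulation()].
#' @return Data frame with columns \code{trial}, \code{onset_s},
#'   \code{state}, \code{n_windows}.
#' @export
classify_trials <- function(seg, trials, prestim_window_s = 10,
                            exclusion = c(0.001, 16.432)) {
  seg <- exclude_stimulation(seg, trials, exclusion)
  out <- trials[, c("trial", "onset_s")]
  out$state <- NA_character_
  out$n_windows <- 0L
  for (i in seq_len(nrow(trials))) {
    onset <- trials$onset_s[i]
    sel <- seg$time >= onset - prestim_window_s & seg$time < onset
    if (!any(sel))
      stop(sprintf("trial %d has no windows in its %g s pre-stimulus period",
                   trials$trial[i], prestim_window_s))
    w <- seg[sel, , drop = FALSE]
    tab <- table(w$state)
    top <- names(tab)[tab == max(tab)]
    out$state[i] <- if (length(top) == 1L) top else {
      # tie: state of the window nearest the onset
      w$state[which.max(w$time)]
    }
    out$n_windows[i] <- sum(sel)
  }
  out
}

#' Train a classifier end-to-end from a labelled recording
#'
#' Convenience wrapper: cuts the recording into its single-state reference
#' intervals, extracts initialisation-scheme band powers within each
#' interval long enough to hold at least one window, pools them per state
#' and calls [define_model_vectors()]. Transition-straddling windows are
#' thereby excluded from training.
#'
#' @param rec An [lfp_recording()].
#' @param truth A [ground_truth()] (or reference intervals data frame).
#' @param scheme Initialisation scheme, default 4 s / 0.4 s.
#' @param channels,normalisation,taper Passed to [band_powers()].
#' @param ... Passed to [define_model_vectors()] (\code{l},
#'   \code{bounds_state}, \code{rounding_precision}, \code{codes}).
#' @return An \code{absc_model}.
#' @export
absc_train <- function(rec, truth, scheme = init_scheme(), channels = NULL,
                       normalisation = "relative", taper = "rectangular",
                       ...) {
  iv <- if (inherits(truth, "ground_truth")) truth$intervals else truth
  rate <- rec$sample_rate
  win <- round(scheme$window_s * rate)
  pooled <- list()
  for (i in seq_len(nrow(iv))) {
    i0 <- max(1L, floor((iv$start_s[i] - rec$t0) * rate) + 1L)
    i1 <- min(ncol(rec$samples), floor((iv$end_s[i] - rec$t0) * rate))
    if (i1 - i0 + 1L < win) next
    sub <- lfp_recording(rec$samples[, i0:i1, drop = FALSE], rate,
                         rec$channel_ids, t0 = rec$t0 + (i0 - 1L) / rate)
    bp <- band_powers(sub, scheme, channels = channels,
                      normalisation = normalisation, taper = taper)
    st <- iv$state[i]
    pooled[[st]] <- if (is.null(pooled[[st]])) bp else {
      bp2 <- pooled[[st]]
      bp2$powers <- rbind(bp2$powers, bp$powers)
      bp2$times <- c(bp2$times, bp$times)
      bp2
    }
  }
  if (length(pooled) < 2L)
    stop("training recording must contain usable intervals of both states")
  define_model_vectors(pooled, ...)
}

#' Classify a recording end-to-end with a trained model
#'
#' @param rec An [lfp_recording()].
#' @param model An \code{absc_model}.
#' @param scheme Classification scheme, default 10 s / 1 s.
#' @param channels Channel subset (default: model's frozen channels when
#'   available, else deep-channel default).
#' @return A \code{state_segmentation}.
#' @export
absc_classify <- function(rec, model, scheme = window_scheme(),
                          channels = NULL) {
  feat <- model$features
  if (is.null(channels) && !is.null(feat) &&
      all(feat$channels %in% rec$channel_ids))
    channels <- feat$channels
  bp <- band_powers(rec, scheme,
                    bands = if (!is.null(feat)) feat$bands else eeg_bands(),
                    channels = channels,
                    normalisation = if (!is.null(feat)) feat$normalisation
                                    else "relative",
                    taper = if (!is.null(feat)) feat$taper else "rectangular")
  classify_states(bp, model)
}
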