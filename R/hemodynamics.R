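#' Stable single-state periods of a segmentation
#'
#' Converts maximal runs of identical window labels to time intervals and
#' keeps only those strictly longer than \code{min_duration_s}. Short
#' periods are excluded because they are vulnerable to noise and to state
#' transitions.
#'
#' @param seg A \code{state_segmentation}.
#' @param min_duration_s Minimum duration in seconds (default 30; strict).
#' @return Data frame with \code{start_s}, \code{end_s}, \code{state},
#'   \code{duration_s}.
#' @export
stable_periods <- function(seg, min_duration_s = 30) {
  if (nrow(seg) == 0L) stop("empty segmentation")
  iv <- segmentation_intervals(seg)
  iv <- iv[iv$duration_s > min_duration_s & !is.na(iv$state), , drop = FALSE]
  rownames(iv) <- NULL
  iv[, c("start_s", "end_s", "state", "duration_s")]
}

#' Mean haemoglobin levels per state over stable periods
#'
#' Averages Hbo, Hbr and Hbt across time within each stable period, then
#' pools per state with duration weighting (equivalent to concatenating the
#' labelled samples), and reports desynchronised-minus-synchronised
#' differences.
#'
#' @param hemo A \code{hemo_recording}.
#' @param periods Data frame from [stable_periods()].
#' @return A list of class \code{state_period_summary}: \code{per_period}
#'   (one row per period with its means), \code{per_state} (pooled means),
#'   \code{difference} (named vector, desync - sync, micromolar).
#' @export
baseline_state_means <- function(hemo, periods) {
  stopifnot(inherits(hemo, "hemo_recording"))
  if (nrow(periods) > 0 &&
      (min(periods$start_s) < min(hemo$time) - 1e-9 ||
       max(periods$end_s) > max(hemo$time) + 1 / attr(hemo, "sample_rate") + 1e-9))
    stop("period outside the haemodynamic recording span")
  species <- c("hbo", "hbr", "hbt")
  pp <- periods
  for (sp in species) pp[[sp]] <- NA_real_
  for (i in seq_len(nrow(periods))) {
    sel <- hemo$time >= periods$start_s[i] & hemo$time < periods$end_s[i]
    for (sp in species) pp[[sp]][i] <- mean(hemo[[sp]][sel])
  }
  states <- cortical_states()
  per_state <- data.frame(state = states)
  for (sp in species) {
    per_state[[sp]] <- vapply(states, function(st) {
      sel <- pp$state == st
      if (!any(sel)) return(NA_real_)
      stats::weighted.mean(pp[[sp]][sel], w = pp$duration_s[sel])
    }, numeric(1))
  }
  diffs <- vapply(species, function(sp)
    per_state[[sp]][per_state$state == "desynchronised"] -
      per_state[[sp]][per_state$state == "synchronised"], numeric(1))
  structure(list(per_period = pp, per_state = per_state, difference = diffs),
            class = "state_period_summary")
}

#' @export
print.state_period_summary <- function(x, ...) {
  cat("<state_period_summary>\n")
  print(x$per_state, row.names = FALSE)
  cat("desync - sync (uM): ",
      paste(sprintf("%s %+0.2f", names(x$difference), x$difference),
            collapse = ", "), "\n")
  invisible(x)
}

#' State-sorted time-locked trial averages of the haemodynamics
#'
#' Extracts a \code{[-pre_s, +post_s)} epoch around each stimulus onset,
#' subtracts each trial's own pre-stimulus mean (per species), and averages
#' the baselined traces per assigned state. The scalar summary per state and
#' species is the mean over \code{summary_window_s} after onset. An
#' experiment only qualifies for a state's cross-experiment average if it
#' contributes at least \code{min_trials} trials in that state; states
#' falling short are flagged \code{excluded}.
#'
#' @param hemo A \code{hemo_recording}.
#' @param trials A \code{trial_set}.
#' @param trial_states Character vector, one state per trial (as from
#'   [classify_trials()]).
#' @param pre_s,post_s Epoch extent around onset in seconds (defaults 10
#'   and 60, covering a 70 s trial).
#' @param summary_window_s Post-onset span for the scalar summary, default
#'   \code{c(0, 10)}.
#' @param min_trials Inclusion threshold per state (default 5).
#' @return A list of class \code{trial_average}: per state \code{n_trials},
#'   \code{excluded}, \code{traces} (data frame time x species) and
#'   \code{summary} (named scalar means over the summary window).
#' @export
state_sorted_trial_average <- function(hemo, trials, trial_states,
                                       pre_s = 10, post_s = 60,
                                       summary_window_s = c(0, 10),
                                       min_trials = 5L) {
  stopifnot(inherits(hemo, "hemo_recording"),
            length(trial_states) == nrow(trials))
  rate <- attr(hemo, "sample_rate")
  rel <- seq(-pre_s, post_s - 1 / rate, by = 1 / rate)
  species <- c("hbo", "hbr", "hbt")
  out <- list()
  for (st in cortical_states()) {
    idx <- which(trial_states == st)
    if (length(idx) == 0L) {
      out[[st]] <- list(n_trials = 0L, excluded = TRUE, traces = NULL,
                        summary = stats::setNames(rep(NA_real_, 3L), species))
      next
    }
    acc <- matrix(0, nrow = length(rel), ncol = 3L,
                  dimnames = list(NULL, species))
    for (i in idx) {
      onset <- trials$onset_s[i]
      if (onset - pre_s < min(hemo$time) - 1e-9 ||
          onset + post_s > max(hemo$time) + 1 / rate + 1e-9)
        stop(sprintf("trial %d epoch extends beyond the recording",
                     trials$trial[i]))
      j0 <- round((onset - pre_s - hemo$time[1L]) * rate) + 1L
      jj <- j0:(j0 + length(rel) - 1L)
      for (sp in species) {
        tr <- hemo[[sp]][jj]
        acc[, sp] <- acc[, sp] + (tr - mean(tr[rel < 0]))
      }
    }
    traces <- as.data.frame(acc / length(idx))
    traces <- cbind(data.frame(time = rel), traces)
    sw <- rel >= summary_window_s[1L] & rel <= summary_window_s[2L]
    out[[st]] <- list(
      n_trials = length(idx),
      excluded = length(idx) < min_trials,
      traces = traces,
      summary = vapply(species, function(sp) mean(traces[[sp]][sw]),
                       numeric(1)))
  }
  structure(out, class = "trial_average", min_trials = min_trials)
}

#' @export
print.trial_average <- function(x, ...) {
  cat("<trial_average>\n")
  for (st in names(x)) {
    cat(sprintf("  %s: %d trial(s)%s", st, x[[st]]$n_trials,
                if (x[[st]]$excluded) "  [excluded: below minimum]" else ""))
    if (!is.null(x[[st]]$traces))
      cat(sprintf("  0-10 s means (uM): hbo %+0.2f, hbr %+0.2f, hbt %+0.2f",
                  x[[st]]$summary["hbo"], x[[st]]$summary["hbr"],
                  x[[st]]$summary["hbt"]))
    cat("\n")
  }
  invisible(x)
}

#' Per-trial evoked summary scalars
#'
#' For each stimulation trial: subtract the trial's own pre-stimulus mean
#' (per species) and average the baselined trace over
#' \code{summary_window_s} after onset. These per-unit scalars feed
#' [randomisation_control()]; [state_sorted_trial_average()] reports their
#' state-averaged counterparts.
#'
#' @param hemo A \code{hemo_recording}.
#' @param trials A \code{trial_set}.
#' @param species One of \code{"hbo"}, \code{"hbr"}, \code{"hbt"}.
#' @param pre_s Pre-stimulus baseline span in seconds (default 10).
#' @param summary_window_s Post-onset averaging span, default \code{c(0, 10)}.
#' @return Numeric vector, one summary per trial (micromolar).
#' @export
trial_summaries <- function(hemo, trials, species = "hbt", pre_s = 10,
                            summary_window_s = c(0, 10)) {
  stopifnot(inherits(hemo, "hemo_recording"),
            species %in% c("hbo", "hbr", "hbt"))
  vapply(seq_len(nrow(trials)), function(i) {
    onset <- trials$onset_s[i]
    if (onset - pre_s < min(hemo$time) - 1e-9 ||
        onset + summary_window_s[2L] > max(hemo$time) + 1e-9)
      stop(sprintf("trial %d extends beyond the recording", trials$trial[i]))
    base <- hemo$time >= onset - pre_s & hemo$time < onset
    post <- hemo$time >= onset + summary_window_s[1L] &
      hemo$time <= onset + summary_window_s[2L]
    mean(hemo[[species]][post]) - mean(hemo[[species]][base])
  }, numeric(1))
}

#' Randomisation control for state-sorted differences
#'
#' Tests whether a measured desynchronised-minus-synchronised difference
#' could arise from the partitioning alone: the state labels of the analysis
#' units (trials or stable periods) are randomly permuted \code{n_repeats}
#' times (within experiment when a grouping is supplied, preserving each
#' experiment's state counts and unit durations), the difference is
#' recomputed for each permutation, and the true difference is pooled with
#' the null differences. A value is an outlier of the pooled set iff
#' \code{x > Q3 + 1.5 IQR} or \code{x < Q1 - 1.5 IQR}, with quartiles by
#' linear interpolation (R type 7).
#'
#' @param values Numeric summary per unit (e.g. mean Hbt of a period or the
#'   0--10 s evoked mean of a trial).
#' @param labels State per unit.
#' @param experiment Optional grouping factor; the difference is then the
#'   unweighted mean over experiments of per-experiment differences
#'   (experiments missing a state are dropped from that mean), and
#'   permutation happens within experiment.
#' @param n_repeats Number of permutations (default 50).
#' @param seed Optional integer seed.
#' @return A list of class \code{randomisation_control}: \code{true_diff},
#'   \code{null_diffs}, \code{q1}, \code{q3}, \code{iqr}, \code{outliers}
#'   (logical over \code{c(true, nulls)}), \code{true_is_outlier},
#'   \code{true_unique_outlier}.
#' @export
randomisation_control <- function(values, labels, experiment = NULL,
                                  n_repeats = 50L, seed = NULL) {
  stopifnot(length(values) == length(labels))
  if (length(values) < 2L) stop("too few units to permute")
  if (is.null(experiment)) experiment <- rep(1L, length(values))
  experiment <- as.factor(experiment)
  if (!is.null(seed)) set.seed(seed)

  diff_fun <- function(lab) {
    d <- tapply(seq_along(values), experiment, function(ii) {
      de <- lab[ii] == "desynchronised"
      if (!any(de) || all(de)) return(NA_real_)
      mean(values[ii][de]) - mean(values[ii][!de])
    })
    mean(unlist(d), na.rm = TRUE)
  }

  true_diff <- diff_fun(labels)
  if (is.na(true_diff)) stop("need both states present to form a difference")
  null_diffs <- vapply(seq_len(n_repeats), function(r) {
    perm <- labels
    for (g in levels(experiment)) {
      ii <- which(experiment == g)
      perm[ii] <- sample(labels[ii])
    }
    diff_fun(perm)
  }, numeric(1))

  pooled <- c(true_diff, null_diffs)
  q <- stats::quantile(pooled, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2L] - q[1L]
  out <- pooled > q[2L] + 1.5 * iqr | pooled < q[1L] - 1.5 * iqr
  structure(list(true_diff = true_diff, null_diffs = null_diffs,
                 q1 = q[1L], q3 = q[2L], iqr = iqr, outliers = out,
                 true_is_outlier = out[1L],
                 true_unique_outlier = out[1L] && sum(out) == 1L),
            class = "randomisation_control")
}

#' @export
print.randomisation_control <- function(x, ...) {
  cat(sprintf("<randomisation_control> true diff %+0.3f vs %d permuted diffs\n",
              x$true_diff, length(x$null_diffs)))
  cat(sprintf("  1.5 IQR fences: [%0.3f, %0.3f]; true %s outlier%s\n",
              x$q1 - 1.5 * x$iqr, x$q3 + 1.5 * x$iqr,
              if (x$true_is_outlier) "IS an" else "is NOT an",
              if (x$true_unique_outlier) " (unique)" else ""))
  invisible(x)
}
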