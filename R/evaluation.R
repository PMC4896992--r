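#' Point-by-point accuracy of a segmentation against reference labels
#'
#' Each window's label is compared with the reference state at the window's
#' start time. Windows the method left unlabelled (NA) are counted
#' separately: \code{percent_correct} is computed among classified windows
#' only, while \code{total_accuracy} counts unclassified windows as
#' incorrect, so \code{total_accuracy = percent_correct x fraction
#' classified}.
#'
#' @param seg A \code{state_segmentation}.
#' @param reference A [ground_truth()], a reference intervals data frame
#'   (\code{start_s}, \code{end_s}, \code{state}), or another segmentation
#'   sharing the same window times.
#' @return One-row data frame with \code{n_windows},
#'   \code{percent_correct}, \code{percent_unclassified},
#'   \code{total_accuracy} (all percentages 0--100).
#' @export
score_segmentation <- function(seg, reference) {
  ref_labels <- if (inherits(reference, "state_segmentation")) {
    if (nrow(reference) != nrow(seg) ||
        any(abs(reference$time - seg$time) > 1e-6))
      stop("reference segmentation does not share the window times")
    reference$state
  } else {
    state_at_time(reference, seg$time)
  }
  if (all(is.na(ref_labels)))
    stop("segmentation and reference spans do not overlap")
  classified <- !is.na(seg$state)
  n <- nrow(seg)
  correct <- sum(classified & !is.na(ref_labels) & seg$state == ref_labels)
  pc <- if (any(classified)) 100 * correct / sum(classified) else NA_real_
  pu <- 100 * sum(!classified) / n
  data.frame(n_windows = n,
             percent_correct = pc,
             percent_unclassified = pu,
             total_accuracy = 100 * correct / n)
}

#' Compare classification methods across recordings
#'
#' Runs each method on each recording, scores it against the recording's
#' reference labels, and tabulates per-method mean and SD across
#' recordings. A method failing on a recording is recorded (NA row, message
#' retained) rather than aborting the comparison. Elapsed wall time per
#' method is reported for information only.
#'
#' @param recordings List of [lfp_recording()] objects.
#' @param references List of references (one per recording), as accepted by
#'   [score_segmentation()].
#' @param methods Named list of functions taking a recording and returning a
#'   \code{state_segmentation}.
#' @return A list of class \code{accuracy_report}: \code{per_recording}
#'   (long data frame), \code{summary} (per-method mean/SD of the three
#'   percentages plus total elapsed seconds), \code{errors} (named list of
#'   failure messages).
#' @export
compare_methods <- function(recordings, references, methods) {
  stopifnot(length(recordings) == length(references), length(methods) >= 1L,
            length(recordings) >= 1L, !is.null(names(methods)))
  rows <- list(); errors <- list(); elapsed <- numeric(0)
  for (m in names(methods)) {
    t0 <- proc.time()[["elapsed"]]
    for (i in seq_along(recordings)) {
      row <- tryCatch({
        seg <- methods[[m]](recordings[[i]])
        score_segmentation(seg, references[[i]])
      }, error = function(e) {
        errors[[paste0(m, ":", i)]] <<- conditionMessage(e)
        data.frame(n_windows = NA_integer_, percent_correct = NA_real_,
                   percent_unclassified = NA_real_, total_accuracy = NA_real_)
      })
      row$method <- m; row$recording <- i
      rows[[length(rows) + 1L]] <- row
    }
    elapsed[m] <- proc.time()[["elapsed"]] - t0
  }
  per_recording <- do.call(rbind, rows)
  agg <- function(v, f) tapply(v, per_recording$method, f, na.rm = TRUE)
  methods_order <- names(methods)
  summary <- data.frame(
    method = methods_order,
    mean_percent_correct = agg(per_recording$percent_correct, mean)[methods_order],
    sd_percent_correct = agg(per_recording$percent_correct, stats::sd)[methods_order],
    mean_percent_unclassified = agg(per_recording$percent_unclassified, mean)[methods_order],
    mean_total_accuracy = agg(per_recording$total_accuracy, mean)[methods_order],
    sd_total_accuracy = agg(per_recording$total_accuracy, stats::sd)[methods_order],
    elapsed_s = elapsed[methods_order],
    row.names = NULL)
  structure(list(per_recording = per_recording, summary = summary,
                 errors = errors),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, digits = 2, ...) {
  cat("<accuracy_report> mean +/- SD across",
      length(unique(x$per_recording$recording)), "recording(s)\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf(
      "  %-18s correct %5.2f%% (SD %0.2f)  unclassified %5.2f%%  total %5.2f%% (SD %0.2f)  [%0.1f s]\n",
      s$method[i], s$mean_percent_correct[i], s$sd_percent_correct[i],
      s$mean_percent_unclassified[i], s$mean_total_accuracy[i],
      s$sd_total_accuracy[i], s$elapsed_s[i]))
  if (length(x$errors))
    cat("  failures:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}
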