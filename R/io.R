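# Plain-text interchange formats: tab-separated tables preceded by
# "#key: value" header lines carrying rates/units/metadata.

write_header <- function(con, meta) {
  for (k in names(meta))
    writeLines(sprintf("#%s: %s", k, paste(meta[[k]], collapse = ",")), con)
}

read_header <- function(path) {
  lines <- readLines(path, n = 50L)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#", "", h)
    k <- sub(":.*$", "", kv)
    v <- sub("^[^:]*:\\s*", "", kv)
    meta[[k]] <- v
  }
  list(meta = meta, skip = length(hdr))
}

#' Write / read an LFP recording as delimited text
#'
#' Columns are channels (named by id), rows are samples; header lines carry
#' the sample rate, channel ids, start time and units.
#'
#' @param rec An [lfp_recording()].
#' @param path Output / input file path.
#' @param units Voltage unit label recorded in the header.
#' @return \code{read_lfp} returns an [lfp_recording()];
#'   \code{write_lfp} returns \code{path} invisibly.
#' @export
write_lfp <- function(rec, path, units = "a.u.") {
  con <- file(path, "w")
  on.exit(close(con))
  write_header(con, list(format = "cortstate-lfp-v1",
                         sample_rate_hz = rec$sample_rate,
                         channels = rec$channel_ids, t0_s = rec$t0,
                         units = units))
  m <- t(rec$samples)
  colnames(m) <- paste0("ch", rec$channel_ids)
  utils::write.table(format(m, digits = 7, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lfp
#' @export
read_lfp <- function(path) {
  h <- read_header(path)
  d <- utils::read.table(path, sep = "\t", header = TRUE, skip = h$skip)
  lfp_recording(t(as.matrix(d)),
                sample_rate = as.numeric(h$meta$sample_rate_hz),
                channel_ids = as.integer(strsplit(h$meta$channels, ",")[[1L]]),
                t0 = as.numeric(h$meta$t0_s %||% 0))
}

#' Write / read a haemodynamic recording (t, Hbo, Hbr, Hbt)
#'
#' @param hemo A \code{hemo_recording}.
#' @param path File path.
#' @return \code{read_hemo} returns a \code{hemo_recording}.
#' @export
write_hemo <- function(hemo, path) {
  con <- file(path, "w")
  on.exit(close(con))
  write_header(con, list(format = "cortstate-hemo-v1",
                         sample_rate_hz = attr(hemo, "sample_rate"),
                         units = "micromolar"))
  utils::write.table(as.data.frame(hemo), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_hemo
#' @export
read_hemo <- function(path) {
  h <- read_header(path)
  d <- utils::read.table(path, sep = "\t", header = TRUE, skip = h$skip)
  hemo_recording(d$time, d$hbo, d$hbr, d$hbt,
                 sample_rate = as.numeric(h$meta$sample_rate_hz))
}

#' Write / read state intervals (start_s, end_s, state)
#' @param intervals Data frame with \code{start_s}, \code{end_s},
#'   \code{state} (a [ground_truth()] is accepted).
#' @param path File path.
#' @return \code{read_intervals} returns the data frame.
#' @export
write_intervals <- function(intervals, path) {
  if (inherits(intervals, "ground_truth")) intervals <- intervals$intervals
  utils::write.table(intervals[, c("start_s", "end_s", "state")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_intervals
#' @export
read_intervals <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write / read a trial schedule (onset_s, duration_s, pulse_rate_hz)
#' @param trials A \code{trial_set}.
#' @param path File path.
#' @return \code{read_trials} returns a \code{trial_set}.
#' @export
write_trials <- function(trials, path) {
  utils::write.table(as.data.frame(trials), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE)
  if (is.null(d$trial)) d$trial <- seq_len(nrow(d))
  if (is.null(d$n_pulses))
    d$n_pulses <- as.integer(round(d$duration_s * d$pulse_rate_hz))
  class(d) <- c("trial_set", "data.frame")
  d
}

#' Write a band-power series as delimited text
#'
#' Columns t and the five bands; the header records scheme, channels and
#' normalisation so the feature configuration travels with the data.
#' @param bp A \code{band_power_series}.
#' @param path File path.
#' @export
write_band_powers <- function(bp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  write_header(con, list(format = "cortstate-bands-v1",
                         window_s = bp$scheme$window_s,
                         step_s = bp$scheme$step_s,
                         channels = bp$channels_used,
                         normalisation = bp$normalisation,
                         taper = bp$taper))
  d <- cbind(data.frame(t = bp$times), as.data.frame(bp$powers))
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a state segmentation (t, state)
#' @param seg A \code{state_segmentation}.
#' @param path File path.
#' @return \code{read_segmentation} returns a \code{state_segmentation}.
#' @export
write_segmentation <- function(seg, path) {
  con <- file(path, "w")
  on.exit(close(con))
  sch <- attr(seg, "scheme")
  meta <- list(format = "cortstate-labels-v1",
               method = attr(seg, "method") %||% "unknown")
  if (!is.null(sch)) {
    meta$window_s <- sch$window_s
    meta$step_s <- sch$step_s
  }
  write_header(con, meta)
  utils::write.table(as.data.frame(seg), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_segmentation
#' @export
read_segmentation <- function(path) {
  h <- read_header(path)
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  scheme <- if (!is.null(h$meta$window_s))
    window_scheme(as.numeric(h$meta$window_s), as.numeric(h$meta$step_s))
  else NULL
  state_segmentation(d$time, d$state, scheme = scheme,
                     method = h$meta$method %||% "unknown")
}

#' Serialise / load a trained model as YAML
#'
#' The model file is a human-readable, versioned YAML document holding the
#' band definitions, window scheme, normalisation mode, bounds, codes and
#' the per-state model vectors.
#'
#' @param model An \code{absc_model}.
#' @param path File path.
#' @return \code{read_absc_model} returns an \code{absc_model}.
#' @export
write_absc_model <- function(model, path) {
  feat <- model$features
  doc <- list(
    format = "cortstate-model-v1",
    codes = as.integer(model$codes),
    l = model$l,
    bounds = list(ub = model$bounds$ub, lb = model$bounds$lb,
                  source_state = model$bounds$source_state,
                  rounding_precision = model$bounds$rounding_precision),
    variance_explained = as.list(model$variance_explained),
    vectors = lapply(model$vectors, function(m)
      lapply(seq_len(nrow(m)), function(i) as.integer(m[i, ]))),
    counts = model$counts,
    features = if (!is.null(feat)) list(
      bands = lapply(seq_len(nrow(feat$bands)), function(i)
        list(name = feat$bands$name[i], lo_hz = feat$bands$lo_hz[i],
             hi_hz = feat$bands$hi_hz[i])),
      window_s = feat$scheme$window_s, step_s = feat$scheme$step_s,
      normalisation = feat$normalisation, taper = feat$taper,
      channels = as.integer(feat$channels)) else NULL)
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_absc_model
#' @export
read_absc_model <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!identical(doc$format, "cortstate-model-v1"))
    stop("not a cortstate model file")
  pair_names <- colnames(band_pairs())
  vectors <- lapply(doc$vectors, function(v) {
    m <- do.call(rbind, lapply(v, as.integer))
    colnames(m) <- pair_names
    m
  })
  features <- if (!is.null(doc$features)) {
    f <- doc$features
    list(bands = do.call(rbind, lapply(f$bands, as.data.frame)),
         scheme = window_scheme(f$window_s, f$step_s,
                                role = "initialisation"),
         normalisation = f$normalisation, taper = f$taper,
         channels = f$channels)
  } else NULL
  structure(list(vectors = vectors,
                 counts = lapply(doc$counts, as.integer),
                 l = as.integer(doc$l),
                 bounds = structure(list(
                   ub = doc$bounds$ub, lb = doc$bounds$lb,
                   source_state = doc$bounds$source_state,
                   rounding_precision = doc$bounds$rounding_precision),
                   class = "absc_bounds"),
                 codes = as.integer(doc$codes),
                 variance_explained = unlist(doc$variance_explained),
                 features = features),
            class = "absc_model")
}
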