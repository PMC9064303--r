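#' Construct a spike train
#'
#' A spike train holds the sorted event times of one recording node
#' (an electrode's multi-unit activity, or a model neuron) together with its
#' observation window. Times are in seconds. Observation windows are
#' half-open, `[t_start, t_end)`, so that adjacent analysis windows never
#' double-count an event.
#'
#' @param times Numeric vector of spike times in seconds (sorted on input).
#' @param t_start,t_end Observation bounds in seconds, `t_end > t_start`.
#' @param node_id Node label (coerced to character).
#' @return An object of class `spike_train` with elements `node_id`, `times`,
#'   `t_start`, `t_end`.
#' @export
spike_train <- function(times, t_start, t_end, node_id = "1") {
  if (!is.numeric(times)) stop("`times` must be numeric")
  if (!is.numeric(t_start) || !is.numeric(t_end) || t_end <= t_start) {
    stop("need numeric bounds with t_end > t_start")
  }
  times <- sort(as.numeric(times))
  if (length(times) > 0 && (times[1] < t_start || times[length(times)] >= t_end)) {
    stop("spike times must lie within [t_start, t_end)")
  }
  structure(
    list(node_id = as.character(node_id), times = times,
         t_start = as.numeric(t_start), t_end = as.numeric(t_end)),
    class = "spike_train"
  )
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> node %s: %d spikes on [%g, %g) s (%.3g Hz)\n",
              x$node_id, length(x$times), x$t_start, x$t_end,
              length(x$times) / (x$t_end - x$t_start)))
  invisible(x)
}

#' Construct a recording
#'
#' A recording is one session: a set of spike trains sharing a common
#' observation window, plus session metadata (culture/simulation label and
#' a day or window label used to order longitudinal comparisons).
#'
#' @param trains List of [spike_train] objects with unique `node_id`s and
#'   identical observation windows.
#' @param culture_id Session label.
#' @param day Integer day (days in vitro, or a simulation window index).
#' @return An object of class `recording`.
#' @export
recording <- function(trains, culture_id = "culture", day = 0L) {
  if (length(trains) == 0) stop("a recording needs at least one spike train")
  ids <- vapply(trains, function(tr) tr$node_id, character(1))
  if (anyDuplicated(ids)) stop("node_ids must be unique")
  t0 <- unique(vapply(trains, function(tr) tr$t_start, numeric(1)))
  t1 <- unique(vapply(trains, function(tr) tr$t_end, numeric(1)))
  if (length(t0) != 1 || length(t1) != 1) {
    stop("all trains must share the same observation window")
  }
  names(trains) <- ids
  structure(
    list(culture_id = as.character(culture_id), day = as.integer(day),
         trains = trains, t_start = t0, t_end = t1),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  counts <- vapply(x$trains, function(tr) length(tr$times), integer(1))
  cat(sprintf("<recording> %s day %d: %d nodes, %d spikes on [%g, %g) s\n",
              x$culture_id, x$day, length(x$trains), sum(counts),
              x$t_start, x$t_end))
  invisible(x)
}

#' Number of spikes per node in a recording
#' @param rec A [recording].
#' @return Named integer vector of spike counts.
#' @export
spike_counts <- function(rec) {
  vapply(rec$trains, function(tr) length(tr$times), integer(1))
}

#' Read spike events from delimited text
#'
#' Reads a two-column event file (node identifier, spike time) into a
#' [recording]. Lines starting with `#` are comments. Fields may be separated
#' by tabs, commas, or whitespace. Events outside the half-open window
#' `[t_start, t_end)` are dropped and the number dropped is reported via
#' `message()`. Times are seconds by default; when the second column holds
#' integer sample indices, pass `sample_rate` (Hz) to convert on load.
#'
#' @param path Path to the event file.
#' @param t_start,t_end Observation window in seconds.
#' @param sample_rate Optional sampling rate in Hz; when given, the time
#'   column is interpreted as integer sample indices and divided by it.
#' @param culture_id,day Session metadata, stored on the result.
#' @return A [recording] with one [spike_train] per distinct node id.
#' @export
read_spike_events <- function(path, t_start = 0, t_end = 3600,
                              sample_rate = NULL,
                              culture_id = "culture", day = 0L) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) stop("empty event file: ", path)
  body <- lines[keep]
  line_no <- which(keep)
  parts <- strsplit(trimws(body), "[\t, ]+")
  bad <- which(lengths(parts) < 2)
  if (length(bad) > 0) {
    stop(sprintf("malformed line %d in %s: %s",
                 line_no[bad[1]], path, body[bad[1]]))
  }
  ids <- vapply(parts, `[[`, character(1), 1L)
  tms <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  if (anyNA(tms)) {
    bad <- which(is.na(tms))[1]
    stop(sprintf("malformed line %d in %s: non-numeric time", line_no[bad], path))
  }
  if (!is.null(sample_rate)) tms <- tms / sample_rate
  in_window <- tms >= t_start & tms < t_end
  n_dropped <- sum(!in_window)
  if (n_dropped > 0) {
    message(sprintf("read_spike_events: dropped %d events outside [%g, %g)",
                    n_dropped, t_start, t_end))
  }
  ids <- ids[in_window]
  tms <- tms[in_window]
  if (length(ids) == 0) stop("no in-window events in ", path)
  split_times <- split(tms, ids)
  trains <- lapply(names(split_times), function(id) {
    spike_train(split_times[[id]], t_start, t_end, node_id = id)
  })
  recording(trains, culture_id = culture_id, day = day)
}

#' Write spike events to delimited text
#'
#' Inverse of [read_spike_events()]: one `node_id<TAB>time_s` line per event,
#' times printed with enough digits to round-trip exactly.
#'
#' @param rec A [recording].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spike_events <- function(rec, path) {
  rows <- lapply(rec$trains, function(tr) {
    if (length(tr$times) == 0) return(NULL)
    data.frame(node_id = tr$node_id, time_s = tr$times)
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$time_s), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# node_id\ttime_s", con)
  writeLines(sprintf("%s\t%.17g", df$node_id, df$time_s), con)
  invisible(path)
}

#' Remove low-activity nodes
#'
#' Drops every train with fewer than `min_spikes` events, mirroring the
#' standard multi-electrode array preprocessing step in which electrodes with
#' less than 100 spikes are removed from the analysis (the bound is strict:
#' a node with exactly `min_spikes` spikes is retained).
#'
#' @param rec A [recording].
#' @param min_spikes Minimum spike count to retain a node.
#' @return The filtered [recording].
#' @export
filter_low_activity <- function(rec, min_spikes = 100) {
  if (min_spikes < 0) stop("min_spikes must be >= 0")
  counts <- spike_counts(rec)
  drop <- names(counts)[counts < min_spikes]
  if (length(drop) == length(counts)) {
    stop("all nodes fall below min_spikes; nothing to analyse")
  }
  if (length(drop) > 0) {
    message("filter_low_activity: removed node(s) ",
            paste(drop, collapse = ", "))
  }
  keep <- setdiff(names(rec$trains), drop)
  recording(rec$trains[keep], culture_id = rec$culture_id, day = rec$day)
}

#' Jitter spike times
#'
#' Adds independent Uniform(-`half_width`, +`half_width`) offsets to every
#' spike time and re-sorts each train. Recordings sampled on a fixed clock
#' (e.g. 25 kHz, a 40 microsecond grid) contain exactly tied interspike
#' intervals which the nearest-neighbour estimators must not be allowed to
#' exploit; jitter breaks those ties with probability one. Spikes pushed
#' across the window edge are clamped just inside it.
#'
#' @param rec A [recording].
#' @param half_width Jitter half-width in seconds (default 20e-6, half of a
#'   40 microsecond sampling grid).
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @return The jittered [recording].
#' @export
jitter_spike_times <- function(rec, half_width = 20e-6, seed = NULL) {
  if (half_width < 0) stop("half_width must be >= 0")
  if (half_width == 0) return(rec)
  with_seed(seed, {
    trains <- lapply(rec$trains, function(tr) {
      n <- length(tr$times)
      if (n == 0) return(tr)
      t_new <- tr$times + stats::runif(n, -half_width, half_width)
      t_new <- pmin(pmax(t_new, tr$t_start),
                    tr$t_end - .Machine$double.eps * abs(tr$t_end))
      spike_train(t_new, tr$t_start, tr$t_end, node_id = tr$node_id)
    })
    recording(trains, culture_id = rec$culture_id, day = rec$day)
  })
}

#' Restrict a recording to a sub-window
#'
#' Keeps only the events in the half-open window `[t_start, t_end)` and
#' resets the observation bounds of every train to that window.
#'
#' @param rec A [recording].
#' @param t_start,t_end New window in seconds.
#' @return A [recording] over the sub-window (empty trains are kept).
#' @export
crop_recording <- function(rec, t_start, t_end) {
  if (t_start < rec$t_start || t_end > rec$t_end || t_end <= t_start) {
    stop("sub-window must lie within the recording window")
  }
  trains <- lapply(rec$trains, function(tr) {
    keep <- tr$times >= t_start & tr$times < t_end
    spike_train(tr$times[keep], t_start, t_end, node_id = tr$node_id)
  })
  recording(trains, culture_id = rec$culture_id, day = rec$day)
}
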