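#' Event table for a task recording
#'
#' @param events Data frame with columns \code{label}, \code{onset} (s) and
#'   \code{duration} (s).
#' @param total_duration Total recording duration in s.
#' @param sampling_rate Sampling rate in Hz (default 39.7365, the device's
#'   full multiplexing-cycle rate).
#' @return An object of class \code{event_table}.
#' @export
event_table <- function(events, total_duration, sampling_rate = 39.7365) {
  stopifnot(is.data.frame(events),
            all(c("label", "onset", "duration") %in% names(events)))
  events <- events[order(events$onset), , drop = FALSE]
  rownames(events) <- NULL
  if (nrow(events) > 1L) {
    ends <- events$onset + events$duration
    if (any(events$onset[-1L] < ends[-nrow(events)] - 1e-9)) {
      stopf("events overlap")
    }
  }
  if (nrow(events) && (min(events$onset) < -1e-9 ||
                       max(events$onset + events$duration) > total_duration + 1e-9)) {
    stopf("events extend outside [0, %g] s", total_duration)
  }
  structure(list(events = events, total_duration = total_duration,
                 sampling_rate = sampling_rate),
            class = "event_table")
}

new_task_design <- function(task_name, tbl, stimulation_labels, baseline_window) {
  structure(list(task_name = task_name, event_table = tbl,
                 stimulation_labels = stimulation_labels,
                 baseline_window = baseline_window),
            class = "task_design")
}

#' Silent word generation (SWG) block protocol
#'
#' Builds the block-design timeline: a 60 s rest, then \code{n_blocks}
#' blocks each consisting of \code{slides_per_condition} contiguous 10 s
#' letter slides (stimulation) followed by the same number of 10 s
#' nonsense-symbol slides (within-task baseline), then a closing 60 s rest.
#' With the defaults each block spans 60 s and the stimulation epochs are
#' five 30 s letter periods.
#'
#' @param n_blocks Number of task blocks (default 5).
#' @param slide_duration Duration of one slide in s (default 10).
#' @param slides_per_condition Slides per condition per block (default 3).
#' @param rest Flanking rest duration in s (default 60).
#' @param sampling_rate Hz.
#' @return A \code{task_design} with \code{stimulation_labels = "letter"}
#'   and the pre-task rest minute as \code{baseline_window}.
#' @export
build_swg <- function(n_blocks = 5, slide_duration = 10,
                      slides_per_condition = 3, rest = 60,
                      sampling_rate = 39.7365) {
  if (slide_duration <= 0 || rest <= 0 || slides_per_condition < 1) {
    stopf("durations must be positive")
  }
  ev <- list(data.frame(label = "rest", onset = 0, duration = rest))
  t <- rest
  block_len <- 2 * slides_per_condition * slide_duration
  if (n_blocks > 0) {
    for (b in seq_len(n_blocks)) {
      ev[[length(ev) + 1L]] <- data.frame(
        label = "letter", onset = t,
        duration = slides_per_condition * slide_duration)
      t <- t + slides_per_condition * slide_duration
      ev[[length(ev) + 1L]] <- data.frame(
        label = "symbol", onset = t,
        duration = slides_per_condition * slide_duration)
      t <- t + slides_per_condition * slide_duration
    }
  }
  ev[[length(ev) + 1L]] <- data.frame(label = "rest", onset = t, duration = rest)
  total <- t + rest
  tbl <- event_table(do.call(rbind, ev), total, sampling_rate)
  new_task_design("SWG", tbl, "letter", c(0, rest))
}

#' Unstructured task protocol (digit span backward, symbol search)
#'
#' One continuous task epoch flanked by rest minutes; activation inference
#' for these designs uses the windowed-variability statistic, so the task
#' must span at least one 10 s analysis window and the pre-task rest minute
#' serves as the baseline.
#'
#' @param task_name Task label, e.g. \code{"SS"} or \code{"DS_backward"}.
#' @param task_duration Task length in s (SS is nominally 120 s; digit span
#'   length depends on performance, so the measured duration is supplied).
#' @param rest Flanking rest in s (default 60; must be positive, a baseline
#'   is required).
#' @param sampling_rate Hz.
#' @export
build_unstructured <- function(task_name, task_duration, rest = 60,
                               sampling_rate = 39.7365) {
  if (rest <= 0) stopf("a positive flanking rest is required as baseline")
  if (task_duration < 10) {
    stopf("task_duration %g s is shorter than one 10 s analysis window", task_duration)
  }
  ev <- data.frame(
    label = c("rest", "task", "rest"),
    onset = c(0, rest, rest + task_duration),
    duration = c(rest, task_duration, rest)
  )
  tbl <- event_table(ev, 2 * rest + task_duration, sampling_rate)
  new_task_design(task_name, tbl, "task", c(0, rest))
}

#' Sampled stimulation indicator
#'
#' Binary time series that is 1 during stimulation epochs of the design and
#' 0 elsewhere, the square-wave neuronal response assumed by the GLM.
#'
#' @param design A \code{task_design}.
#' @param n_samples Number of samples; must agree with
#'   \code{total_duration * sampling_rate} within one sample.
#' @param sampling_rate Hz; defaults to the design's event-table rate.
#' @return Numeric 0/1 vector of length \code{n_samples}.
#' @export
design_vector <- function(design, n_samples,
                          sampling_rate = design$event_table$sampling_rate) {
  expected <- design$event_table$total_duration * sampling_rate
  if (abs(n_samples - expected) > 1) {
    stopf("n_samples (%d) inconsistent with %g s at %g Hz",
          n_samples, design$event_table$total_duration, sampling_rate)
  }
  tt <- (seq_len(n_samples) - 1) / sampling_rate
  out <- numeric(n_samples)
  ev <- design$event_table$events
  stim <- ev[ev$label %in% design$stimulation_labels, , drop = FALSE]
  for (i in seq_len(nrow(stim))) {
    out[tt >= stim$onset[i] & tt < stim$onset[i] + stim$duration[i]] <- 1
  }
  out
}

# Onsets/durations of stimulation epochs of a design.
stimulation_epochs <- function(design) {
  ev <- design$event_table$events
  ev[ev$label %in% design$stimulation_labels, c("onset", "duration"), drop = FALSE]
}

#' Read / write event tables as CSV
#'
#' Plain CSV with columns \code{label}, \code{onset}, \code{duration};
#' total duration and sampling rate are carried in a \code{#}-prefixed
#' header line so tables round-trip losslessly.
#'
#' @param tbl An \code{event_table}.
#' @param path File path.
#' @rdname events_csv
#' @export
write_events_csv <- function(tbl, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# total_duration=%.10g sampling_rate=%.10g",
                     tbl$total_duration, tbl$sampling_rate), con)
  utils::write.csv(tbl$events, con, row.names = FALSE)
  invisible(path)
}

#' @rdname events_csv
#' @export
read_events_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec("total_duration=([0-9.eE+-]+) sampling_rate=([0-9.eE+-]+)", hdr))[[1L]]
  if (length(m) != 3L) stopf("missing header line in %s", path)
  ev <- utils::read.csv(path, skip = 1L, stringsAsFactors = FALSE)
  event_table(ev, as.numeric(m[2L]), as.numeric(m[3L]))
}
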