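#' CR latency windows
#'
#' The valid CR period runs from 121 ms after CS onset (excluding
#' short-latency alpha/startle responses) to 3292 ms (8 ms before US onset,
#' so the unconditioned reflex never contaminates CR scoring). It is divided
#' into short- (121-1180 ms), middle- (1181-2240 ms) and late-latency
#' (2241-3292 ms) windows. The printed integer bounds leave the open
#' intervals (1180, 1181) and (2240, 2241) unassigned; membership is
#' therefore evaluated as `[121, 1181)`, `[1181, 2241)` and `[2241, 3292]`,
#' which partitions the valid period exactly while agreeing with the printed
#' bounds at every integer millisecond.
#'
#' @param valid,short,middle,long interval bounds in ms.
#' @return A list of class `"latency_windows"`.
#' @export
latency_windows <- function(valid = c(121, 3292),
                            short = c(121, 1180),
                            middle = c(1181, 2240),
                            long = c(2241, 3292)) {
  w <- list(valid = as.numeric(valid), short = as.numeric(short),
            middle = as.numeric(middle), long = as.numeric(long))
  ok <- short[1] == valid[1] && long[2] == valid[2] &&
    short[2] < middle[1] && middle[2] < long[1] &&
    all(vapply(w, function(v) v[1] < v[2], logical(1)))
  if (!ok) {
    abort("latency windows must be ordered, disjoint and span the valid CR period.",
          class = "debcr_config_error")
  }
  structure(w, class = "latency_windows")
}

#' Which latency window contains an onset time
#'
#' @param onset_ms numeric vector of epoch onsets (ms from CS onset).
#' @param windows a [latency_windows()] object.
#' @return Character vector: `"short"`, `"middle"`, `"long"`, or `NA` when
#'   the onset falls outside the valid CR period.
#' @export
window_of <- function(onset_ms, windows = latency_windows()) {
  out <- rep(NA_character_, length(onset_ms))
  out[onset_ms >= windows$short[1] & onset_ms < windows$middle[1]] <- "short"
  out[onset_ms >= windows$middle[1] & onset_ms < windows$long[1]] <- "middle"
  out[onset_ms >= windows$long[1] & onset_ms <= windows$long[2]] <- "long"
  out
}

#' Detect supra-threshold epochs
#'
#' Finds maximal contiguous runs of samples whose standardized amplitude
#' strictly exceeds the trial threshold, keeps those whose onset lies in
#' `interval_ms` and whose duration strictly exceeds `min_duration_ms`
#' (">10 ms" is strict: at 10 kHz a run must span at least 101 samples).
#' Duration is the run length times the sample period.
#'
#' @param st a [standardize()]d trace.
#' @param interval_ms interval the epoch onset must fall in (default the
#'   valid CR period 121-3292 ms). Closed on both ends unless
#'   `right_open = TRUE`.
#' @param min_duration_ms minimum duration in ms, exclusive (default 10).
#' @param right_open if `TRUE` the interval is `[lo, hi)`; used for the
#'   baseline window, which excludes CS onset itself.
#'
#' @return A tibble ordered by onset: `onset_ms`, `offset_ms`,
#'   `duration_ms`, `peak_z`, `peak_time_ms` (ties at the peak broken by
#'   earliest time).
#' @export
detect_epochs <- function(st, interval_ms = c(121, 3292),
                          min_duration_ms = 10, right_open = FALSE) {
  stopifnot(inherits(st, "standardized_trace"))
  t <- trace_times(st)
  dt <- .ms_per_s / st$fs
  if (interval_ms[1] < t[1] - 1e-6 ||
      interval_ms[2] > t[length(t)] + dt + 1e-6) {
    abort("`interval_ms` lies outside the trace span.",
          class = "debcr_config_error")
  }
  above <- st$z > st$threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths * dt > min_duration_ms)
  starts <- starts[keep]; ends <- ends[keep]
  onset <- t[starts]
  sel <- if (right_open) {
    onset >= interval_ms[1] & onset < interval_ms[2]
  } else {
    onset >= interval_ms[1] & onset <= interval_ms[2]
  }
  starts <- starts[sel]; ends <- ends[sel]; onset <- onset[sel]
  if (length(starts) == 0) {
    return(tibble(onset_ms = numeric(), offset_ms = numeric(),
                  duration_ms = numeric(), peak_z = numeric(),
                  peak_time_ms = numeric()))
  }
  peak_i <- vapply(seq_along(starts), function(k) {
    i <- starts[k]:ends[k]
    i[which.max(st$z[i])]
  }, integer(1))
  dur <- (ends - starts + 1L) * dt
  tibble(onset_ms = onset, offset_ms = onset + dur, duration_ms = dur,
         peak_z = st$z[peak_i], peak_time_ms = t[peak_i])
}

#' Flag hyperactivity trials
#'
#' A trial is hyperactive - and excluded from all further analysis - when
#' the standardized EMG exceeds the trial threshold for more than
#' `min_duration_ms` during the pre-CS baseline period.
#'
#' @inheritParams detect_epochs
#' @return Logical flag.
#' @export
flag_hyperactive <- function(st, min_duration_ms = 10) {
  ep <- detect_epochs(st, interval_ms = st$baseline_window_ms,
                      min_duration_ms = min_duration_ms, right_open = TRUE)
  nrow(ep) > 0
}

#' Classify one trial
#'
#' Applies the full trial-scoring rule: hyperactive trials are invalidated
#' and not scored; otherwise supra-threshold epochs with onset in the valid
#' CR period (121-3292 ms) are detected, each latency window is flagged as
#' containing a CR when some epoch's onset falls in it (an epoch straddling
#' a boundary belongs to its onset window; a trial can be a CR trial in
#' several windows via distinct epochs), and per-window CR metrics are
#' extracted with [extract_metrics()].
#'
#' @param st a [standardize()]d trace.
#' @param windows a [latency_windows()] object.
#' @param min_duration_ms epoch duration gate in ms, exclusive (default 10).
#' @param peak_scope `"epochs"` (default): peak amplitude/latency are taken
#'   over the detected epochs starting in the window; `"window"`: over the
#'   window's entire span (the looser reading of "during the CR period").
#'
#' @return A list of class `"trial_classification"`: `is_hyperactive`,
#'   `is_valid`, `reason` (`NA`, `"hyperactive"` or `"degenerate"`),
#'   `epochs` (tibble), `cr` (named logical, short/middle/long), `metrics`
#'   (tibble with `window`, `start_latency_ms`, `peak_latency_ms`,
#'   `peak_amplitude_z`, one row per flagged window).
#' @export
classify_trial <- function(st, windows = latency_windows(),
                           min_duration_ms = 10,
                           peak_scope = c("epochs", "window")) {
  peak_scope <- match.arg(peak_scope)
  wn <- c("short", "middle", "long")
  if (flag_hyperactive(st, min_duration_ms)) {
    return(structure(
      list(is_hyperactive = TRUE, is_valid = FALSE, reason = "hyperactive",
           epochs = detect_epochs(st, windows$valid, min_duration_ms)[0, ],
           cr = stats::setNames(rep(NA, 3), wn),
           metrics = .empty_metrics()),
      class = "trial_classification"
    ))
  }
  ep <- detect_epochs(st, interval_ms = windows$valid,
                      min_duration_ms = min_duration_ms)
  epw <- window_of(ep$onset_ms, windows)
  cr <- stats::setNames(wn %in% epw, wn)
  metrics <- dplyr::bind_rows(lapply(wn[cr], function(w) {
    extract_metrics(st, ep[which(epw == w), , drop = FALSE], w,
                    windows = windows, peak_scope = peak_scope)
  }))
  if (nrow(metrics) == 0) metrics <- .empty_metrics()
  structure(
    list(is_hyperactive = FALSE, is_valid = TRUE, reason = NA_character_,
         epochs = ep, cr = cr, metrics = metrics),
    class = "trial_classification"
  )
}

.empty_metrics <- function() {
  tibble(window = character(), start_latency_ms = numeric(),
         peak_latency_ms = numeric(), peak_amplitude_z = numeric())
}

#' Per-window CR metrics
#'
#' For the epochs whose onset lies in window `w`: the CR start latency is
#' the onset of the earliest such epoch; the CR peak amplitude is the
#' maximum standardized amplitude over those epochs (or over the whole
#' window span when `peak_scope = "window"`), and the CR peak latency is
#' the time of that maximum, ties broken by earliest time.
#'
#' @param st a [standardize()]d trace.
#' @param epochs tibble of epochs (as from [detect_epochs()]) whose onsets
#'   lie in window `w`; must be non-empty.
#' @param w window name (`"short"`, `"middle"`, `"long"`).
#' @inheritParams classify_trial
#' @return One-row tibble: `window`, `start_latency_ms`, `peak_latency_ms`,
#'   `peak_amplitude_z`.
#' @export
extract_metrics <- function(st, epochs, w, windows = latency_windows(),
                            peak_scope = c("epochs", "window")) {
  peak_scope <- match.arg(peak_scope)
  if (nrow(epochs) == 0) {
    abort("`extract_metrics()` called with no epoch in the window.",
          class = "debcr_contract_error")
  }
  start <- min(epochs$onset_ms)
  t <- trace_times(st)
  dt <- .ms_per_s / st$fs
  if (peak_scope == "epochs") {
    idx <- unlist(lapply(seq_len(nrow(epochs)), function(k) {
      which(t >= epochs$onset_ms[k] & t < epochs$offset_ms[k])
    }))
  } else {
    span <- windows[[w]]
    idx <- which(t >= span[1] & t <= span[2])
  }
  pk <- idx[which.max(st$z[idx])]   # which.max -> earliest tie wins
  tibble(window = w, start_latency_ms = start, peak_latency_ms = t[pk],
         peak_amplitude_z = st$z[pk])
}

#' Score one raw trace end to end
#'
#' Runs [process_trace()] then [classify_trial()], converting a degenerate
#' (flat-baseline) standardization failure into an invalid classification
#' with `reason = "degenerate"` rather than an error.
#'
#' @inheritParams process_trace
#' @inheritParams classify_trial
#' @return A `"trial_classification"`.
#' @export
score_trace <- function(trace, windows = latency_windows(), tau_ms = 1,
                        method = c("exponential", "boxcar"),
                        baseline_window_ms = c(-300, 0), threshold_k = 4,
                        min_duration_ms = 10,
                        peak_scope = c("epochs", "window")) {
  st <- tryCatch(
    process_trace(trace, tau_ms = tau_ms, method = method,
                  baseline_window_ms = baseline_window_ms,
                  threshold_k = threshold_k),
    debcr_degenerate_trial = function(e) NULL
  )
  if (is.null(st)) {
    wn <- c("short", "middle", "long")
    return(structure(
      list(is_hyperactive = FALSE, is_valid = FALSE, reason = "degenerate",
           epochs = .empty_metrics()[, 0], cr = stats::setNames(rep(NA, 3), wn),
           metrics = .empty_metrics()),
      class = "trial_classification"
    ))
  }
  classify_trial(st, windows = windows, min_duration_ms = min_duration_ms,
                 peak_scope = peak_scope)
}

#' Tabulate trial classifications
#'
#' Flattens a list of [classify_trial()] results into the per-trial wide
#' table written to disk by the pipeline: one row per trial with validity
#' flags and, per window, the CR flag and metrics.
#'
#' @param classifications list of `"trial_classification"` objects, in
#'   schedule order.
#' @param schedule the session schedule tibble the trials were recorded
#'   under (see [build_session_schedule()]).
#' @return A tibble with columns `trial`, `block`, `trial_type`,
#'   `is_valid`, `is_hyperactive`, `is_degenerate`, and for each window `w`
#'   in short/middle/long: `cr_<w>`, `start_<w>`, `peaklat_<w>`, `amp_<w>`
#'   (latencies in ms, amplitude in z units, `NA` where no CR).
#' @export
classification_table <- function(classifications, schedule) {
  stopifnot(length(classifications) == nrow(schedule))
  wn <- c("short", "middle", "long")
  rows <- lapply(seq_along(classifications), function(i) {
    cl <- classifications[[i]]
    out <- list(trial = schedule$trial[i], block = schedule$block[i],
                trial_type = schedule$trial_type[i],
                is_valid = cl$is_valid,
                is_hyperactive = isTRUE(cl$is_hyperactive),
                is_degenerate = identical(cl$reason, "degenerate"))
    for (w in wn) {
      m <- cl$metrics[cl$metrics$window == w, , drop = FALSE]
      out[[paste0("cr_", w)]] <- if (cl$is_valid) isTRUE(cl$cr[[w]]) else NA
      out[[paste0("start_", w)]] <-
        if (nrow(m)) m$start_latency_ms else NA_real_
      out[[paste0("peaklat_", w)]] <-
        if (nrow(m)) m$peak_latency_ms else NA_real_
      out[[paste0("amp_", w)]] <-
        if (nrow(m)) m$peak_amplitude_z else NA_real_
    }
    as_tibble(out)
  })
  dplyr::bind_rows(rows)
}
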