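#' Stimulus timing for one dEBC trial
#'
#' Returns the conditioned-stimulus / unconditioned-stimulus timing of a
#' long-delay eyeblink conditioning trial, with CS onset as the time origin
#' (t = 0). In the default paradigm the CS is a 3350-ms tone, the US a 50-ms
#' periorbital shock starting 3300 ms after CS onset, so that the US
#' co-terminates with the CS. CS-alone probe trials carry no US.
#'
#' @param trial_type `"paired"` (CS followed by US) or `"cs_alone"`.
#' @param cs_duration_ms CS duration in ms (default 3350).
#' @param isi_ms inter-stimulus interval, CS onset to US onset, in ms
#'   (default 3300).
#' @param us_duration_ms US duration in ms (default 50).
#'
#' @return A list of class `"stimulus_timing"` with elements `cs_onset_ms`
#'   (always 0), `cs_duration_ms`, `us_onset_ms` and `us_duration_ms`
#'   (both `NA` for CS-alone trials).
#'
#' @examples
#' stimulus_times("paired")
#' stimulus_times("cs_alone")
#' @export
stimulus_times <- function(trial_type = c("paired", "cs_alone"),
                           cs_duration_ms = 3350,
                           isi_ms = 3300,
                           us_duration_ms = 50) {
  trial_type <- match.arg(trial_type)
  if (cs_duration_ms <= 0) {
    abort("`cs_duration_ms` must be > 0.", class = "debcr_config_error")
  }
  if (trial_type == "paired") {
    if (us_duration_ms <= 0) {
      abort("`us_duration_ms` must be > 0 on paired trials.",
            class = "debcr_config_error")
    }
    if (isi_ms + us_duration_ms != cs_duration_ms) {
      abort(paste0(
        "US must co-terminate with the CS: isi_ms + us_duration_ms (",
        isi_ms + us_duration_ms, ") != cs_duration_ms (", cs_duration_ms, ")."
      ), class = "debcr_config_error")
    }
    us_onset <- isi_ms
    us_dur <- us_duration_ms
  } else {
    us_onset <- NA_real_
    us_dur <- NA_real_
  }
  structure(
    list(cs_onset_ms = 0, cs_duration_ms = cs_duration_ms,
         us_onset_ms = us_onset, us_duration_ms = us_dur),
    class = "stimulus_timing"
  )
}

#' Session design parameters for the long-dEBC paradigm
#'
#' Encodes the daily-session structure: 12 blocks of 10 trials (9 CS-US
#' paired + 1 CS-alone each, 120 trials total) at inter-trial intervals
#' drawn from 25-40 s, repeated over 7 daily acquisition sessions.
#'
#' @param n_sessions number of daily sessions (default 7).
#' @param n_blocks blocks per session (default 12).
#' @param trials_per_block trials per block (default 10).
#' @param paired_per_block CS-US paired trials per block (default 9); the
#'   remainder are CS-alone trials.
#' @param iti_range_s inter-trial interval range in seconds (default
#'   `c(25, 40)`).
#' @param cs_duration_ms,isi_ms,us_duration_ms stimulus timing, see
#'   [stimulus_times()].
#' @param cs_tone CS tone metadata (frequency, level); carried in manifests,
#'   unused by the analysis.
#'
#' @return A list of class `"design_params"`.
#' @examples
#' design_params()
#' @export
design_params <- function(n_sessions = 7,
                          n_blocks = 12,
                          trials_per_block = 10,
                          paired_per_block = 9,
                          iti_range_s = c(25, 40),
                          cs_duration_ms = 3350,
                          isi_ms = 3300,
                          us_duration_ms = 50,
                          cs_tone = list(freq_hz = 3000, level_db = 85)) {
  chk <- function(ok, msg) if (!ok) abort(msg, class = "debcr_config_error")
  chk(n_sessions >= 1, "`n_sessions` must be >= 1.")
  chk(n_blocks >= 1, "`n_blocks` must be >= 1.")
  chk(trials_per_block >= 1, "`trials_per_block` must be >= 1.")
  chk(paired_per_block >= 0 && paired_per_block <= trials_per_block,
      "`paired_per_block` must be between 0 and `trials_per_block`.")
  chk(length(iti_range_s) == 2 && iti_range_s[1] <= iti_range_s[2] &&
        iti_range_s[1] > 0,
      "`iti_range_s` must be a positive interval with lower <= upper.")
  # validates co-termination up front
  stimulus_times("paired", cs_duration_ms, isi_ms, us_duration_ms)
  structure(
    list(n_sessions = n_sessions, n_blocks = n_blocks,
         trials_per_block = trials_per_block,
         paired_per_block = paired_per_block,
         iti_range_s = as.numeric(iti_range_s),
         cs_duration_ms = cs_duration_ms, isi_ms = isi_ms,
         us_duration_ms = us_duration_ms, cs_tone = cs_tone),
    class = "design_params"
  )
}

#' Generate one session's trial schedule
#'
#' Builds the ordered trial list for a single daily session. Within each
#' block the positions of the CS-alone trials are randomized uniformly
#' (the field-standard practice; placement is otherwise unconstrained),
#' and ITIs are drawn continuous-uniform from `iti_range_s`.
#'
#' @param params a [design_params()] object.
#' @param seed optional integer seed for reproducible schedules.
#'
#' @return A tibble with one row per trial: `trial` (1-based index within
#'   the session), `block`, `trial_type` (`"paired"`/`"cs_alone"`), `iti_s`,
#'   and the stimulus timing columns `cs_duration_ms`, `us_onset_ms`,
#'   `us_duration_ms` (`NA` on CS-alone trials).
#'
#' @examples
#' sched <- build_session_schedule(design_params(), seed = 1)
#' table(sched$trial_type)
#' @export
build_session_schedule <- function(params = design_params(), seed = NULL) {
  if (!inherits(params, "design_params")) {
    abort("`params` must be created by `design_params()`.",
          class = "debcr_config_error")
  }
  if (!is.null(seed)) set.seed(seed)
  tpb <- params$trials_per_block
  n_alone <- tpb - params$paired_per_block
  blocks <- lapply(seq_len(params$n_blocks), function(b) {
    type <- rep("paired", tpb)
    if (n_alone > 0) {
      type[sample.int(tpb, n_alone)] <- "cs_alone"
    }
    type
  })
  trial_type <- unlist(blocks)
  n <- length(trial_type)
  timing_p <- stimulus_times("paired", params$cs_duration_ms, params$isi_ms,
                             params$us_duration_ms)
  tibble(
    trial = seq_len(n),
    block = rep(seq_len(params$n_blocks), each = tpb),
    trial_type = trial_type,
    iti_s = runif(n, params$iti_range_s[1], params$iti_range_s[2]),
    cs_duration_ms = params$cs_duration_ms,
    us_onset_ms = ifelse(trial_type == "paired", timing_p$us_onset_ms,
                         NA_real_),
    us_duration_ms = ifelse(trial_type == "paired", timing_p$us_duration_ms,
                            NA_real_)
  )
}
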