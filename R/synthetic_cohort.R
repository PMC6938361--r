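#' Band-limited EMG noise model
#'
#' Baseline orbicularis oculi EMG is emulated as Gaussian white noise
#' band-pass filtered to the acquisition band (default 100-1000 Hz, a
#' second-order Butterworth applied forward-backward), then full-wave
#' rectified to serve as the non-negative raw carrier onto which response
#' bursts are added. The analysis pipeline never sees the filter - it is an
#' acquisition property of the simulated hardware, not an analysis step.
#'
#' @param sigma SD of the white noise before filtering, raw signal units
#'   (default 1; the whole pipeline is scale-invariant).
#' @param band_hz pass band in Hz (default `c(100, 1000)`).
#' @param fs sampling rate in Hz (default 10000).
#' @return A list of class `"noise_model"`.
#' @export
noise_model <- function(sigma = 1, band_hz = c(100, 1000), fs = 10000) {
  if (sigma < 0) abort("`sigma` must be >= 0.", class = "debcr_config_error")
  if (band_hz[1] <= 0 || band_hz[2] >= fs / 2 || band_hz[1] >= band_hz[2]) {
    abort("`band_hz` must lie within (0, fs/2).", class = "debcr_config_error")
  }
  structure(list(sigma = sigma, band_hz = as.numeric(band_hz), fs = fs),
            class = "noise_model")
}

# rectified band-limited Gaussian carrier
.gen_carrier <- function(n, noise) {
  if (noise$sigma == 0) return(numeric(n))
  bf <- signal::butter(2, noise$band_hz / (noise$fs / 2), type = "pass")
  abs(as.numeric(signal::filtfilt(bf, rnorm(n, 0, noise$sigma))))
}

#' Calibrate baseline envelope statistics of a noise model
#'
#' Burst amplitudes throughout the simulator are specified in units of the
#' baseline envelope SD (the same units the detection threshold lives in).
#' This helper measures the mean and SD of the integrated rectified noise
#' envelope by simulation, so amplitudes in "baseline SDs" can be converted
#' to raw envelope units. Consumes random numbers from the current RNG
#' stream.
#'
#' @param noise a [noise_model()].
#' @param tau_ms integrator time constant used by the analysis (default 1).
#' @param n_ms length of calibration noise in ms (default 20000).
#' @return List with `mean` and `sd` of the baseline envelope (raw units).
#' @export
calibrate_envelope <- function(noise, tau_ms = 1, n_ms = 20000) {
  n <- round(n_ms * noise$fs / .ms_per_s)
  env <- integrate_envelope(raw_trace(.gen_carrier(n, noise), fs = noise$fs),
                            tau_ms = tau_ms)$samples
  drop <- min(length(env), round(10 * tau_ms * noise$fs / .ms_per_s))
  env <- env[-seq_len(drop)]   # discard integrator settling
  list(mean = mean(env), sd = sd(env))
}

# unimodal burst kernel: half-cosine rise to 1 at peak_frac*duration,
# half-cosine decay to 0 at duration, cubed to give the sharp apex of a
# blink burst; compact support, peak exactly 1.
.raised_cosine <- function(duration_ms, peak_frac, dt, power = 3) {
  n <- max(2L, round(duration_ms / dt))
  np <- min(max(1L, round(peak_frac * n)), n - 1L)
  rise <- (1 - cos(pi * seq(0, 1, length.out = np))) / 2
  decay <- (1 + cos(pi * seq(0, 1, length.out = n - np + 1L))) / 2
  c(rise, decay[-1])^power
}

# flat-top kernel for hyperactive baseline bursts (see learning_model())
.trapezoid <- function(duration_ms, ramp_ms, dt) {
  n <- max(3L, round(duration_ms / dt))
  nr <- max(1L, round(ramp_ms / dt))
  c(seq(0, 1, length.out = nr), rep(1, max(0L, n - 2L * nr)),
    seq(1, 0, length.out = nr))
}

# add kernel*amp to x starting at sample i0, truncating at the trace end
.add_burst <- function(x, i0, kernel, amp) {
  i0 <- max(1L, i0)
  idx <- i0:min(length(x), i0 + length(kernel) - 1L)
  x[idx] <- x[idx] + amp * kernel[seq_along(idx)]
  x
}

#' Learning model for synthetic cohorts
#'
#' Declares, per treatment group, how conditioned responding evolves over
#' daily sessions, and the trial-level event parameters. The per-window CR
#' probability follows a logistic acquisition curve
#' `p(s) = p_max / (1 + exp(-k (s - s0)))` with asymptote `p_max(group,
#' window)`, slope `k(group)` and inflection session `s0(group)`. All burst
#' amplitudes are in baseline-envelope-SD units (the z scale the detector
#' operates on).
#'
#' The default group parameters are illustrative, not fitted: the source
#' study reports its group curves only graphically, so the defaults are
#' chosen to reproduce the qualitative orderings it describes - saline
#' above PCP in every window, PCP-eNpHR above PCP-EYFP, and an earlier
#' long-window peak latency under PCP.
#'
#' @param groups named list of per-group parameter lists, each with
#'   `p_max` (named numeric, short/middle/long, summing to <= 1), `k`,
#'   `s0`, `onset_mean` (named numeric, ms; mean CR burst onset per
#'   window), `amp_log_mean`, `amp_log_sd` (log-normal CR peak amplitude,
#'   baseline-SD units).
#' @param onset_sd_ms SD of the CR burst onset around its window mean (ms).
#' @param burst_duration_ms,burst_peak_frac CR burst kernel: duration and
#'   the fraction of it at which the peak occurs (fast rise, slower decay).
#' @param spont_rate_hz Poisson rate of spontaneous blinks per second.
#' @param spont_amp_log_mean,spont_amp_log_sd,spont_duration_ms spontaneous
#'   blink burst parameters.
#' @param hyper_prob probability a trial carries an injected baseline burst
#'   making it hyperactive by construction.
#' @param hyper_amp_sd,hyper_duration_ms hyperactive burst amplitude
#'   (baseline SDs) and duration (ms). The default 40-SD, 14-ms flat-top
#'   burst is deliberately short and tall: the trial threshold is z-scored
#'   against the same baseline that contains the burst, so a long or
#'   moderate burst inflates its own baseline SD and deflates itself below
#'   threshold, while this shape is reliably flagged.
#' @param ur_amp_log_mean,ur_amp_log_sd,ur_delay_ms,ur_duration_ms
#'   unconditioned-response burst after the US on paired trials.
#' @param threshold_k nominal detection threshold in baseline SDs; used
#'   only to record ground-truth start latencies (the time the injected
#'   burst alone first exceeds `threshold_k` calibration SDs).
#' @return A list of class `"learning_model"`.
#' @export
learning_model <- function(
    groups = list(
      saline     = list(p_max = c(short = 0.15, middle = 0.30, long = 0.45),
                        k = 1.2, s0 = 3.0,
                        onset_mean = c(short = 600, middle = 1700, long = 2750),
                        amp_log_mean = log(12), amp_log_sd = 0.30),
      PCP        = list(p_max = c(short = 0.05, middle = 0.10, long = 0.12),
                        k = 0.8, s0 = 4.0,
                        onset_mean = c(short = 560, middle = 1650, long = 2450),
                        amp_log_mean = log(8), amp_log_sd = 0.30),
      PCP_eNpHR  = list(p_max = c(short = 0.10, middle = 0.20, long = 0.35),
                        k = 1.0, s0 = 3.5,
                        onset_mean = c(short = 590, middle = 1680, long = 2700),
                        amp_log_mean = log(11), amp_log_sd = 0.30),
      PCP_EYFP   = list(p_max = c(short = 0.05, middle = 0.10, long = 0.14),
                        k = 0.8, s0 = 4.0,
                        onset_mean = c(short = 560, middle = 1650, long = 2480),
                        amp_log_mean = log(8), amp_log_sd = 0.30)
    ),
    onset_sd_ms = 150,
    burst_duration_ms = 200, burst_peak_frac = 0.15,
    spont_rate_hz = 0.01,
    spont_amp_log_mean = log(8), spont_amp_log_sd = 0.3,
    spont_duration_ms = 80,
    hyper_prob = 0.02, hyper_amp_sd = 40, hyper_duration_ms = 14,
    ur_amp_log_mean = log(25), ur_amp_log_sd = 0.2,
    ur_delay_ms = 5, ur_duration_ms = 120,
    threshold_k = 4) {
  wn <- c("short", "middle", "long")
  win <- latency_windows()
  for (g in names(groups)) {
    gr <- groups[[g]]
    p <- gr$p_max[wn]
    if (anyNA(p) || any(p < 0) || any(p > 1) || sum(p) > 1) {
      abort(paste0("group '", g, "': `p_max` must give short/middle/long ",
                   "probabilities in [0,1] with sum <= 1."),
            class = "debcr_config_error")
    }
    om <- gr$onset_mean[wn]
    for (w in wn) {
      if (is.na(om[[w]]) || om[[w]] < win[[w]][1] || om[[w]] > win[[w]][2]) {
        abort(paste0("group '", g, "': `onset_mean[", w,
                     "]` must lie inside the ", w, " window."),
              class = "debcr_config_error")
      }
    }
  }
  if (spont_rate_hz < 0 || hyper_prob < 0 || hyper_prob > 1) {
    abort("`spont_rate_hz` must be >= 0 and `hyper_prob` in [0,1].",
          class = "debcr_config_error")
  }
  structure(
    list(groups = groups, onset_sd_ms = onset_sd_ms,
         burst_duration_ms = burst_duration_ms,
         burst_peak_frac = burst_peak_frac,
         spont_rate_hz = spont_rate_hz,
         spont_amp_log_mean = spont_amp_log_mean,
         spont_amp_log_sd = spont_amp_log_sd,
         spont_duration_ms = spont_duration_ms,
         hyper_prob = hyper_prob, hyper_amp_sd = hyper_amp_sd,
         hyper_duration_ms = hyper_duration_ms,
         ur_amp_log_mean = ur_amp_log_mean, ur_amp_log_sd = ur_amp_log_sd,
         ur_delay_ms = ur_delay_ms, ur_duration_ms = ur_duration_ms,
         threshold_k = threshold_k),
    class = "learning_model"
  )
}

#' Logistic CR acquisition probability
#'
#' `p = p_max / (1 + exp(-k (session - s0)))`: at the inflection session
#' `s0` (or with zero slope) the probability is `p_max / 2`; it approaches
#' `p_max` for late sessions when `k > 0`.
#'
#' @param model a [learning_model()].
#' @param group group name (must exist in the model).
#' @param window `"short"`, `"middle"` or `"long"`.
#' @param session session index, >= 1.
#' @return Probability in `[0, p_max]`.
#' @examples
#' cr_probability(learning_model(), "saline", "long", 7)
#' @export
cr_probability <- function(model, group, window, session) {
  stopifnot(inherits(model, "learning_model"))
  gr <- model$groups[[group]]
  if (is.null(gr)) {
    abort(paste0("unknown group '", group, "'."), class = "debcr_config_error")
  }
  if (!window %in% c("short", "middle", "long")) {
    abort(paste0("unknown window '", window, "'."),
          class = "debcr_config_error")
  }
  if (any(session < 1)) {
    abort("`session` must be >= 1.", class = "debcr_config_error")
  }
  gr$p_max[[window]] / (1 + exp(-gr$k * (session - gr$s0)))
}

# truncated-normal draw via inverse CDF
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  qnorm(runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd)), mean, sd)
}

#' Simulate one trial's EMG trace with ground truth
#'
#' Builds the trial as rectified band-limited noise plus injected bursts:
#' at most one CR burst (window sampled from the per-window acquisition
#' probabilities, onset truncated-normal within the window), an
#' unconditioned-response burst after the US on paired trials, Poisson
#' spontaneous blinks, and - with probability `hyper_prob` - a baseline
#' burst making the trial hyperactive by construction. Burst injection is
#' at the envelope level of the rectified carrier: the analysis only sees
#' envelope statistics, so no biophysical motor-unit model is attempted.
#'
#' @param spec one row of a [build_session_schedule()] tibble (or any list
#'   with `trial_type`, `us_onset_ms`, `cs_duration_ms`).
#' @param model a [learning_model()].
#' @param group,session which group/session the trial belongs to.
#' @param noise a [noise_model()].
#' @param calib envelope calibration from [calibrate_envelope()]; computed
#'   on the fly when `NULL` (one extra RNG draw).
#' @param t0_ms trace start in ms (default -300); the trace runs to CS
#'   offset.
#' @return A list with `trace` (a [raw_trace()]) and `truth`: list with
#'   `is_hyperactive`, `cr_window` (`NA` or window name), `cr_onset_ms`
#'   (burst support onset), `cr_start_ms` (nominal supra-threshold start:
#'   first time the noiseless burst exceeds `threshold_k` calibration SDs),
#'   `cr_peak_time_ms`, `cr_amp_sd` (peak in baseline-SD units),
#'   `ur_present`, `spont_times_ms`.
#' @export
simulate_trial <- function(spec, model, group, session,
                           noise = noise_model(), calib = NULL,
                           t0_ms = -300) {
  stopifnot(inherits(model, "learning_model"))
  end_ms <- spec$cs_duration_ms
  if (t0_ms > -300 || end_ms < 3292) {
    abort("trace span must cover at least [-300, 3292] ms.",
          class = "debcr_config_error")
  }
  dt <- .ms_per_s / noise$fs
  n <- round((end_ms - t0_ms) / dt)
  if (is.null(calib)) calib <- calibrate_envelope(noise)
  x <- .gen_carrier(n, noise)
  win <- latency_windows()
  wn <- c("short", "middle", "long")
  to_i <- function(t_ms) as.integer(round((t_ms - t0_ms) / dt)) + 1L

  # hyperactive baseline burst
  is_hyper <- runif(1) < model$hyper_prob
  if (is_hyper) {
    k <- .trapezoid(model$hyper_duration_ms, 1, dt)
    on <- runif(1, -280, -60)
    x <- .add_burst(x, to_i(on), k, model$hyper_amp_sd * calib$sd)
  }

  # at most one CR burst; window drawn from the acquisition probabilities
  p <- vapply(wn, function(w) cr_probability(model, group, w, session),
              numeric(1))
  u <- runif(1)
  cw <- NA_character_
  cum <- cumsum(p)
  hit <- which(u < cum)
  if (length(hit)) cw <- wn[hit[1]]
  cr_onset <- cr_start <- cr_peak_t <- cr_amp <- NA_real_
  if (!is.na(cw)) {
    gr <- model$groups[[group]]
    lo <- win[[cw]][1]
    hi <- min(win[[cw]][2], win$valid[2]) - 45  # keep nominal start inside
    cr_onset <- .rtruncnorm(1, gr$onset_mean[[cw]], model$onset_sd_ms, lo, hi)
    cr_amp <- exp(rnorm(1, gr$amp_log_mean, gr$amp_log_sd))
    kern <- .raised_cosine(model$burst_duration_ms, model$burst_peak_frac, dt)
    # nominal supra-threshold start of the injected burst alone
    over <- which(kern * cr_amp > model$threshold_k)
    cr_start <- if (length(over)) cr_onset + (over[1] - 1) * dt else NA_real_
    cr_peak_t <- cr_onset + (which.max(kern) - 1) * dt
    x <- .add_burst(x, to_i(cr_onset), kern, cr_amp * calib$sd)
  }

  # spontaneous blinks (Poisson over the whole span)
  span_s <- (end_ms - t0_ms) / .ms_per_s
  n_sp <- rpois(1, model$spont_rate_hz * span_s)
  spont <- sort(runif(n_sp, t0_ms, end_ms - model$spont_duration_ms))
  if (n_sp > 0) {
    ks <- .raised_cosine(model$spont_duration_ms, 0.3, dt)
    for (ton in spont) {
      amp <- exp(rnorm(1, model$spont_amp_log_mean, model$spont_amp_log_sd))
      x <- .add_burst(x, to_i(ton), ks, amp * calib$sd)
    }
  }

  # UR after the US on paired trials
  ur <- identical(spec$trial_type, "paired") && !is.na(spec$us_onset_ms)
  if (ur) {
    ku <- .raised_cosine(model$ur_duration_ms, 0.25, dt)
    amp <- exp(rnorm(1, model$ur_amp_log_mean, model$ur_amp_log_sd))
    x <- .add_burst(x, to_i(spec$us_onset_ms + model$ur_delay_ms), ku,
                    amp * calib$sd)
  }

  list(
    trace = raw_trace(x, fs = noise$fs, t0_ms = t0_ms),
    truth = list(is_hyperactive = is_hyper, cr_window = cw,
                 cr_onset_ms = cr_onset, cr_start_ms = cr_start,
                 cr_peak_time_ms = cr_peak_t, cr_amp_sd = cr_amp,
                 ur_present = ur, spont_times_ms = spont)
  )
}

#' Simulate a full session for one subject
#'
#' @param schedule a [build_session_schedule()] tibble.
#' @inheritParams simulate_trial
#' @return List with `schedule`, `trials` (list of [simulate_trial()]
#'   results) and `calib`.
#' @export
simulate_session <- function(schedule, model, group, session,
                             noise = noise_model(), calib = NULL) {
  if (is.null(calib)) calib <- calibrate_envelope(noise)
  trials <- lapply(seq_len(nrow(schedule)), function(i) {
    simulate_trial(schedule[i, ], model, group, session, noise, calib)
  })
  list(schedule = schedule, trials = trials, calib = calib)
}

#' Simulate a multi-group cohort
#'
#' Generates the full subjects x sessions x trials dataset with per-trial
#' ground truth. The default group sizes follow the source study's design
#' (saline 13, PCP 10, PCP-eNpHR 12, PCP-EYFP 16). All randomness flows
#' from `seed`; identical seeds give identical datasets.
#'
#' @param design a [design_params()].
#' @param model a [learning_model()].
#' @param group_sizes named integer vector of subjects per group; names
#'   must exist in `model$groups`.
#' @param noise a [noise_model()].
#' @param seed integer seed (stored in the dataset manifest).
#' @param sessions session indices to simulate (default all
#'   `1:design$n_sessions`).
#' @param keep_traces keep raw traces in memory (`TRUE`, default) or drop
#'   them after recording ground truth (`FALSE`; use [run_pipeline()] for
#'   memory-light simulate-and-score runs).
#' @return A list of class `"debcr_dataset"`: `format_version`, `seed`,
#'   `design`, `model`, `group_sizes`, `fs`, `t0_ms`, `manifest` (tibble,
#'   one row per trial: subject, group, session, trial, block, trial_type,
#'   iti_s, us_onset_ms, us_duration_ms, cs_duration_ms, trace_key),
#'   `truth` (tibble, one row per trial), `traces` (named list of
#'   numeric matrices, samples x trials, keyed by `"<subject>_s<session>"`;
#'   `NULL` when `keep_traces = FALSE`).
#' @examples
#' \donttest{
#' ds <- simulate_cohort(group_sizes = c(saline = 2), sessions = 1, seed = 1)
#' dim(ds$traces[[1]])
#' }
#' @export
simulate_cohort <- function(design = design_params(),
                            model = learning_model(),
                            group_sizes = c(saline = 13, PCP = 10,
                                            PCP_eNpHR = 12, PCP_EYFP = 16),
                            noise = noise_model(),
                            seed = NULL,
                            sessions = seq_len(design$n_sessions),
                            keep_traces = TRUE) {
  if (any(group_sizes < 1)) {
    abort("`group_sizes` must be positive.", class = "debcr_config_error")
  }
  if (!all(names(group_sizes) %in% names(model$groups))) {
    abort("every name in `group_sizes` must be a model group.",
          class = "debcr_config_error")
  }
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    set.seed(seed)
  }
  calib <- calibrate_envelope(noise)
  manifest <- list(); truth <- list(); traces <- list()
  si <- 0L
  for (g in names(group_sizes)) {
    for (k in seq_len(group_sizes[[g]])) {
      si <- si + 1L
      subject <- sprintf("%s_%02d", g, k)
      for (s in sessions) {
        sched <- build_session_schedule(design)
        sess <- simulate_session(sched, model, g, s, noise, calib)
        key <- sprintf("%s_s%d", subject, s)
        manifest[[key]] <- dplyr::mutate(
          sched, subject = subject, group = g, session = s,
          trace_key = key, .before = 1
        )
        truth[[key]] <- dplyr::bind_rows(lapply(seq_along(sess$trials),
          function(i) {
            tr <- sess$trials[[i]]$truth
            tibble(subject = subject, group = g, session = s,
                   trial = sched$trial[i],
                   is_hyperactive = tr$is_hyperactive,
                   cr_window = tr$cr_window, cr_onset_ms = tr$cr_onset_ms,
                   cr_start_ms = tr$cr_start_ms,
                   cr_peak_time_ms = tr$cr_peak_time_ms,
                   cr_amp_sd = tr$cr_amp_sd, ur_present = tr$ur_present,
                   n_spont = length(tr$spont_times_ms))
          }))
        if (keep_traces) {
          traces[[key]] <- vapply(sess$trials,
                                  function(tr) tr$trace$samples,
                                  numeric(length(sess$trials[[1]]$trace$samples)))
        }
      }
    }
  }
  structure(
    list(format_version = 1L, seed = seed, design = design, model = model,
         group_sizes = group_sizes, fs = noise$fs, t0_ms = -300,
         noise = noise,
         manifest = dplyr::bind_rows(manifest),
         truth = dplyr::bind_rows(truth),
         traces = if (keep_traces) traces else NULL),
    class = "debcr_dataset"
  )
}

#' Summary-level cohort simulation for statistical calibration
#'
#' Draws per-subject, per-session CR percentages directly from the learning
#' model - `n_cr ~ Binomial(n_paired, p_subject)` with a per-subject random
#' offset on the probability scale - skipping trace synthesis. This is the
#' generator used for ANOVA type-I-error and power studies, where thousands
#' of replicate cohorts are needed and between-subject heterogeneity
#' matters; the trial-level generator keeps CR draws iid within a cell so
#' its ground truth converges to `cr_probability()` exactly.
#'
#' @inheritParams simulate_cohort
#' @param subject_sd SD of the per-subject probability offset (default
#'   0.03); 0 gives pure binomial sampling.
#' @param windows which windows to emit (default all three).
#' @param null_model if `TRUE`, every group uses the first group's
#'   parameters (no group effect; used for type-I error calibration).
#' @return A long-format cohort tibble: `group`, `subject`, `session`,
#'   `window`, `measure` (`"cr_percent"`), `value`.
#' @export
simulate_summary_cohort <- function(model = learning_model(),
                                    design = design_params(),
                                    group_sizes = c(saline = 13, PCP = 10,
                                                    PCP_eNpHR = 12,
                                                    PCP_EYFP = 16),
                                    sessions = seq_len(design$n_sessions),
                                    subject_sd = 0.03,
                                    windows = c("short", "middle", "long"),
                                    null_model = FALSE,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_paired <- design$n_blocks * design$paired_per_block
  cells <- expand.grid(session = sessions, window = windows,
                       stringsAsFactors = FALSE)
  rows <- list()
  for (g in names(group_sizes)) {
    g_eff <- if (null_model) names(model$groups)[1] else g
    p_cell <- mapply(function(s, w) cr_probability(model, g_eff, w, s),
                     cells$session, cells$window)
    for (k in seq_len(group_sizes[[g]])) {
      off <- rnorm(1, 0, subject_sd)
      p <- pmin(pmax(p_cell + off, 0), 1)
      rows[[length(rows) + 1L]] <- tibble(
        group = g, subject = sprintf("%s_%02d", g, k),
        session = cells$session, window = cells$window,
        measure = "cr_percent",
        value = 100 * rbinom(nrow(cells), n_paired, p) / n_paired
      )
    }
  }
  dplyr::bind_rows(rows)
}
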