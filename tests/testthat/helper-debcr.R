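# Shared fixtures and independent oracles, built in code at test time.

# Construct a standardized trace directly from a z vector, bypassing the
# processing chain; used to probe detection rules in isolation.
make_st <- function(z, threshold = 4, fs = 10000, t0_ms = -300,
                    baseline_window_ms = c(-300, 0)) {
  structure(
    list(z = z, fs = fs, t0_ms = t0_ms, baseline_mean = 0, baseline_sd = 1,
         threshold = threshold, threshold_k = threshold,
         baseline_window_ms = baseline_window_ms),
    class = "standardized_trace"
  )
}

# Brute-force epoch oracle: walk the samples one by one, enumerate every
# maximal supra-threshold run, then apply the onset-interval and duration
# rules. Deliberately naive and independent of detect_epochs().
oracle_epochs <- function(st, interval_ms = c(121, 3292),
                          min_duration_ms = 10, right_open = FALSE) {
  t <- st$t0_ms + (seq_along(st$z) - 1) * 1000 / st$fs
  dt <- 1000 / st$fs
  runs <- list()
  i <- 1
  n <- length(st$z)
  while (i <= n) {
    if (st$z[i] > st$threshold) {
      j <- i
      while (j < n && st$z[j + 1] > st$threshold) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  out <- list()
  for (r in runs) {
    onset <- t[r[1]]
    dur <- (r[2] - r[1] + 1) * dt
    in_int <- if (right_open) {
      onset >= interval_ms[1] && onset < interval_ms[2]
    } else {
      onset >= interval_ms[1] && onset <= interval_ms[2]
    }
    if (dur > min_duration_ms && in_int) {
      zi <- st$z[r[1]:r[2]]
      pk <- r[1] + which.max(zi) - 1
      out[[length(out) + 1]] <- data.frame(
        onset_ms = onset, offset_ms = onset + dur, duration_ms = dur,
        peak_z = st$z[pk], peak_time_ms = t[pk]
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(onset_ms = numeric(), offset_ms = numeric(),
                      duration_ms = numeric(), peak_z = numeric(),
                      peak_time_ms = numeric()))
  }
  do.call(rbind, out)
}

# Random standardized test traces: smoothed Gaussian z with occasional
# injected excursions so supra-threshold runs of many lengths occur.
random_st <- function(n = 3000, threshold = NULL) {
  z <- as.numeric(stats::filter(rnorm(n, 0, 2), rep(1 / 5, 5), sides = 1))
  z[is.na(z)] <- 0
  n_b <- rpois(1, 2)
  for (b in seq_len(n_b)) {
    len <- sample(30:200, 1)
    i0 <- sample(n - len, 1)
    z[i0:(i0 + len - 1)] <- z[i0:(i0 + len - 1)] + runif(1, 3, 8)
  }
  if (is.null(threshold)) threshold <- runif(1, 2, 5)
  make_st(z, threshold = threshold)
}

# Small seeded long-format cohort table for ANOVA tests.
make_cohort_table <- function(n_per_group = 4, n_sessions = 3,
                              groups = c("a", "b"), effect = 0, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (g in seq_along(groups)) {
    for (i in seq_len(if (length(n_per_group) > 1) n_per_group[g] else
                      n_per_group)) {
      b <- rnorm(1)
      for (s in seq_len(n_sessions)) {
        rows[[length(rows) + 1]] <- data.frame(
          group = groups[g], subject = paste0(groups[g], i), session = s,
          value = b + effect * (g - 1) + 0.2 * s + rnorm(1)
        )
      }
    }
  }
  do.call(rbind, rows)
}

# aov-based oracle for the mixed RM-ANOVA (independent route).
aov_mixed_oracle <- function(d) {
  d$group <- factor(d$group); d$subject <- factor(d$subject)
  d$session <- factor(d$session)
  fit <- stats::aov(value ~ group * session + Error(subject), data = d)
  s <- summary(fit)
  bs <- s[["Error: subject"]][[1]]
  ws <- s[["Error: Within"]][[1]]
  list(
    f_group = bs["group", "F value"], p_group = bs["group", "Pr(>F)"],
    f_session = ws["session", "F value"],
    p_session = ws["session", "Pr(>F)"],
    f_int = ws["group:session", "F value"],
    p_int = ws["group:session", "Pr(>F)"]
  )
}

aov_oneway_oracle <- function(d) {
  d$subject <- factor(d$subject); d$session <- factor(d$session)
  fit <- stats::aov(value ~ session + Error(subject), data = d)
  ws <- summary(fit)[["Error: Within"]][[1]]
  list(f_session = ws["session", "F value"],
       p_session = ws["session", "Pr(>F)"])
}

# One-trial schedule row for direct simulate_trial() calls.
paired_spec <- function() {
  build_session_schedule(design_params(n_blocks = 1, trials_per_block = 1,
                                       paired_per_block = 1), seed = 1)[1, ]
}

# Model with a single certain long-window CR of fixed amplitude, no other
# events; used for controlled injection studies.
fixed_cr_model <- function(amp_sd = 6, p = c(short = 0, middle = 0, long = 1),
                           onset_mean = 2700, onset_sd = 150,
                           burst_duration_ms = 200, burst_peak_frac = 0.15) {
  learning_model(
    groups = list(g = list(
      p_max = p, k = 50, s0 = 0,
      onset_mean = c(short = 600, middle = 1700, long = onset_mean),
      amp_log_mean = log(amp_sd), amp_log_sd = 0
    )),
    onset_sd_ms = onset_sd,
    burst_duration_ms = burst_duration_ms,
    burst_peak_frac = burst_peak_frac,
    spont_rate_hz = 0, hyper_prob = 0
  )
}

# Event-free model (pure noise + UR).
empty_model <- function(hyper_prob = 0, spont_rate_hz = 0) {
  learning_model(
    groups = list(g = list(
      p_max = c(short = 0, middle = 0, long = 0), k = 1, s0 = 3,
      onset_mean = c(short = 600, middle = 1700, long = 2700),
      amp_log_mean = log(10), amp_log_sd = 0.3
    )),
    spont_rate_hz = spont_rate_hz, hyper_prob = hyper_prob
  )
}
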