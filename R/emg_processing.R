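#' Construct a raw EMG trace
#'
#' A raw trace is one trial's orbicularis oculi EMG on a fixed time axis
#' relative to CS onset (t = 0). The default acquisition covers
#' -300 ms to the CS offset at 10 kHz.
#'
#' @param samples numeric vector of raw EMG samples.
#' @param fs sampling rate in Hz (default 10000).
#' @param t0_ms time of the first sample in ms relative to CS onset
#'   (default -300).
#'
#' @return An object of class `"raw_trace"`: list with `samples`, `fs`,
#'   `t0_ms`.
#' @examples
#' tr <- raw_trace(rnorm(36500))
#' range(trace_times(tr))
#' @export
raw_trace <- function(samples, fs = 10000, t0_ms = -300) {
  if (!is.numeric(samples) || length(samples) < 2) {
    abort("`samples` must be a numeric vector of length >= 2.",
          class = "debcr_config_error")
  }
  if (fs <= 0) abort("`fs` must be > 0.", class = "debcr_config_error")
  structure(list(samples = as.numeric(samples), fs = fs, t0_ms = t0_ms),
            class = "raw_trace")
}

#' Time axis of a trace
#'
#' @param trace a [raw_trace()] or [standardize()]d trace.
#' @return Numeric vector of sample times in ms relative to CS onset.
#' @export
trace_times <- function(trace) {
  n <- length(trace$samples %||% trace$z)
  trace$t0_ms + (seq_len(n) - 1) * .ms_per_s / trace$fs
}

#' Full-wave rectification
#'
#' Replaces every sample by its absolute value; the time axis is unchanged.
#' Idempotent.
#'
#' @param trace a [raw_trace()] (or bare numeric vector).
#' @return The rectified trace (same class as the input).
#' @export
rectify <- function(trace) {
  if (is.numeric(trace)) return(abs(trace))
  trace$samples <- abs(trace$samples)
  trace
}

#' Leaky integration of a rectified trace
#'
#' Smooths the rectified EMG into an envelope with a first-order exponential
#' (leaky) integrator with time constant `tau_ms`:
#' `y[i] = a*y[i-1] + (1-a)*x[i]`, `a = exp(-dt/tau)`, initialized at the
#' first input sample so the baseline window carries no start-up ramp. The
#' filter has unit DC gain: a constant input is reproduced unchanged. A
#' causal moving-average (`method = "boxcar"`, width `tau_ms`) is available
#' as an alternative reading of a "1-ms time constant".
#'
#' @param trace a rectified [raw_trace()].
#' @param tau_ms integration time constant in ms (default 1).
#' @param method `"exponential"` (default) or `"boxcar"`.
#' @return The envelope trace (class `"raw_trace"`, non-negative if the
#'   input is).
#' @export
integrate_envelope <- function(trace, tau_ms = 1,
                               method = c("exponential", "boxcar")) {
  method <- match.arg(method)
  if (tau_ms <= 0) abort("`tau_ms` must be > 0.", class = "debcr_config_error")
  x <- trace$samples
  dt <- .ms_per_s / trace$fs
  if (method == "exponential") {
    a <- exp(-dt / tau_ms)
    y <- as.numeric(stats::filter((1 - a) * x, a, method = "recursive",
                                  init = x[1]))
  } else {
    w <- max(1L, round(tau_ms / dt))
    cs <- cumsum(x)
    y <- numeric(length(x))
    if (w > 1) {
      # partial-window means at the left edge, full-window causal mean after
      y[seq_len(w - 1)] <- cs[seq_len(w - 1)] / seq_len(w - 1)
      idx <- w:length(x)
      y[idx] <- (cs[idx] - c(0, cs)[idx - w + 1]) / w
    } else {
      y <- x
    }
  }
  trace$samples <- y
  trace
}

#' Baseline z-scoring of an envelope
#'
#' Standardizes the integrated envelope against the trial's own pre-CS
#' baseline: every sample becomes a standard score relative to the mean and
#' SD of the envelope over the 300 ms immediately preceding CS onset
#' (window `[-300, 0)`, half-open so the CS-onset sample is excluded). The
#' per-trial detection threshold is the mean plus `threshold_k` (default 4)
#' SDs of the standardized baseline; because standardization uses the same
#' window's sample statistics, the threshold equals `threshold_k` exactly
#' (to numerical tolerance). SD uses the n-1 denominator.
#'
#' @param trace envelope trace from [integrate_envelope()].
#' @param baseline_window_ms baseline interval in ms, default `c(-300, 0)`,
#'   treated as half-open `[lo, hi)`.
#' @param threshold_k threshold multiplier in baseline SD units (default 4).
#'
#' @return An object of class `"standardized_trace"`: list with `z`
#'   (standardized samples), `fs`, `t0_ms`, `baseline_mean`, `baseline_sd`
#'   (envelope units), `threshold` (z units), `threshold_k`,
#'   `baseline_window_ms`.
#'
#' @section Degenerate trials: a flat baseline (zero SD) cannot be
#'   standardized; a `"debcr_degenerate_trial"` error is signalled.
#'   [score_trace()] catches it and marks the trial invalid instead of
#'   failing.
#' @export
standardize <- function(trace, baseline_window_ms = c(-300, 0),
                        threshold_k = 4) {
  t <- trace_times(trace)
  if (baseline_window_ms[1] < t[1] - 1e-6 ||
      baseline_window_ms[2] > t[length(t)] + .ms_per_s / trace$fs + 1e-6) {
    abort("baseline window lies outside the trace span.",
          class = "debcr_config_error")
  }
  bi <- t >= baseline_window_ms[1] & t < baseline_window_ms[2]
  if (sum(bi) < 2) {
    abort("baseline window contains fewer than 2 samples.",
          class = "debcr_config_error")
  }
  m <- mean(trace$samples[bi])
  s <- sd(trace$samples[bi])
  if (!is.finite(s) || s == 0) {
    abort("flat baseline: zero SD, trial cannot be standardized.",
          class = "debcr_degenerate_trial")
  }
  z <- (trace$samples - m) / s
  zb <- z[bi]
  structure(
    list(z = z, fs = trace$fs, t0_ms = trace$t0_ms,
         baseline_mean = m, baseline_sd = s,
         threshold = mean(zb) + threshold_k * sd(zb),
         threshold_k = threshold_k,
         baseline_window_ms = as.numeric(baseline_window_ms)),
    class = "standardized_trace"
  )
}

#' Per-trial detection threshold
#'
#' The trial threshold is the mean plus `threshold_k` times the SD of the
#' standardized EMG over the trial's baseline; on a standardized trace this
#' is `threshold_k` (default 4) by construction.
#'
#' @param st a [standardize()]d trace.
#' @return Threshold in z units.
#' @export
compute_threshold <- function(st) {
  stopifnot(inherits(st, "standardized_trace"))
  st$threshold
}

#' Raw trace to standardized envelope
#'
#' Convenience wrapper: [rectify()] then [integrate_envelope()] then
#' [standardize()].
#'
#' @inheritParams integrate_envelope
#' @inheritParams standardize
#' @return A `"standardized_trace"`.
#' @examples
#' st <- process_trace(raw_trace(rnorm(36500)))
#' compute_threshold(st)
#' @export
process_trace <- function(trace, tau_ms = 1,
                          method = c("exponential", "boxcar"),
                          baseline_window_ms = c(-300, 0), threshold_k = 4) {
  standardize(
    integrate_envelope(rectify(trace), tau_ms = tau_ms, method = method),
    baseline_window_ms = baseline_window_ms, threshold_k = threshold_k
  )
}
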