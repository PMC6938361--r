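#' Summarize one subject-session
#'
#' Aggregates a session's trial classifications into the behavioral
#' measures: per latency window, the CR percentage (CR trials over valid
#' trials, in percent) and the CR-trial-conditional means of peak
#' amplitude, start latency and peak latency. Only trials containing a CR
#' in a window contribute to that window's conditional means. The default
#' scope restricts denominators (and numerators) to CS-US paired trials,
#' matching how CR% is reported per session; `"all_trials"` includes
#' CS-alone probe trials.
#'
#' With zero valid in-scope trials the CR percentages are undefined: they
#' are returned as `NA` with `undefined = TRUE`, never as 0, and downstream
#' statistics drop such cells.
#'
#' @param cls a [classification_table()] tibble for one subject-session.
#' @param subject,group,session identifiers copied into the summary.
#' @param scope `"paired_only"` (default) or `"all_trials"`.
#' @return A tibble with one row per window: `subject`, `group`, `session`,
#'   `n_total`, `n_valid`, `n_hyperactive`, `n_degenerate` (whole-session
#'   counts, all trial types), `window`, `n_cr`, `cr_percent`,
#'   `mean_peak_amplitude`, `mean_start_latency`, `mean_peak_latency`,
#'   `undefined`.
#' @export
summarize_session <- function(cls, subject = "s1", group = NA_character_,
                              session = NA_integer_,
                              scope = c("paired_only", "all_trials")) {
  scope <- match.arg(scope)
  n_total <- nrow(cls)
  n_valid_all <- sum(cls$is_valid)
  n_hyper <- sum(cls$is_hyperactive)
  n_degen <- sum(cls$is_degenerate)
  stopifnot(n_total == n_valid_all + n_hyper + n_degen)
  in_scope <- if (scope == "paired_only") cls$trial_type == "paired" else
    rep(TRUE, n_total)
  sc <- cls[in_scope & cls$is_valid, , drop = FALSE]
  nv <- nrow(sc)
  rows <- lapply(c("short", "middle", "long"), function(w) {
    crf <- sc[[paste0("cr_", w)]]
    n_cr <- sum(crf, na.rm = TRUE)
    crt <- sc[which(crf), , drop = FALSE]
    cm <- function(col) if (n_cr > 0) mean(crt[[col]]) else NA_real_
    tibble(
      subject = subject, group = group, session = session,
      n_total = n_total, n_valid = n_valid_all, n_hyperactive = n_hyper,
      n_degenerate = n_degen, window = w, n_cr = n_cr,
      cr_percent = if (nv > 0) 100 * n_cr / nv else NA_real_,
      mean_peak_amplitude = cm(paste0("amp_", w)),
      mean_start_latency = cm(paste0("start_", w)),
      mean_peak_latency = cm(paste0("peaklat_", w)),
      undefined = nv == 0
    )
  })
  dplyr::bind_rows(rows)
}

#' Build the long-format cohort table
#'
#' Pivots per-session summaries into the tidy table the repeated-measures
#' ANOVA consumes: one row per (group, subject, session, window, measure)
#' with a numeric `value`. Conditional means that are undefined (no CR
#' trials in the cell) are omitted - absent, never zero - and undefined CR
#' percentages (no valid trials) are omitted likewise.
#'
#' @param summaries a tibble of row-bound [summarize_session()] outputs
#'   covering the cohort.
#' @return A tibble with columns `group`, `subject`, `session`, `window`,
#'   `measure` (one of `"cr_percent"`, `"peak_amplitude"`,
#'   `"start_latency"`, `"peak_latency"`), `value`.
#' @export
aggregate_cohort <- function(summaries) {
  long <- tidyr::pivot_longer(
    summaries,
    cols = c("cr_percent", "mean_peak_amplitude", "mean_start_latency",
             "mean_peak_latency"),
    names_to = "measure", values_to = "value"
  )
  long$measure <- c(cr_percent = "cr_percent",
                    mean_peak_amplitude = "peak_amplitude",
                    mean_start_latency = "start_latency",
                    mean_peak_latency = "peak_latency")[long$measure]
  long <- long[!is.na(long$value),
               c("group", "subject", "session", "window", "measure", "value")]
  key <- paste(long$group, long$subject, long$session, long$window,
               long$measure)
  if (anyDuplicated(key)) {
    abort(paste0("duplicate cohort-table key: ", key[anyDuplicated(key)]),
          class = "debcr_config_error")
  }
  long
}

#' Score a simulated dataset into a cohort table
#'
#' Runs the detection pipeline over every trace of a
#' [simulate_cohort()] dataset (with traces retained), summarizes each
#' subject-session, and returns the classification tables, summaries and
#' long cohort table.
#'
#' @param dataset a `"debcr_dataset"` with `traces`.
#' @param scope see [summarize_session()].
#' @param ... passed to [score_trace()].
#' @return List with `classifications` (named list of per-session
#'   classification tables), `summaries`, `cohort` (the
#'   [aggregate_cohort()] table).
#' @export
score_dataset <- function(dataset, scope = "paired_only", ...) {
  stopifnot(inherits(dataset, "debcr_dataset"), !is.null(dataset$traces))
  keys <- unique(dataset$manifest$trace_key)
  cls_list <- list()
  summ <- list()
  for (key in keys) {
    man <- dataset$manifest[dataset$manifest$trace_key == key, , drop = FALSE]
    mat <- dataset$traces[[key]]
    cls <- lapply(seq_len(ncol(mat)), function(i) {
      score_trace(raw_trace(mat[, i], fs = dataset$fs,
                            t0_ms = dataset$t0_ms), ...)
    })
    tab <- classification_table(cls, man)
    cls_list[[key]] <- tab
    summ[[key]] <- summarize_session(tab, subject = man$subject[1],
                                     group = man$group[1],
                                     session = man$session[1], scope = scope)
  }
  summaries <- dplyr::bind_rows(summ)
  list(classifications = cls_list, summaries = summaries,
       cohort = aggregate_cohort(summaries))
}
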