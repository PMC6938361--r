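#' Mixed (two-way) repeated-measures ANOVA
#'
#' Classical sums-of-squares decomposition for one between-subject factor
#' (group) and one within-subject factor (session), the design the study's
#' group-by-session comparisons use. The group effect is tested against
#' subjects-within-groups; the session and interaction effects against the
#' session-by-subjects-within-groups residual. Unequal group sizes are
#' handled by the weighted cell-means decomposition, which for this design
#' (one between factor, complete within data) coincides with the Type III
#' solution. No sphericity correction is applied by default;
#' Greenhouse-Geisser-corrected p values for the within effects are
#' available with `gg_correction = TRUE`.
#'
#' Subjects missing any session are dropped (complete-case) with a message
#' listing their IDs; nothing is imputed. With zero error sums of squares
#' the F ratios are undefined and returned as `NA` with
#' `degenerate = TRUE`.
#'
#' @param table a long cohort table (see [aggregate_cohort()]) or any data
#'   frame with columns `group`, `subject`, `session`, and a value column.
#' @param measure,window optional filters applied when the table has
#'   `measure` / `window` columns.
#' @param value_col name of the value column (default `"value"`).
#' @param gg_correction apply the Greenhouse-Geisser epsilon to the
#'   within-factor p values (default `FALSE`, matching how such designs
#'   are conventionally reported without stated correction).
#' @return An object of class `"debcr_anova"`: list with `anova_table`
#'   (tibble: effect, df, ss, ms, statistic, p), `type = "mixed"`,
#'   `group_means`, `session_means`, `group_n`, `n_sessions`, `data`
#'   (the complete-case data used), `dropped_subjects`, `degenerate`.
#' @examples
#' tab <- simulate_summary_cohort(sessions = 1:3,
#'   group_sizes = c(saline = 4, PCP = 4), seed = 1)
#' fit <- mixed_rm_anova(tab, measure = "cr_percent", window = "long")
#' fit$anova_table
#' @export
mixed_rm_anova <- function(table, measure = NULL, window = NULL,
                           value_col = "value", gg_correction = FALSE) {
  d <- .prep_anova_data(table, measure, window, value_col)
  dropped <- .complete_case_subjects(d)
  d <- d[!d$subject %in% dropped, , drop = FALSE]
  if (length(unique(d$group)) < 2) {
    abort("mixed RM-ANOVA needs >= 2 groups after filtering.",
          class = "debcr_config_error")
  }
  if (length(unique(d$session)) < 2) {
    abort("mixed RM-ANOVA needs >= 2 sessions after filtering.",
          class = "debcr_config_error")
  }
  .check_cells(d)

  k <- length(unique(d$session))
  GM <- mean(d$value)
  subj <- dplyr::summarise(dplyr::group_by(d, .data$group, .data$subject),
                           m = mean(.data$value), .groups = "drop")
  grp <- dplyr::summarise(dplyr::group_by(subj, .data$group),
                          m = mean(.data$m), n = dplyr::n(),
                          .groups = "drop")
  sess <- dplyr::summarise(dplyr::group_by(d, .data$session),
                           m = mean(.data$value), .groups = "drop")
  cell <- dplyr::summarise(dplyr::group_by(d, .data$group, .data$session),
                           m = mean(.data$value), .groups = "drop")
  N <- nrow(subj)
  G <- nrow(grp)

  ss_total <- sum((d$value - GM)^2)
  ss_bs <- k * sum((subj$m - GM)^2)
  ss_group <- k * sum(grp$n * (grp$m - GM)^2)
  ss_subj <- ss_bs - ss_group
  ss_session <- N * sum((sess$m - GM)^2)
  cell$gm <- grp$m[match(cell$group, grp$group)]
  cell$gn <- grp$n[match(cell$group, grp$group)]
  cell$sm <- sess$m[match(cell$session, sess$session)]
  ss_int <- sum(cell$gn * (cell$m - cell$gm - cell$sm + GM)^2)
  ss_error <- ss_total - ss_bs - ss_session - ss_int

  df <- c(group = G - 1, subjects = N - G, session = k - 1,
          interaction = (G - 1) * (k - 1), error = (N - G) * (k - 1))
  ms <- c(ss_group, ss_subj, ss_session, ss_int, ss_error) / df
  degenerate <- ms[["subjects"]] <= 0 || ms[["error"]] <= 0
  f_group <- if (ms[["subjects"]] > 0) ms[["group"]] / ms[["subjects"]] else NA
  f_sess <- if (ms[["error"]] > 0) ms[["session"]] / ms[["error"]] else NA
  f_int <- if (ms[["error"]] > 0) ms[["interaction"]] / ms[["error"]] else NA
  eps <- if (gg_correction) .gg_epsilon(d) else 1
  p_group <- if (is.na(f_group)) NA else
    pf(f_group, df[["group"]], df[["subjects"]], lower.tail = FALSE)
  p_sess <- if (is.na(f_sess)) NA else
    pf(f_sess, eps * df[["session"]], eps * df[["error"]],
       lower.tail = FALSE)
  p_int <- if (is.na(f_int)) NA else
    pf(f_int, eps * df[["interaction"]], eps * df[["error"]],
       lower.tail = FALSE)
  tab <- tibble(
    effect = c("group", "subjects_within_groups", "session",
               "group:session", "session_error"),
    df = as.numeric(df),
    ss = c(ss_group, ss_subj, ss_session, ss_int, ss_error),
    ms = ms,
    statistic = c(f_group, NA, f_sess, f_int, NA),
    p = c(p_group, NA, p_sess, p_int, NA)
  )
  structure(
    list(anova_table = tab, type = "mixed",
         group_means = stats::setNames(grp$m, grp$group),
         session_means = stats::setNames(sess$m, as.character(sess$session)),
         group_n = stats::setNames(grp$n, grp$group),
         n_sessions = k, data = d, dropped_subjects = dropped,
         gg_epsilon = eps, degenerate = degenerate),
    class = "debcr_anova"
  )
}

#' One-way repeated-measures ANOVA
#'
#' Single within-subject factor (session), subjects as blocks: the total
#' variation splits into subject, session and residual sums of squares;
#' the session effect is tested against the residual. Complete-case on
#' subjects, like [mixed_rm_anova()].
#'
#' @inheritParams mixed_rm_anova
#' @return A `"debcr_anova"` with `type = "one_way_rm"`.
#' @export
one_way_rm_anova <- function(table, measure = NULL, window = NULL,
                             value_col = "value", gg_correction = FALSE) {
  d <- .prep_anova_data(table, measure, window, value_col,
                        need_group = FALSE)
  dropped <- .complete_case_subjects(d)
  d <- d[!d$subject %in% dropped, , drop = FALSE]
  k <- length(unique(d$session))
  n <- length(unique(d$subject))
  if (k < 2 || n < 2) {
    abort("one-way RM-ANOVA needs >= 2 sessions and >= 2 subjects.",
          class = "debcr_config_error")
  }
  GM <- mean(d$value)
  subj <- dplyr::summarise(dplyr::group_by(d, .data$subject),
                           m = mean(.data$value), .groups = "drop")
  sess <- dplyr::summarise(dplyr::group_by(d, .data$session),
                           m = mean(.data$value), .groups = "drop")
  ss_total <- sum((d$value - GM)^2)
  ss_subj <- k * sum((subj$m - GM)^2)
  ss_sess <- n * sum((sess$m - GM)^2)
  ss_err <- ss_total - ss_subj - ss_sess
  df <- c(subject = n - 1, session = k - 1, error = (n - 1) * (k - 1))
  ms <- c(ss_subj, ss_sess, ss_err) / df
  degenerate <- ms[["error"]] <= 0
  f_sess <- if (!degenerate) ms[["session"]] / ms[["error"]] else NA
  eps <- if (gg_correction) .gg_epsilon(d) else 1
  p_sess <- if (is.na(f_sess)) NA else
    pf(f_sess, eps * df[["session"]], eps * df[["error"]],
       lower.tail = FALSE)
  tab <- tibble(
    effect = c("subject", "session", "error"),
    df = as.numeric(df),
    ss = c(ss_subj, ss_sess, ss_err),
    ms = ms,
    statistic = c(NA, f_sess, NA),
    p = c(NA, p_sess, NA)
  )
  structure(
    list(anova_table = tab, type = "one_way_rm",
         session_means = stats::setNames(sess$m, as.character(sess$session)),
         n_subjects = n, n_sessions = k, data = d,
         dropped_subjects = dropped, gg_epsilon = eps,
         degenerate = degenerate),
    class = "debcr_anova"
  )
}

#' LSD post hoc pairwise comparisons
#'
#' Fisher's least-significant-difference tests after an omnibus
#' repeated-measures ANOVA: for every pair of levels,
#' `t = (m_i - m_j) / SE` with the ANOVA error term appropriate to the
#' factor - subjects-within-groups (on the subject-mean scale) for group
#' pairs, the within residual for session pairs - and a two-sided p with
#' no multiplicity correction, as LSD prescribes.
#'
#' @param fit a `"debcr_anova"` from [mixed_rm_anova()] or
#'   [one_way_rm_anova()].
#' @param factor `"group"` (mixed fits only) or `"session"`.
#' @return A tibble: `level_1`, `level_2`, `diff` (mean difference,
#'   level_1 minus level_2), `se`, `statistic` (t), `df`, `p`.
#' @export
lsd_posthoc <- function(fit, factor = c("group", "session")) {
  stopifnot(inherits(fit, "debcr_anova"))
  factor <- match.arg(factor)
  at <- fit$anova_table
  if (factor == "group") {
    if (fit$type != "mixed") {
      abort("group contrasts require a mixed RM-ANOVA fit.",
            class = "debcr_config_error")
    }
    means <- fit$group_means
    ns <- fit$group_n
    # subjects-within-groups MS on the subject-mean scale
    ms_err <- at$ms[at$effect == "subjects_within_groups"] / fit$n_sessions
    df_err <- at$df[at$effect == "subjects_within_groups"]
  } else {
    means <- fit$session_means
    n_tot <- if (fit$type == "mixed") sum(fit$group_n) else fit$n_subjects
    ns <- stats::setNames(rep(n_tot, length(means)), names(means))
    err_name <- if (fit$type == "mixed") "session_error" else "error"
    ms_err <- at$ms[at$effect == err_name]
    df_err <- at$df[at$effect == err_name]
  }
  lv <- names(means)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt(ms_err * (1 / ns[[i]] + 1 / ns[[j]]))
    dd <- means[[i]] - means[[j]]
    # zero error with zero difference is an exact null, not a degeneracy
    tt <- if (se > 0) dd / se else if (dd == 0) 0 else NA_real_
    tibble(level_1 = i, level_2 = j, diff = dd, se = se, statistic = tt,
           df = df_err,
           p = if (is.na(tt)) NA_real_ else 2 * pt(-abs(tt), df_err))
  })
  dplyr::bind_rows(rows)
}

#' @export
print.debcr_anova <- function(x, ...) {
  cat(switch(x$type, mixed = "Mixed (group x session)",
             one_way_rm = "One-way"), "repeated-measures ANOVA\n")
  if (length(x$dropped_subjects)) {
    cat("Dropped (incomplete sessions):",
        paste(x$dropped_subjects, collapse = ", "), "\n")
  }
  print(as.data.frame(x$anova_table), digits = 5)
  invisible(x)
}

.prep_anova_data <- function(table, measure, window, value_col,
                             need_group = TRUE) {
  d <- as_tibble(table)
  if (!is.null(measure) && "measure" %in% names(d)) {
    d <- d[d$measure == measure, , drop = FALSE]
  }
  if (!is.null(window) && "window" %in% names(d)) {
    d <- d[d$window == window, , drop = FALSE]
  }
  need <- c(if (need_group) "group", "subject", "session", value_col)
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    abort(paste0("missing columns: ", paste(miss, collapse = ", ")),
          class = "debcr_config_error")
  }
  d$value <- d[[value_col]]
  if (!need_group && !"group" %in% names(d)) d$group <- "all"
  if (is.factor(d$session)) d$session <- as.character(d$session)
  d[c("group", "subject", "session", "value")]
}

.complete_case_subjects <- function(d) {
  sessions <- sort(unique(d$session))
  per <- dplyr::summarise(dplyr::group_by(d, .data$subject),
                          n = length(unique(.data$session)),
                          .groups = "drop")
  dropped <- per$subject[per$n < length(sessions)]
  if (length(dropped)) {
    rlang::inform(paste0("dropping incomplete subjects: ",
                         paste(dropped, collapse = ", ")))
  }
  dropped
}

.check_cells <- function(d) {
  cells <- dplyr::summarise(dplyr::group_by(d, .data$group, .data$session),
                            n = dplyr::n(), .groups = "drop")
  full <- tidyr::expand_grid(group = unique(d$group),
                             session = unique(d$session))
  full <- dplyr::left_join(full, cells, by = c("group", "session"))
  bad <- full[is.na(full$n) | full$n == 0, , drop = FALSE]
  if (nrow(bad)) {
    abort(paste0("empty design cell: group=", bad$group[1], ", session=",
                 bad$session[1]), class = "debcr_config_error")
  }
}

# Greenhouse-Geisser epsilon from the session covariance of subject profiles
.gg_epsilon <- function(d) {
  wide <- tidyr::pivot_wider(d, id_cols = "subject", names_from = "session",
                             values_from = "value")
  m <- as.matrix(wide[, -1])
  S <- stats::cov(m)
  k <- ncol(S)
  md <- mean(diag(S)); mall <- mean(S); mr <- rowMeans(S)
  num <- (k * (md - mall))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(mr^2) + k^2 * mall^2)
  if (den <= 0) return(1)
  min(1, max(1 / (k - 1), num / den))
}
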