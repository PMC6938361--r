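test_that("all-equal observations give zero SS and a degenerate fit", {
  d <- make_cohort_table(n_per_group = 3, n_sessions = 3)
  d$value <- 5
  fit <- mixed_rm_anova(d)
  expect_true(all(fit$anova_table$ss == 0))
  expect_true(fit$degenerate)
  expect_true(all(is.na(fit$anova_table$statistic[c(1, 3, 4)])))
})

test_that("copying one group's values onto another kills the group effect", {
  d <- make_cohort_table(n_per_group = 4, n_sessions = 3, seed = 3)
  a <- d[d$group == "a", ]
  b <- a; b$group <- "b"; b$subject <- sub("^a", "b", b$subject)
  d2 <- rbind(a, b)
  fit <- mixed_rm_anova(d2)
  f_group <- fit$anova_table$statistic[fit$anova_table$effect == "group"]
  expect_equal(f_group, 0, tolerance = 1e-12)
  p_group <- fit$anova_table$p[fit$anova_table$effect == "group"]
  expect_equal(p_group, 1, tolerance = 1e-12)
})

test_that("mixed RM-ANOVA matches the aov oracle on seeded designs", {
  # balanced 2 x 3 x 4 and unbalanced 3-group designs
  cases <- list(
    make_cohort_table(n_per_group = 4, n_sessions = 3, seed = 11,
                      effect = 0.5),
    make_cohort_table(n_per_group = c(3, 5, 4), n_sessions = 4,
                      groups = c("a", "b", "c"), seed = 12, effect = 0.8),
    make_cohort_table(n_per_group = c(13, 10), n_sessions = 7,
                      groups = c("x", "y"), seed = 13, effect = 0.3)
  )
  for (d in cases) {
    fit <- mixed_rm_anova(d)
    at <- fit$anova_table
    o <- aov_mixed_oracle(d)
    expect_equal(at$statistic[at$effect == "group"], o$f_group,
                 tolerance = 1e-8)
    expect_equal(at$p[at$effect == "group"], o$p_group, tolerance = 1e-8)
    expect_equal(at$statistic[at$effect == "session"], o$f_session,
                 tolerance = 1e-8)
    expect_equal(at$p[at$effect == "session"], o$p_session,
                 tolerance = 1e-8)
    expect_equal(at$statistic[at$effect == "group:session"], o$f_int,
                 tolerance = 1e-8)
    expect_equal(at$p[at$effect == "group:session"], o$p_int,
                 tolerance = 1e-8)
  }
})

test_that("one-way RM-ANOVA matches the aov oracle and its edge cases", {
  d <- make_cohort_table(n_per_group = 6, n_sessions = 4,
                         groups = "a", seed = 14)
  fit <- one_way_rm_anova(d)
  o <- aov_oneway_oracle(d)
  at <- fit$anova_table
  expect_equal(at$statistic[at$effect == "session"], o$f_session,
               tolerance = 1e-8)
  expect_equal(at$p[at$effect == "session"], o$p_session, tolerance = 1e-8)

  # identical sessions: F = 0
  d2 <- d
  d2$value <- ave(d2$value, d2$subject)  # same value in every session
  fit2 <- one_way_rm_anova(d2)
  expect_equal(fit2$anova_table$ss[fit2$anova_table$effect == "session"], 0,
               tolerance = 1e-12)

  # additive subject offsets only: all session variation is subject SS
  d3 <- expand.grid(subject = paste0("s", 1:5), session = 1:4)
  d3$group <- "a"
  offs <- stats::setNames(rnorm(5), paste0("s", 1:5))
  d3$value <- offs[as.character(d3$subject)]
  fit3 <- one_way_rm_anova(d3)
  expect_equal(fit3$anova_table$ss[fit3$anova_table$effect == "session"], 0,
               tolerance = 1e-12)
})

test_that("F statistics are invariant to shift and positive scaling", {
  d <- make_cohort_table(n_per_group = 4, n_sessions = 3, seed = 15,
                         effect = 0.6)
  f0 <- mixed_rm_anova(d)$anova_table$statistic
  d1 <- d; d1$value <- d1$value + 100
  d2 <- d; d2$value <- d2$value * 3.5
  expect_equal(mixed_rm_anova(d1)$anova_table$statistic, f0,
               tolerance = 1e-9)
  expect_equal(mixed_rm_anova(d2)$anova_table$statistic, f0,
               tolerance = 1e-9)
})

test_that("incomplete subjects are dropped with a message, never imputed", {
  d <- make_cohort_table(n_per_group = 4, n_sessions = 3, seed = 16)
  d <- d[!(d$subject == "a1" & d$session == 2), ]
  expect_message(fit <- mixed_rm_anova(d), "a1")
  expect_equal(fit$dropped_subjects, "a1")
  expect_false("a1" %in% fit$data$subject)
})

test_that("ANOVA input validation catches bad designs", {
  d <- make_cohort_table(n_per_group = 3, n_sessions = 3,
                         groups = "a", seed = 17)
  expect_error(mixed_rm_anova(d), class = "debcr_config_error")
  d2 <- make_cohort_table(n_per_group = 3, n_sessions = 1, seed = 18)
  expect_error(mixed_rm_anova(d2), class = "debcr_config_error")
})

test_that("LSD post hoc has exact nulls, symmetry and t-distribution p", {
  d <- make_cohort_table(n_per_group = c(4, 5, 3), n_sessions = 3,
                         groups = c("a", "b", "c"), seed = 19, effect = 0.7)
  fit <- mixed_rm_anova(d)
  ph <- lsd_posthoc(fit, "group")
  expect_equal(nrow(ph), 3)
  # p equals the two-sided t probability recomputed independently
  expect_equal(ph$p, 2 * (1 - pt(abs(ph$statistic), ph$df)),
               tolerance = 1e-12)
  # equal means give t = 0, p = 1
  deq <- d; deq$value <- ave(deq$value, deq$session)
  pheq <- lsd_posthoc(mixed_rm_anova(deq), "group")
  expect_equal(pheq$statistic, rep(0, 3), tolerance = 1e-9)
  expect_equal(pheq$p, rep(1, 3), tolerance = 1e-9)
  # session pairs from the within error term
  phs <- lsd_posthoc(fit, "session")
  expect_equal(nrow(phs), 3)
  expect_equal(phs$p, 2 * (1 - pt(abs(phs$statistic), phs$df)),
               tolerance = 1e-12)
})

test_that("LSD group contrasts reproduce a hand-computed t", {
  d <- make_cohort_table(n_per_group = 4, n_sessions = 3, seed = 21,
                         effect = 1)
  fit <- mixed_rm_anova(d)
  ph <- lsd_posthoc(fit, "group")
  ms_sw <- fit$anova_table$ms[fit$anova_table$effect ==
                                "subjects_within_groups"]
  se <- sqrt(ms_sw / fit$n_sessions * (1 / 4 + 1 / 4))
  expect_equal(ph$se, se, tolerance = 1e-12)
  expect_equal(ph$diff,
               unname(fit$group_means["a"] - fit$group_means["b"]),
               tolerance = 1e-12)
})
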