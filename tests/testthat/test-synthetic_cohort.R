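test_that("logistic acquisition curve has the expected anchor points", {
  m <- learning_model(groups = list(g = list(
    p_max = c(short = 0.1, middle = 0.2, long = 0.6), k = 0, s0 = 3,
    onset_mean = c(short = 600, middle = 1700, long = 2700),
    amp_log_mean = log(10), amp_log_sd = 0.2
  )))
  # zero slope: p = p_max / 2 at every session
  for (s in c(1, 3, 7)) {
    expect_equal(cr_probability(m, "g", "long", s), 0.3)
  }
  m2 <- learning_model()
  # inflection session: p = p_max / 2
  expect_equal(cr_probability(m2, "saline", "long", 3),
               m2$groups$saline$p_max[["long"]] / 2)
  # asymptote
  expect_equal(cr_probability(m2, "saline", "long", 500),
               m2$groups$saline$p_max[["long"]], tolerance = 1e-9)
  expect_error(cr_probability(m2, "nope", "long", 1),
               class = "debcr_config_error")
  expect_error(cr_probability(m2, "saline", "huge", 1),
               class = "debcr_config_error")
  expect_error(cr_probability(m2, "saline", "long", 0),
               class = "debcr_config_error")
})

test_that("model validation rejects inconsistent parameters", {
  expect_error(learning_model(groups = list(g = list(
    p_max = c(short = 0.5, middle = 0.5, long = 0.5), k = 1, s0 = 3,
    onset_mean = c(short = 600, middle = 1700, long = 2700),
    amp_log_mean = 1, amp_log_sd = 0.1
  ))), class = "debcr_config_error")
  expect_error(learning_model(groups = list(g = list(
    p_max = c(short = 0.1, middle = 0.1, long = 0.1), k = 1, s0 = 3,
    onset_mean = c(short = 50, middle = 1700, long = 2700),
    amp_log_mean = 1, amp_log_sd = 0.1
  ))), class = "debcr_config_error")
})

test_that("silent trial: zero noise and zero event rates give a zero trace", {
  set.seed(1)
  tr <- simulate_trial(paired_spec(), empty_model(), "g", 1,
                       noise = noise_model(sigma = 0),
                       calib = list(mean = 0, sd = 1))
  # UR burst still fires on paired trials; drop it via a CS-alone spec
  spec <- paired_spec(); spec$trial_type <- "cs_alone"
  spec$us_onset_ms <- NA_real_
  tr <- simulate_trial(spec, empty_model(), "g", 1,
                       noise = noise_model(sigma = 0),
                       calib = list(mean = 0, sd = 1))
  expect_equal(tr$trace$samples, rep(0, length(tr$trace$samples)))
})

test_that("an injected high-amplitude CR is recovered at its onset", {
  set.seed(2)
  # sharp-rise burst (6-ms rise) with amplitude far above noise:
  # the detected start latency collapses onto the injected onset
  m <- fixed_cr_model(amp_sd = 400, onset_mean = 2500, onset_sd = 0,
                      burst_duration_ms = 60, burst_peak_frac = 0.1)
  noise <- noise_model(); calib <- calibrate_envelope(noise)
  for (i in 1:5) {
    tr <- simulate_trial(paired_spec(), m, "g", 5, noise, calib)
    cl <- score_trace(tr$trace)
    expect_true(cl$cr[["long"]])
    mm <- cl$metrics[cl$metrics$window == "long", ]
    expect_lt(abs(mm$start_latency_ms - 2500), 5)
  }
})

test_that("every trial is hyperactive when hyper_prob = 1", {
  set.seed(3)
  m <- empty_model(hyper_prob = 1)
  noise <- noise_model(); calib <- calibrate_envelope(noise)
  truth_flags <- logical(40); detected <- logical(40)
  for (i in 1:40) {
    tr <- simulate_trial(paired_spec(), m, "g", 1, noise, calib)
    truth_flags[i] <- tr$truth$is_hyperactive
    detected[i] <- score_trace(tr$trace)$is_hyperactive
  }
  expect_true(all(truth_flags))
  expect_true(all(detected))
})

test_that("cohort simulation is deterministic given the seed", {
  gs <- c(saline = 1, PCP = 1)
  d1 <- simulate_cohort(group_sizes = gs, sessions = 1, seed = 42)
  d2 <- simulate_cohort(group_sizes = gs, sessions = 1, seed = 42)
  expect_identical(d1$traces, d2$traces)
  expect_identical(d1$manifest, d2$manifest)
  expect_identical(d1$truth, d2$truth)
  d3 <- simulate_cohort(group_sizes = gs, sessions = 1, seed = 43)
  expect_false(identical(d1$traces, d3$traces))
})

test_that("cohort dimensions follow the design and group sizes", {
  gs <- c(saline = 2, PCP = 1)
  ds <- simulate_cohort(design_params(n_blocks = 2), group_sizes = gs,
                        sessions = 1:2, seed = 7)
  expect_equal(length(unique(ds$manifest$subject)), 3)
  expect_equal(nrow(ds$manifest), 3 * 2 * 20)
  expect_equal(nrow(ds$truth), nrow(ds$manifest))
  expect_equal(dim(ds$traces[[1]]), c(36500, 20))
  # the default four-group design is the study's 51 subjects x 7 sessions
  expect_equal(sum(eval(formals(simulate_cohort)$group_sizes)), 51)
  expect_equal(design_params()$n_sessions, 7)
  expect_equal(design_params()$n_blocks * design_params()$trials_per_block,
               120)
})

test_that("ground-truth CR fraction tracks the acquisition probability", {
  set.seed(8)
  # saline-like group at asymptote with p(long) = 0.6
  m <- fixed_cr_model(amp_sd = 10,
                      p = c(short = 0, middle = 0, long = 0.6))
  ds <- simulate_cohort(model = m,
                        group_sizes = c(g = 2), sessions = 5, seed = 8)
  paired <- ds$manifest$trial_type == "paired"
  got <- mean(!is.na(ds$truth$cr_window[paired]) &
                ds$truth$cr_window[paired] == "long")
  expect_lt(abs(got - 0.6), 3 * sqrt(0.6 * 0.4 / sum(paired)))
})

test_that("ground-truth CR onsets stay inside the valid CR period", {
  set.seed(9)
  ds <- simulate_cohort(group_sizes = c(saline = 1), sessions = 7, seed = 9,
                        keep_traces = FALSE)
  on <- ds$truth$cr_onset_ms[!is.na(ds$truth$cr_onset_ms)]
  expect_true(all(on >= 121 & on <= 3292))
  st <- ds$truth$cr_start_ms[!is.na(ds$truth$cr_start_ms)]
  expect_true(all(st >= 121 & st <= 3292))
  # start latencies stay inside their labelled window
  lab <- ds$truth$cr_window[!is.na(ds$truth$cr_start_ms)]
  expect_identical(unname(window_of(st)), lab)
})

test_that("summary-level cohorts have the right shape and range", {
  tab <- simulate_summary_cohort(sessions = 1:3,
                                 group_sizes = c(saline = 3, PCP = 2),
                                 seed = 10)
  expect_equal(nrow(tab), 5 * 3 * 3)
  expect_true(all(tab$value >= 0 & tab$value <= 100))
  t2 <- simulate_summary_cohort(sessions = 1:3,
                                group_sizes = c(saline = 3, PCP = 2),
                                seed = 10)
  expect_identical(tab, t2)
})
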