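#' Write a simulated dataset to disk
#'
#' Serializes a [simulate_cohort()] dataset into a directory:
#' `manifest.json` (format version, seed, design, model and noise
#' parameters, group sizes, and one record per trial), `truth.csv`
#' (ground-truth labels), and one Arrow/Feather file per subject-session
#' holding the trial traces column-wise (bit-exact floating point). Times
#' in all files are milliseconds relative to CS onset; `fs` and `t0_ms` in
#' the manifest make the sample/ms conversion explicit.
#'
#' @param dataset a `"debcr_dataset"` with traces.
#' @param path directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "debcr_dataset"))
  if (is.null(dataset$traces)) {
    abort("dataset has no traces (`keep_traces = FALSE`); nothing to write.",
          class = "debcr_config_error")
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  header <- list(
    format_version = dataset$format_version,
    seed = dataset$seed,
    fs = dataset$fs, t0_ms = dataset$t0_ms,
    design = unclass(dataset$design),
    noise = unclass(dataset$noise),
    model = .model_to_list(dataset$model),
    group_sizes = as.list(dataset$group_sizes),
    manifest = dataset$manifest
  )
  jsonlite::write_json(header, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(dataset$truth, file.path(path, "truth.csv"),
                   row.names = FALSE)
  for (key in names(dataset$traces)) {
    df <- as.data.frame(dataset$traces[[key]])
    names(df) <- sprintf("t%03d", seq_len(ncol(df)))
    arrow::write_feather(df, file.path(path, paste0(key, ".feather")))
  }
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#'
#' Validates the manifest against the stored traces: a manifest trial whose
#' trace file or column is missing is an error naming the trial, as is a
#' sampling-rate mismatch.
#'
#' @param path dataset directory.
#' @return A `"debcr_dataset"`.
#' @export
read_dataset <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) {
    abort(paste0("no manifest.json under ", path),
          class = "debcr_io_error")
  }
  h <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (is.null(h$format_version) || h$format_version != 1L) {
    abort("unsupported or missing dataset format version.",
          class = "debcr_io_error")
  }
  manifest <- as_tibble(h$manifest)
  truth <- as_tibble(utils::read.csv(file.path(path, "truth.csv")))
  if ("cr_window" %in% names(truth)) {
    truth$cr_window <- as.character(truth$cr_window)
  }
  traces <- list()
  for (key in unique(manifest$trace_key)) {
    f <- file.path(path, paste0(key, ".feather"))
    if (!file.exists(f)) {
      abort(paste0("missing trace file for '", key, "'."),
            class = "debcr_io_error")
    }
    df <- as.data.frame(arrow::read_feather(f))
    n_tr <- sum(manifest$trace_key == key)
    if (ncol(df) != n_tr) {
      abort(paste0("trace file '", key, "' has ", ncol(df),
                   " trials; manifest lists ", n_tr, "."),
            class = "debcr_io_error")
    }
    traces[[key]] <- unname(as.matrix(df))
  }
  design <- do.call(design_params, h$design)
  structure(
    list(format_version = 1L, seed = h$seed, design = design,
         model = .model_from_list(h$model),
         group_sizes = unlist(h$group_sizes), fs = h$fs, t0_ms = h$t0_ms,
         noise = noise_model(h$noise$sigma, h$noise$band_hz, h$noise$fs),
         manifest = manifest, truth = truth, traces = traces),
    class = "debcr_dataset"
  )
}

.model_to_list <- function(model) {
  out <- unclass(model)
  out$groups <- lapply(out$groups, function(g) {
    g$p_max <- as.list(g$p_max)
    g$onset_mean <- as.list(g$onset_mean)
    g
  })
  out
}

.model_from_list <- function(lst) {
  groups <- lapply(lst$groups, function(g) {
    g$p_max <- unlist(g$p_max)
    g$onset_mean <- unlist(g$onset_mean)
    g
  })
  args <- lst[setdiff(names(lst), "groups")]
  do.call(learning_model, c(list(groups = groups), args))
}

#' Pipeline configuration
#'
#' Bundles and validates everything one end-to-end run needs. Validation
#' happens here, before any computation.
#'
#' @param design a [design_params()].
#' @param model a [learning_model()].
#' @param group_sizes named subjects-per-group vector.
#' @param noise a [noise_model()].
#' @param sessions session indices to simulate.
#' @param scope CR% denominator scope, see [summarize_session()].
#' @param measure,window measure and latency window the ANOVA layer tests.
#' @param alpha significance level (default 0.05).
#' @return A list of class `"debcr_config"`.
#' @export
pipeline_config <- function(design = design_params(),
                            model = learning_model(),
                            group_sizes = c(saline = 4, PCP = 4,
                                            PCP_eNpHR = 4, PCP_EYFP = 4),
                            noise = noise_model(),
                            sessions = seq_len(design$n_sessions),
                            scope = c("paired_only", "all_trials"),
                            measure = "cr_percent", window = "long",
                            alpha = 0.05) {
  scope <- match.arg(scope)
  stopifnot(inherits(design, "design_params"),
            inherits(model, "learning_model"),
            inherits(noise, "noise_model"))
  if (alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be in (0, 1).", class = "debcr_config_error")
  }
  if (!all(names(group_sizes) %in% names(model$groups))) {
    abort("every name in `group_sizes` must be a model group.",
          class = "debcr_config_error")
  }
  if (!window %in% c("short", "middle", "long")) {
    abort("`window` must be short, middle or long.",
          class = "debcr_config_error")
  }
  structure(list(design = design, model = model, group_sizes = group_sizes,
                 noise = noise, sessions = sessions, scope = scope,
                 measure = measure, window = window, alpha = alpha),
            class = "debcr_config")
}

#' Run the full pipeline
#'
#' Simulate -> process -> summarize -> test, streaming one subject-session
#' at a time so raw traces never accumulate in memory. Writes the per-trial
#' classification table, the long cohort table, the ANOVA table and the LSD
#' post hoc table as CSV, plus a JSON run log recording the seed, the
#' configuration (including a content hash) and the package version.
#' Reruns with the same seed reproduce every output byte-for-byte.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param seed integer seed driving all randomness.
#' @return Invisibly, a list with the in-memory `classifications`,
#'   `summaries`, `cohort`, `anova` fit, `posthoc` table and the output
#'   `paths`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, seed = 1) {
  stopifnot(inherits(config, "debcr_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  calib <- calibrate_envelope(config$noise)
  cls_all <- list(); summ <- list()
  for (g in names(config$group_sizes)) {
    for (kk in seq_len(config$group_sizes[[g]])) {
      subject <- sprintf("%s_%02d", g, kk)
      for (s in config$sessions) {
        sched <- build_session_schedule(config$design)
        sess <- simulate_session(sched, config$model, g, s, config$noise,
                                 calib)
        cls <- lapply(sess$trials, function(tr) score_trace(tr$trace))
        tab <- classification_table(cls, sched)
        key <- sprintf("%s_s%d", subject, s)
        cls_all[[key]] <- dplyr::mutate(tab, subject = subject, group = g,
                                        session = s, .before = 1)
        summ[[key]] <- summarize_session(tab, subject = subject, group = g,
                                         session = s, scope = config$scope)
      }
    }
  }
  classifications <- dplyr::bind_rows(cls_all)
  summaries <- dplyr::bind_rows(summ)
  cohort <- aggregate_cohort(summaries)
  fit <- mixed_rm_anova(cohort, measure = config$measure,
                        window = config$window)
  posthoc <- lsd_posthoc(fit, "group")
  paths <- list(
    classifications = file.path(out_dir, "trial_classifications.csv"),
    cohort = file.path(out_dir, "cohort_table.csv"),
    anova = file.path(out_dir, "anova.csv"),
    posthoc = file.path(out_dir, "lsd_posthoc.csv"),
    log = file.path(out_dir, "run_log.json")
  )
  utils::write.csv(classifications, paths$classifications, row.names = FALSE)
  utils::write.csv(cohort, paths$cohort, row.names = FALSE)
  utils::write.csv(fit$anova_table, paths$anova, row.names = FALSE)
  utils::write.csv(posthoc, paths$posthoc, row.names = FALSE)
  cfg_list <- list(design = unclass(config$design),
                   model = .model_to_list(config$model),
                   noise = unclass(config$noise),
                   group_sizes = as.list(config$group_sizes),
                   sessions = config$sessions, scope = config$scope,
                   measure = config$measure, window = config$window,
                   alpha = config$alpha)
  jsonlite::write_json(
    list(seed = seed,
         package_version = as.character(utils::packageVersion("debcr")),
         config_hash = rlang::hash(cfg_list),
         config = cfg_list),
    paths$log, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  invisible(list(classifications = classifications, summaries = summaries,
                 cohort = cohort, anova = fit, posthoc = posthoc,
                 paths = paths))
}
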