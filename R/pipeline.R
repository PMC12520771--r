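TRIAL_CSV_COLS <- c("experiment", "condition", "phase", "subject", "block",
                    "trial", "probe_db", "comparison_db", "response",
                    "anchor_db", "seed")

#' Write / read the trial-level CSV
#'
#' Flat UTF-8 CSV with a header row and one row per trial:
#' `experiment, condition, phase, subject, block, trial, probe_db,
#' comparison_db, response, anchor_db, seed`. `response` is 0 (probe louder)
#' or 1 (comparison louder) and is empty for unanswered designs; `anchor_db`
#' is filled by simulation only. The round trip preserves values, types and
#' row order exactly.
#'
#' @param trials data frame of trial records (missing schema columns are
#'   added as NA)
#' @param path file path
#' @return `write_trials` returns `path` invisibly; `read_trials` returns the
#'   data frame with the schema's column types
#' @export
write_trials <- function(trials, path) {
  df <- as.data.frame(trials)
  if (!"subject" %in% names(df)) df$subject <- NA_integer_
  if (!"response" %in% names(df)) df$response <- NA_integer_
  if (!"anchor_db" %in% names(df)) df$anchor_db <- NA_real_
  if (!"seed" %in% names(df)) df$seed <- attr(trials, "seed") %||% NA_integer_
  utils::write.csv(df[, TRIAL_CSV_COLS], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  utils::read.csv(path, colClasses = c(
    experiment = "integer", condition = "character", phase = "character",
    subject = "integer", block = "integer", trial = "integer",
    probe_db = "numeric", comparison_db = "numeric", response = "integer",
    anchor_db = "numeric", seed = "integer"))
}

#' Simulate a cohort of observers through an experiment
#'
#' Builds one session design and one simulated response stream per subject.
#' Each subject's design seed and response seed are derived deterministically
#' from `(seed, subject id)`, so any subject can be regenerated in isolation.
#'
#' @param experiment 1, 2 or 3
#' @param group group label: exp 1 `"baseline"`/`"active"`, exp 2
#'   `"continuous_cue"`/`"flashed_cue"` (or `"baseline"`, simulated with the
#'   exp-1 passive structure), exp 3 context `"quiet"`/`"loud"`
#' @param params_list list of per-subject [observer_params()] (e.g. from
#'   [make_cohort()]); its length sets the cohort size
#' @param seed cohort seed
#' @param subject_offset added to the 1-based subject index to keep ids
#'   unique across groups
#' @return trial data frame with `subject`, `response`, `anchor_db` and (for
#'   experiment 3) `context` columns; block orders are attached as attribute
#'   `block_orders`
#' @export
simulate_cohort <- function(experiment, group, params_list, seed = 0L,
                            subject_offset = 0L) {
  n <- length(params_list)
  out <- vector("list", n)
  block_orders <- list()
  for (i in seq_len(n)) {
    sid <- subject_offset + i
    dseed <- subject_seed(seed, 2L * sid)
    rseed <- subject_seed(seed, 2L * sid + 1L)
    design <- switch(as.character(experiment),
      "1" = make_exp1_design(group, dseed),
      "2" = if (group == "baseline") make_exp1_design("baseline", dseed)
            else make_exp2_design(group, dseed),
      "3" = make_exp3_design(group, dseed),
      stop2("loudreg_invalid_parameter", "unknown experiment %s", experiment))
    tr <- simulate_session(design, params_list[[i]], rseed)
    tr$subject <- sid
    tr$seed <- rseed
    if (experiment == 3) tr$context <- group
    block_orders[[as.character(sid)]] <-
      tr$probe_db[!duplicated(tr$block)]
    out[[i]] <- tr
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "block_orders") <- block_orders
  res
}

#' Fit psychometric functions for every subject x phase x probe
#'
#' @param trials trial records with `subject` (and optionally `phase`,
#'   `context`) columns
#' @param method fit method passed to [fit_cumulative_gaussian()]
#' @return fits data frame: `subject`, `condition`, `context` (if present),
#'   `phase`, `probe_db`, `pse_db`, `sigma_db`, `sse_or_loglik`, `converged`
#' @export
fit_trials <- function(trials, method = "lsq") {
  key <- interaction(trials$subject, trials$phase, trials$probe_db, drop = TRUE)
  rows <- lapply(split(trials, key), function(tr) {
    tab <- aggregate_proportions(tr, probe_db = tr$probe_db[1])
    fit <- tryCatch(fit_cumulative_gaussian(tab, method = method),
                    loudreg_degenerate_data = function(e) NULL)
    data.frame(subject = tr$subject[1], condition = tr$condition[1],
               context = if ("context" %in% names(tr)) tr$context[1] else NA_character_,
               phase = tr$phase[1], probe_db = tr$probe_db[1],
               pse_db = if (is.null(fit)) NA_real_ else fit$pse_db,
               sigma_db = if (is.null(fit)) NA_real_ else fit$sigma_db,
               sse_or_loglik = if (is.null(fit)) NA_real_ else fit$sse_or_loglik,
               converged = if (is.null(fit)) FALSE else fit$converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$subject, out$phase, out$probe_db), , drop = FALSE]
  rownames(out) <- NULL
  out
}

default_distributions <- function() {
  list(w_baseline = list(mean = 0.94, sd = 0.03),
       w_cued = list(mean = 0.88, sd = 0.03))
}

#' Replication run configuration
#'
#' @param experiment 1, 2 or 3
#' @param n_per_group subjects per group (>= 2)
#' @param seed master seed; every random draw in the run derives from it
#' @param fit_method `"lsq"` or `"mle"`
#' @param w_mean,w_sd per-condition truncated-normal distribution of the
#'   stimulus weight w (named vectors; defaults: baseline 0.94, cued/active
#'   0.88, sd 0.03 on [0,1])
#' @param params base [observer_params()] supplying anchor, noise and lapse
#' @param out_dir output directory or NULL for no file output
#' @return list of class `run_config`
#' @export
run_config <- function(experiment, n_per_group = 55, seed = 1L,
                       fit_method = "lsq",
                       w_mean = c(baseline = 0.94, active = 0.88,
                                  continuous_cue = 0.88, flashed_cue = 0.88,
                                  quiet = NA, loud = NA),
                       w_sd = 0.03,
                       params = observer_params(),
                       out_dir = NULL) {
  stopifnot(n_per_group >= 2)
  groups <- switch(as.character(experiment),
                   "1" = c("baseline", "active"),
                   "2" = c("baseline", "continuous_cue", "flashed_cue"),
                   "3" = c("quiet", "loud"),
                   stop2("loudreg_invalid_parameter", "unknown experiment"))
  structure(list(experiment = experiment, groups = groups,
                 n_per_group = n_per_group, seed = as.integer(seed),
                 fit_method = fit_method, w_mean = w_mean, w_sd = w_sd,
                 params = params, out_dir = out_dir),
            class = "run_config")
}

#' Read a replication config from a JSON file
#'
#' Nested key/value configuration; recognised keys mirror the arguments of
#' [run_config()] plus an `observer` block passed to [observer_params()].
#'
#' @param path JSON file path
#' @return a `run_config`
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  obs <- do.call(observer_params, as.list(cfg$observer %||% list()))
  args <- cfg[setdiff(names(cfg), "observer")]
  args$params <- obs
  do.call(run_config, args)
}

log_line <- function(log, fmt, ...) c(log, sprintf(fmt, ...))

# condition whose w distribution a group draws from
w_condition_of_group <- function(experiment, group) {
  if (experiment == 3) "active" else group
}

#' Run a full synthetic replication of one experiment
#'
#' Chains design -> observer -> exclusion -> psychometric fits -> subject
#' summaries -> inferential statistics, entirely driven by the config seed.
#' With `out_dir` set, writes `trials.csv`, `fits.csv`, `summaries.csv`,
#' `stats.json` and `log.txt`.
#'
#' For experiments 1-2 the statistics are the level-by-group mixed ANOVA on
#' PSE deviations, per-group mean adaptation slopes, the pooled t-test (with
#' Cohen's d) between each cued/active group and baseline, the one-way ANOVA
#' of slopes across groups (exp 2), and JZS Bayes factors between cued group
#' pairs. For experiment 3 they are the test-phase level-by-context and
#' phase-by-context mixed ANOVAs plus the four context-cell means.
#'
#' @param config a [run_config()]
#' @return list: `trials`, `fits`, `summaries`, `stats` (list, serialised as
#'   JSON), `excluded` (subject ids), `log` (character vector)
#' @export
run_replication <- function(config) {
  stopifnot(inherits(config, "run_config"))
  exp_id <- config$experiment
  log <- character()
  trials_all <- list()
  block_orders <- list()
  for (gi in seq_along(config$groups)) {
    grp <- config$groups[gi]
    wc <- w_condition_of_group(exp_id, grp)
    base <- config$params
    dist <- list(w = list(mean = unname(config$w_mean[[wc]]), sd = config$w_sd))
    cohort <- make_cohort(config$n_per_group, wc, dist,
                          seed = config$seed + 131L * gi + 10007L * exp_id,
                          base_params = base)
    tr <- simulate_cohort(exp_id, grp, cohort,
                          seed = config$seed + 977L * gi + 20011L * exp_id,
                          subject_offset = (gi - 1L) * config$n_per_group)
    trials_all[[grp]] <- tr
    block_orders <- c(block_orders, attr(tr, "block_orders"))
    log <- log_line(log, "simulate: experiment %d group %s, %d subjects, %d trials",
                    exp_id, grp, config$n_per_group, nrow(tr))
  }
  trials <- do.call(rbind, trials_all)
  rownames(trials) <- NULL

  excl <- vapply(split(trials, trials$subject),
                 function(tr) exclusion_check(tr)$excluded, logical(1))
  excluded_ids <- as.integer(names(excl)[excl])
  log <- log_line(log, "exclusion: %d of %d subjects excluded (error rate > 25%%)",
                  length(excluded_ids), length(excl))
  kept <- trials[!trials$subject %in% excluded_ids, , drop = FALSE]

  fits <- fit_trials(kept, method = config$fit_method)
  log <- log_line(log, "fit: %d psychometric fits, %d non-converged",
                  nrow(fits), sum(!fits$converged))

  if (exp_id == 3) {
    ctx <- withCallingHandlers(
      context_effects(fits, on_missing = "drop"),
      warning = function(w) {
        log <<- log_line(log, "warn: %s", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    stats <- exp3_stats(ctx)
    summaries <- ctx
  } else {
    summaries <- withCallingHandlers(
      subject_summaries(fits, block_orders = block_orders),
      warning = function(w) {
        log <<- log_line(log, "warn: %s", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    stats <- exp12_stats(summaries, fits)
  }
  log <- log_line(log, "stats: %d entries", length(stats))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trials(trials, file.path(config$out_dir, "trials.csv"))
    utils::write.csv(fits, file.path(config$out_dir, "fits.csv"), row.names = FALSE)
    utils::write.csv(summaries, file.path(config$out_dir, "summaries.csv"),
                     row.names = FALSE)
    jsonlite::write_json(stats, file.path(config$out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log, file.path(config$out_dir, "log.txt"))
  }
  list(trials = trials, fits = fits, summaries = summaries, stats = stats,
       excluded = excluded_ids, log = log)
}

exp12_stats <- function(summaries, fits) {
  dev <- suppressWarnings(pse_deviations(fits))
  dev$group <- dev$condition
  # listwise deletion: the mixed ANOVA needs every subject at every level,
  # so subjects with a non-converged fit at any probe drop out of it
  k <- length(unique(dev$probe_db))
  complete <- names(which(table(dev$subject) == k))
  aov_tab <- mixed_anova(dev[dev$subject %in% complete, , drop = FALSE],
                         value = "deviation_db", subject = "subject",
                         within = "probe_db", group = "group")
  groups <- unique(summaries$condition)
  slopes <- split(summaries$slope, summaries$condition)
  mean_slopes <- vapply(slopes, mean, numeric(1))
  stats <- list(mixed_anova = as.data.frame(aov_tab),
                mean_slope_by_group = as.list(mean_slopes))
  if ("baseline" %in% groups) {
    for (g in setdiff(groups, "baseline")) {
      tt <- student_t(slopes[[g]], slopes$baseline)
      stats[[paste0("t_", g, "_vs_baseline")]] <- unclass(tt)
    }
  }
  if (length(groups) > 2) {
    stats$oneway_slopes <- as.data.frame(oneway_anova(summaries$slope,
                                                      summaries$condition))
  }
  cued <- intersect(c("active", "continuous_cue", "flashed_cue"), groups)
  if (length(cued) >= 2) {
    for (i in seq_len(length(cued) - 1)) for (j in (i + 1):length(cued)) {
      tt <- student_t(slopes[[cued[i]]], slopes[[cued[j]]])
      bf <- jzs_bf10(tt$t, tt$n1, tt$n2)
      stats[[paste0("bf_", cued[i], "_vs_", cued[j])]] <- unclass(bf)
    }
  }
  stats
}

exp3_stats <- function(ctx) {
  test <- ctx[ctx$cell %in% c("test_majority", "test_minority"), , drop = FALSE]
  test$level <- test$probe_db
  aov_level <- mixed_anova(test, value = "deviation_db", subject = "subject",
                           within = "level", group = "context")
  # phase contrast: per-subject mean deviation in test vs matched baselines
  ph <- do.call(rbind, lapply(split(ctx, ctx$subject), function(d) {
    data.frame(subject = rep(d$subject[1], 2), context = rep(d$context[1], 2),
               phase = c("baseline", "test"),
               value = c(mean(d$deviation_db[d$cell %in% c("baseline_40", "baseline_80")]),
                         mean(d$deviation_db[d$cell %in% c("test_majority", "test_minority")])))
  }))
  aov_phase <- mixed_anova(ph, value = "value", subject = "subject",
                           within = "phase", group = "context")
  cell_means <- stats::aggregate(deviation_db ~ context + cell, data = ctx, FUN = mean)
  list(level_by_context = as.data.frame(aov_level),
       phase_by_context = as.data.frame(aov_phase),
       cell_means = cell_means)
}

#' Parameter recovery for the stimulus weight w
#'
#' With a frozen anchor (alpha = 0) the generative model's PSE deviation is
#' (1 - w)(mu - L), a line in the probe level with slope -(1 - w); the
#' group-mean adaptation slope therefore identifies w as w_hat = 1 + slope.
#' This harness simulates cohorts on the 5-level session for each true w,
#' fits them, and reports the recovered slopes.
#'
#' @param w_grid true w values to sweep
#' @param n_subjects cohort size per replicate (default 55)
#' @param n_reps replicates per w
#' @param seed master seed
#' @param params base [observer_params()]; `anchor_lr` is forced to 0
#' @param condition condition label used for the sweep
#' @return data frame: `true_w`, `mean_slope`, `sd_slope`, `mc_se`,
#'   `w_hat` (= 1 + mean_slope), `rmse` of per-rep w estimates
#' @export
parameter_recovery <- function(w_grid = c(0.8, 0.85, 0.9, 0.95),
                               n_subjects = 55, n_reps = 20, seed = 1L,
                               params = observer_params(),
                               condition = "baseline") {
  p0 <- unclass(params)
  p0$anchor_lr <- 0
  class(p0) <- "observer_params"
  rows <- lapply(seq_along(w_grid), function(wi) {
    w <- w_grid[wi]
    rep_slopes <- vapply(seq_len(n_reps), function(r) {
      sd_seed <- subject_seed(seed, 100000L * wi + r)
      cohort <- make_cohort(n_subjects, condition, list(w = w),
                            seed = sd_seed, base_params = p0)
      tr <- simulate_cohort(1, condition, cohort, seed = sd_seed + 1L)
      fits <- fit_trials(tr)
      mean(suppressWarnings(subject_summaries(fits))$slope)
    }, numeric(1))
    data.frame(true_w = w,
               mean_slope = mean(rep_slopes),
               sd_slope = stats::sd(rep_slopes),
               mc_se = stats::sd(rep_slopes) / sqrt(n_reps),
               w_hat = 1 + mean(rep_slopes),
               rmse = sqrt(mean((1 + rep_slopes - w)^2)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
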