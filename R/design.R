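#' Trial-schedule generators for 2AFC loudness sessions
#'
#' A session design is a data frame of trial specifications (class
#' `session_design`) with one row per trial and metadata attributes.
#' Columns:
#' \describe{
#'   \item{experiment}{1, 2 or 3}
#'   \item{condition}{`"baseline"`, `"active"`, `"continuous_cue"` or
#'     `"flashed_cue"`; the predictability condition the observer weight is
#'     keyed on}
#'   \item{phase}{`"main"` for single-phase sessions; `"baseline1"`,
#'     `"baseline2"`, `"adaptation"`, `"test"` for context sessions}
#'   \item{block, trial}{0-based block index and 0-based trial index within
#'     the session}
#'   \item{probe_db, comparison_db}{probe and comparison tone levels in dB}
#'   \item{cue_onset_ms, tone_onset_ms}{cue timing metadata (NA when no cue);
#'     not used by the observer model}
#'   \item{tone_duration_ms, tone_freq_hz}{300 ms, 1000 Hz for every tone}
#' }
#' Attributes: `probe_levels`, `step_db`, `reps_per_comparison`, `context`
#' (`"none"`, `"quiet"` or `"loud"`) and `seed`.
#'
#' @name session_design
NULL

TONE_DURATION_MS <- 300
TONE_FREQ_HZ <- 1000
PROBE_LEVELS_DB <- c(40, 50, 60, 70, 80)
COMPARISON_OFFSETS <- -3:3

new_session_design <- function(trials, probe_levels, step_db, reps, context, seed) {
  rownames(trials) <- NULL
  structure(trials,
            probe_levels = probe_levels,
            step_db = step_db,
            reps_per_comparison = reps,
            context = context,
            seed = as.integer(seed),
            class = c("session_design", "data.frame"))
}

#' @export
print.session_design <- function(x, ...) {
  cat(sprintf("<session_design> experiment %d, %d trials, step %g dB, context %s, seed %d\n",
              x$experiment[1], nrow(x), attr(x, "step_db"),
              attr(x, "context"), attr(x, "seed")))
  cat(sprintf("  probe levels: %s dB; phases: %s\n",
              paste(attr(x, "probe_levels"), collapse = "/"),
              paste(unique(x$phase), collapse = ", ")))
  invisible(x)
}

# One block of the method of constant stimuli: every comparison offset
# repeated `reps` times around `probe`, uniformly shuffled.
shuffled_block <- function(probe, step, reps) {
  comps <- probe + COMPARISON_OFFSETS * step
  sample(rep(comps, each = reps))
}

trial_frame <- function(experiment, condition, phase, block, probe, comps,
                        cue_onset_ms = NA_real_, tone_onset_ms = NA_real_) {
  data.frame(experiment = experiment,
             condition = condition,
             phase = phase,
             block = block,
             trial = 0L,           # filled in once the session is assembled
             probe_db = probe,
             comparison_db = comps,
             cue_onset_ms = cue_onset_ms,
             tone_onset_ms = tone_onset_ms,
             tone_duration_ms = TONE_DURATION_MS,
             tone_freq_hz = TONE_FREQ_HZ,
             stringsAsFactors = FALSE)
}

finish_session <- function(trials, probe_levels, step, reps, context, seed) {
  trials$trial <- seq_len(nrow(trials)) - 1L
  new_session_design(trials, probe_levels, step, reps, context, seed)
}

#' Build a self-generation experiment session (experiment 1)
#'
#' Method of constant stimuli with 5 probe levels (40--80 dB) presented
#' block-wise in a seed-permuted order; within each 70-trial block the 7
#' comparison levels (probe +/- 3 steps of 2 dB) each occur exactly 10 times
#' in shuffled order, for 350 trials total. In the `"active"` group the probe
#' tone is self-triggered by a key press; in `"baseline"` it appears after a
#' random interval.
#'
#' @param group `"baseline"` or `"active"`
#' @param seed non-negative integer; drives block order and within-block
#'   shuffles (uniform Fisher--Yates via the base RNG)
#' @return a [session_design] of 350 trials
#' @export
#' @examples
#' d <- make_exp1_design("baseline", seed = 1)
#' nrow(d)                       # 350
#' table(d$probe_db)             # 70 trials per probe level
make_exp1_design <- function(group = c("baseline", "active"), seed = 0L) {
  group <- match.arg(group)
  step <- 2; reps <- 10
  with_seed(seed, {
    order_levels <- sample(PROBE_LEVELS_DB)
    blocks <- lapply(seq_along(order_levels), function(b) {
      probe <- order_levels[b]
      trial_frame(1L, group, "main", b - 1L, probe,
                  shuffled_block(probe, step, reps))
    })
    finish_session(do.call(rbind, blocks), PROBE_LEVELS_DB, step, reps,
                   "none", seed)
  })
}

#' Build a temporally-cued passive session (experiment 2)
#'
#' Identical block/comparison structure to [make_exp1_design()]; the probe is
#' externally generated but temporally predictable through a visual cue.
#' `"continuous_cue"`: two bars converge from trial start and meet in the
#' screen centre after 70 frames at 60 Hz (tone onset ~1166.7 ms).
#' `"flashed_cue"`: the fixation cross flashes red at 700 ms for 300 ms and
#' the tone follows at `flash_onset + flashed_tone_offset_ms`. Timing is
#' metadata only; the observer model keys on the condition label.
#'
#' @param cue `"continuous_cue"` or `"flashed_cue"`
#' @param seed non-negative integer seed
#' @param flashed_tone_offset_ms tone onset relative to the flash, default
#'   700 ms
#' @return a [session_design] of 350 trials
#' @export
make_exp2_design <- function(cue = c("continuous_cue", "flashed_cue"), seed = 0L,
                             flashed_tone_offset_ms = 700) {
  cue <- match.arg(cue)
  step <- 2; reps <- 10
  if (cue == "continuous_cue") {
    cue_onset <- 0
    tone_onset <- 70 / 60 * 1000       # bar contact after 70 frames at 60 Hz
  } else {
    cue_onset <- 700
    tone_onset <- 700 + flashed_tone_offset_ms
  }
  with_seed(seed, {
    order_levels <- sample(PROBE_LEVELS_DB)
    blocks <- lapply(seq_along(order_levels), function(b) {
      probe <- order_levels[b]
      trial_frame(2L, cue, "main", b - 1L, probe,
                  shuffled_block(probe, step, reps),
                  cue_onset_ms = cue_onset, tone_onset_ms = tone_onset)
    })
    finish_session(do.call(rbind, blocks), PROBE_LEVELS_DB, step, reps,
                   "none", seed)
  })
}

#' Build a context-adaptation session (experiment 3)
#'
#' Four phases in fixed order. For a `"quiet"` context: baseline1 (70 passive
#' trials, probe 80 dB), baseline2 (70 passive trials, probe 40 dB),
#' adaptation (70 passive trials at the context level 40 dB), then a test
#' phase of 350 self-generated trials in which 80% (280) use the 40 dB
#' majority probe and 20% (70) the 80 dB minority probe, uniformly
#' interleaved. A `"loud"` context mirrors the roles of 40 and 80 dB.
#' Comparisons span probe +/- 3 steps of 3 dB throughout.
#'
#' @param context `"quiet"` or `"loud"`
#' @param seed non-negative integer seed
#' @return a [session_design] of 560 trials
#' @export
make_exp3_design <- function(context = c("quiet", "loud"), seed = 0L) {
  context <- match.arg(context)
  step <- 3; reps <- 10
  ctx_level <- if (context == "quiet") 40 else 80
  rare_level <- if (context == "quiet") 80 else 40
  # baseline1 probes the non-context level first, baseline2 the context level
  with_seed(seed, {
    phases <- list(
      trial_frame(3L, "baseline", "baseline1", 0L, rare_level,
                  shuffled_block(rare_level, step, reps)),
      trial_frame(3L, "baseline", "baseline2", 1L, ctx_level,
                  shuffled_block(ctx_level, step, reps)),
      trial_frame(3L, "baseline", "adaptation", 2L, ctx_level,
                  shuffled_block(ctx_level, step, reps))
    )
    # test phase: per-probe comparison multisets, then a uniform interleave
    maj <- rep(ctx_level + COMPARISON_OFFSETS * step, each = 4 * reps)
    min_ <- rep(rare_level + COMPARISON_OFFSETS * step, each = reps)
    probes <- c(rep(ctx_level, length(maj)), rep(rare_level, length(min_)))
    comps <- c(sample(maj), sample(min_))
    ord <- sample(length(probes))
    phases$test <- trial_frame(3L, "active", "test", 3L,
                               probes[ord], comps[ord])
    finish_session(do.call(rbind, phases), sort(c(ctx_level, rare_level)),
                   step, reps, context, seed)
  })
}
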