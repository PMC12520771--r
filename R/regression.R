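#' PSE deviations from the physical probe level
#'
#' Deviation = PSE - probe level, in dB, per probe level: positive values
#' mean the probe was overestimated (enhancement), negative underestimated
#' (attenuation). Non-converged fits are dropped with a warning.
#'
#' @param fits data frame with one row per (subject, probe) fit: columns
#'   `subject`, `condition`, `probe_db`, `pse_db`, `converged` (and
#'   optionally `phase`)
#' @return the same frame restricted to converged fits with a `deviation_db`
#'   column added
#' @export
pse_deviations <- function(fits) {
  if (!any(fits$converged))
    stop2("loudreg_insufficient_data", "no converged fits")
  bad <- sum(!fits$converged)
  if (bad > 0)
    warning(sprintf("dropping %d non-converged fit(s)", bad), call. = FALSE)
  out <- fits[fits$converged, , drop = FALSE]
  out$deviation_db <- out$pse_db - out$probe_db
  rownames(out) <- NULL
  out
}

#' Adaptation index: slope of deviation against probe level
#'
#' Ordinary least squares fit of deviation_db ~ probe_db for one subject.
#' The slope quantifies regression to the mean: 0 for a veridical observer,
#' and -(1 - w) for the central-tendency observer with a fixed anchor. More
#' negative = stronger pull toward the anchor.
#'
#' @param deviations data frame with `probe_db` and `deviation_db` (one
#'   subject)
#' @return list: `slope` (dB/dB), `intercept` (dB), `n_levels`
#' @export
adaptation_index <- function(deviations) {
  x <- deviations$probe_db
  y <- deviations$deviation_db
  if (length(unique(x)) < 2L)
    stop2("loudreg_insufficient_levels",
          "need >= 2 probe levels for a slope, got %d", length(unique(x)))
  cf <- stats::coef(stats::lm(y ~ x))
  list(slope = unname(cf[2]), intercept = unname(cf[1]),
       n_levels = length(unique(x)))
}

#' Per-subject summaries: deviations and adaptation slope
#'
#' @param fits fits frame as for [pse_deviations()]
#' @param block_orders optional named list mapping subject id to that
#'   subject's block order (vector of probe levels in presentation order)
#' @return data frame with one row per subject: `subject`, `condition`,
#'   `slope`, `intercept`, and one `dev_<level>` column per probe level
#' @export
subject_summaries <- function(fits, block_orders = NULL) {
  dev <- pse_deviations(fits)
  levels_all <- sort(unique(dev$probe_db))
  rows <- lapply(split(dev, dev$subject), function(d) {
    if (length(unique(d$probe_db)) < 2L) {
      warning(sprintf("subject %s: < 2 converged probe levels, skipped", d$subject[1]),
              call. = FALSE)
      return(NULL)
    }
    ai <- adaptation_index(d)
    row <- data.frame(subject = d$subject[1], condition = d$condition[1],
                      slope = ai$slope, intercept = ai$intercept,
                      stringsAsFactors = FALSE)
    for (lv in levels_all)
      row[[paste0("dev_", lv)]] <-
        if (lv %in% d$probe_db) d$deviation_db[match(lv, d$probe_db)] else NA_real_
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(block_orders))
    attr(out, "block_orders") <- block_orders
  out
}

#' First-half versus second-half deviations for the extreme probe levels
#'
#' Classifies each subject's 40 dB and 80 dB blocks by their position in the
#' session: blocks 1-2 are the first half, blocks 4-5 the second half, and
#' the middle block (3) is excluded. Subjects whose target block falls in the
#' middle for a level contribute NA for that level. Output feeds the 2x2
#' (level x half) repeated-measures contrast probing within-session anchor
#' updating.
#'
#' @param summaries output of [subject_summaries()] carrying a
#'   `block_orders` attribute (or pass `block_orders` explicitly)
#' @param levels the two probe levels to contrast, default c(40, 80)
#' @param block_orders named list: subject id -> probe-level presentation
#'   order
#' @return data frame: `subject`, `condition`, `probe_db`, `half`
#'   (`"first"`/`"second"`), `deviation_db`
#' @export
half_split_contrast <- function(summaries, levels = c(40, 80),
                                block_orders = attr(summaries, "block_orders")) {
  if (is.null(block_orders))
    stop2("loudreg_unclassifiable", "block orders unknown")
  rows <- list()
  for (i in seq_len(nrow(summaries))) {
    sj <- summaries$subject[i]
    ord <- block_orders[[as.character(sj)]]
    if (is.null(ord)) next
    got_any <- FALSE
    for (lv in levels) {
      pos <- match(lv, ord)
      if (is.na(pos) || pos == 3L) next   # middle block dropped
      half <- if (pos <= 2L) "first" else "second"
      devcol <- paste0("dev_", lv)
      if (!devcol %in% names(summaries) || is.na(summaries[[devcol]][i])) next
      rows[[length(rows) + 1L]] <-
        data.frame(subject = sj, condition = summaries$condition[i],
                   probe_db = lv, half = half,
                   deviation_db = summaries[[devcol]][i],
                   stringsAsFactors = FALSE)
      got_any <- TRUE
    }
    if (!got_any)
      warning(sprintf("subject %s unclassifiable (target blocks in the middle)", sj),
              call. = FALSE)
  }
  if (!length(rows))
    stop2("loudreg_unclassifiable", "no classifiable subjects")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Context-session deviations for baseline and test phases
#'
#' For context sessions, extracts per-subject PSE deviations for the four
#' cells used by the context analysis: the two baseline phases and the
#' majority/minority probes of the test phase. The majority level equals the
#' context level (40 dB for a quiet context, 80 dB for a loud one).
#'
#' @param fits fits frame with a `phase` column (`baseline1`, `baseline2`,
#'   `test`) and a `context` column (`"quiet"`/`"loud"`)
#' @param on_missing `"error"` (default) signals a subject with no converged
#'   fit in a required cell; `"drop"` removes that subject with a warning
#' @return data frame: `subject`, `context`, `cell` (one of `baseline_40`,
#'   `baseline_80`, `test_majority`, `test_minority`), `probe_db`,
#'   `deviation_db`
#' @export
context_effects <- function(fits, on_missing = c("error", "drop")) {
  on_missing <- match.arg(on_missing)
  dev <- suppressWarnings(pse_deviations(fits))
  per_subject <- function(d) {
    ctx <- d$context[1]
    maj <- if (ctx == "quiet") 40 else 80
    cell_of <- function(phase_pat, probe) {
      r <- d[grepl(phase_pat, d$phase) & d$probe_db == probe, , drop = FALSE]
      if (nrow(r) == 0L)
        stop2("loudreg_missing_phase",
              "subject %s: no converged fit for phase %s at %g dB",
              d$subject[1], phase_pat, probe)
      r$deviation_db[1]
    }
    data.frame(subject = d$subject[1], context = ctx,
               cell = c("baseline_40", "baseline_80", "test_majority",
                        "test_minority"),
               probe_db = c(40, 80, maj, 120 - maj),
               deviation_db = c(cell_of("^baseline", 40),
                                cell_of("^baseline", 80),
                                cell_of("^test$", maj),
                                cell_of("^test$", 120 - maj)),
               stringsAsFactors = FALSE)
  }
  rows <- lapply(split(dev, dev$subject), function(d) {
    if (on_missing == "drop") {
      tryCatch(per_subject(d), loudreg_missing_phase = function(e) {
        warning(conditionMessage(e), call. = FALSE)
        NULL
      })
    } else per_subject(d)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop2("loudreg_missing_phase", "no subject has all four context cells")
  rownames(out) <- NULL
  out
}
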