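#' Central-tendency observer parameters
#'
#' The generative observer perceives the probe tone as a weighted average of
#' its physical level and an internal anchor (a running central-tendency
#' estimate of the sound-level distribution): percept = w*L + (1-w)*mu. The
#' comparison tone, presented immediately and not held in memory, is
#' perceived veridically up to sensory noise. All arithmetic is on the dB
#' scale.
#'
#' @param w_by_condition named numeric vector of stimulus weights w in [0,1],
#'   one entry per condition the observer will encounter
#'   (e.g. `c(baseline = 0.94, active = 0.88)`); 1 - w is the pull toward
#'   the anchor
#' @param anchor_init_db initial anchor mu0 in dB (default 60, the everyday
#'   communication sound level)
#' @param anchor_lr per-tone anchor learning rate alpha in [0,1] of the
#'   exponential-moving-average update; 0 freezes the anchor
#' @param noise_probe_db sensory/memory noise SD of the probe percept, dB (> 0)
#' @param noise_comp_db sensory noise SD of the comparison percept, dB (> 0)
#' @param lapse lapse rate lambda in [0, 0.2]: probability of a
#'   stimulus-independent random response
#' @return an object of class `observer_params`
#' @export
observer_params <- function(w_by_condition = c(baseline = 0.94, active = 0.88,
                                               continuous_cue = 0.88,
                                               flashed_cue = 0.88),
                            anchor_init_db = 60,
                            anchor_lr = 0.005,
                            noise_probe_db = 3,
                            noise_comp_db = 3,
                            lapse = 0.02) {
  if (is.null(names(w_by_condition)) || any(!nzchar(names(w_by_condition))))
    stop2("loudreg_invalid_parameter", "w_by_condition must be a named vector")
  if (any(w_by_condition < 0 | w_by_condition > 1))
    stop2("loudreg_invalid_parameter", "all w must lie in [0, 1]")
  if (noise_probe_db <= 0 || noise_comp_db <= 0)
    stop2("loudreg_invalid_parameter", "noise SDs must be positive")
  if (anchor_lr < 0 || anchor_lr > 1)
    stop2("loudreg_invalid_parameter", "anchor_lr must lie in [0, 1]")
  if (lapse < 0 || lapse > 0.2)
    stop2("loudreg_invalid_parameter", "lapse must lie in [0, 0.2]")
  structure(list(w_by_condition = w_by_condition,
                 anchor_init_db = anchor_init_db,
                 anchor_lr = anchor_lr,
                 noise_probe_db = noise_probe_db,
                 noise_comp_db = noise_comp_db,
                 lapse = lapse),
            class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat("<observer_params>\n")
  cat("  w:", paste(sprintf("%s=%.3g", names(x$w_by_condition), x$w_by_condition),
                    collapse = ", "), "\n")
  cat(sprintf("  anchor: mu0 = %g dB, alpha = %g\n", x$anchor_init_db, x$anchor_lr))
  cat(sprintf("  noise: sigma_p = %g dB, sigma_c = %g dB; lapse = %g\n",
              x$noise_probe_db, x$noise_comp_db, x$lapse))
  invisible(x)
}

#' Anchor running state
#'
#' @param anchor_db current anchor value in dB
#' @param n_updates number of exponential-moving-average updates applied
#' @return an object of class `prior_state`
#' @export
prior_state <- function(anchor_db, n_updates = 0L) {
  structure(list(anchor_db = anchor_db, n_updates = as.integer(n_updates)),
            class = "prior_state")
}

#' Probability of judging the comparison tone louder
#'
#' Closed-form response probability of the central-tendency observer:
#' \deqn{p = \lambda/2 + (1-\lambda)\,
#'   \Phi\!\left(\frac{c - [wL + (1-w)\mu]}{\sqrt{\sigma_p^2+\sigma_c^2}}\right)}
#' where L is the probe level, c the comparison level, mu the current anchor
#' and w the condition's stimulus weight. Vectorised over levels.
#'
#' @param probe_db,comparison_db tone levels in dB
#' @param state a [prior_state()] (supplies the anchor mu)
#' @param params an [observer_params()]
#' @param condition condition label indexing `w_by_condition`
#' @return probability in (0, 1)
#' @export
p_comparison_louder <- function(probe_db, comparison_db, state, params,
                                condition = "baseline") {
  w <- params$w_by_condition[[condition]]
  s2 <- params$noise_probe_db^2 + params$noise_comp_db^2
  if (s2 <= 0)
    stop2("loudreg_invalid_parameter", "total noise variance must be positive")
  percept <- w * probe_db + (1 - w) * state$anchor_db
  params$lapse / 2 +
    (1 - params$lapse) * stats::pnorm((comparison_db - percept) / sqrt(s2))
}

#' Update the anchor with one experienced sound level
#'
#' Exponential moving average: mu' = (1 - alpha) * mu + alpha * level. With
#' alpha = 0 the anchor is frozen; alpha = 1 tracks the last level exactly.
#'
#' @param state a [prior_state()]
#' @param experienced_db experienced sound level in dB
#' @param alpha learning rate in [0, 1]
#' @return the updated `prior_state`
#' @export
update_prior <- function(state, experienced_db, alpha) {
  stopifnot(alpha >= 0, alpha <= 1)
  prior_state((1 - alpha) * state$anchor_db + alpha * experienced_db,
              state$n_updates + 1L)
}

#' Simulate one observer running a session
#'
#' Draws one Bernoulli response per trial from [p_comparison_louder()],
#' updating the anchor after each trial with the trial's probe and comparison
#' levels (in presentation order). The anchor value in effect on each trial is
#' recorded. When `anchor_lr = 0` the whole session is vectorised.
#'
#' @param design a [session_design]
#' @param params an [observer_params()]; must cover every condition present
#'   in the design
#' @param seed non-negative integer seed for the response (and lapse) draws
#' @return the design data frame plus columns `response` (1 = comparison
#'   judged louder, 0 = probe louder) and `anchor_db`
#' @export
simulate_session <- function(design, params, seed = 0L) {
  stopifnot(inherits(design, "session_design"), inherits(params, "observer_params"))
  missing_w <- setdiff(unique(design$condition), names(params$w_by_condition))
  if (length(missing_w))
    stop2("loudreg_invalid_parameter",
          "no w entry for condition(s): %s", paste(missing_w, collapse = ", "))
  n <- nrow(design)
  w <- unname(params$w_by_condition[design$condition])
  s <- sqrt(params$noise_probe_db^2 + params$noise_comp_db^2)
  lam <- params$lapse
  alpha <- params$anchor_lr
  probe <- design$probe_db
  comp <- design$comparison_db
  out <- as.data.frame(design)
  with_seed(seed, {
    if (alpha == 0) {
      anchor <- rep(params$anchor_init_db, n)
      p <- lam / 2 + (1 - lam) * stats::pnorm((comp - (w * probe + (1 - w) * anchor)) / s)
      resp <- as.integer(stats::runif(n) < p)
    } else {
      anchor <- numeric(n)
      resp <- integer(n)
      mu <- params$anchor_init_db
      u <- stats::runif(n)
      for (i in seq_len(n)) {
        anchor[i] <- mu
        p <- lam / 2 + (1 - lam) *
          stats::pnorm((comp[i] - (w[i] * probe[i] + (1 - w[i]) * mu)) / s)
        resp[i] <- as.integer(u[i] < p)
        mu <- (1 - alpha) * mu + alpha * probe[i]
        mu <- (1 - alpha) * mu + alpha * comp[i]
      }
    }
    out$response <- resp
    out$anchor_db <- anchor
  })
  out
}

# inverse-CDF truncated-normal sampler (no extra dependency)
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) {
    if (mean < lower || mean > upper)
      stop2("loudreg_invalid_bounds", "point mass %g outside [%g, %g]", mean, lower, upper)
    return(rep(mean, n))
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  if (phi - plo <= 0)
    stop2("loudreg_invalid_bounds",
          "empty truncation: N(%g, %g) on [%g, %g]", mean, sd, lower, upper)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Draw a cohort of observer parameter sets
#'
#' Per-subject parameters are drawn from independent truncated normal
#' distributions; a scalar entry is treated as a point mass. Each subject's
#' draw uses an RNG stream derived from `(seed, subject id)`, so cohorts are
#' reproducible and insertion-order independent.
#'
#' @param n_subjects number of observers (>= 1)
#' @param condition condition label the varying `w` applies to; other
#'   conditions in `base_params` keep their base value
#' @param param_distribution named list; allowed names `w`, `anchor_init_db`,
#'   `anchor_lr`, `noise_probe_db`, `noise_comp_db`, `lapse`. Each element is
#'   either a single number (point mass) or `list(mean=, sd=, lower=, upper=)`
#' @param seed non-negative integer cohort seed
#' @param base_params template [observer_params()] supplying every field not
#'   listed in `param_distribution`
#' @return list of `n_subjects` [observer_params()] objects
#' @export
make_cohort <- function(n_subjects, condition, param_distribution = list(),
                        seed = 0L, base_params = observer_params()) {
  stopifnot(n_subjects >= 1)
  draw1 <- function(spec, sid, lower, upper) {
    if (is.numeric(spec) && length(spec) == 1L) return(spec)
    with_seed(subject_seed(seed, sid),
              rtruncnorm(1L, spec$mean, spec$sd,
                         max(spec$lower %||% lower, lower),
                         min(spec$upper %||% upper, upper)))
  }
  bounds <- list(w = c(0, 1), anchor_init_db = c(-Inf, Inf), anchor_lr = c(0, 1),
                 noise_probe_db = c(1e-6, Inf), noise_comp_db = c(1e-6, Inf),
                 lapse = c(0, 0.2))
  unknown <- setdiff(names(param_distribution), names(bounds))
  if (length(unknown))
    stop2("loudreg_invalid_parameter",
          "unknown parameter(s): %s", paste(unknown, collapse = ", "))
  lapply(seq_len(n_subjects), function(sid) {
    p <- unclass(base_params)
    for (nm in names(param_distribution)) {
      b <- bounds[[nm]]
      val <- draw1(param_distribution[[nm]], sid + 7919L * match(nm, names(bounds)),
                   b[1], b[2])
      if (nm == "w") p$w_by_condition[[condition]] <- val else p[[nm]] <- val
    }
    class(p) <- "observer_params"
    p
  })
}
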