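#' Aggregate 2AFC responses into a proportion table
#'
#' Collapses trial-level responses for one subject and probe level into one
#' row per comparison level with the proportion of "comparison louder"
#' responses, the per-subject averaging step that precedes psychometric
#' fitting.
#'
#' @param trials data frame of trial records (needs `probe_db`,
#'   `comparison_db`, `response`; optionally `subject`)
#' @param subject subject id to select, or NULL if `trials` holds one subject
#' @param probe_db probe level to select
#' @return data frame (`proportion_table`) with columns `probe_db`,
#'   `comparison_db`, `n_trials`, `prop_comparison_louder`
#' @export
aggregate_proportions <- function(trials, subject = NULL, probe_db) {
  if (!is.null(subject)) trials <- trials[trials$subject == subject, , drop = FALSE]
  trials <- trials[trials$probe_db == probe_db & !is.na(trials$response), , drop = FALSE]
  lv <- sort(unique(trials$comparison_db))
  if (length(lv) < 2L)
    stop2("loudreg_insufficient_data",
          "need responses at >= 2 comparison levels for probe %g", probe_db)
  n <- as.integer(tapply(trials$response, factor(trials$comparison_db, lv), length))
  p <- as.numeric(tapply(trials$response, factor(trials$comparison_db, lv), mean))
  structure(data.frame(probe_db = probe_db, comparison_db = lv,
                       n_trials = n, prop_comparison_louder = p),
            class = c("proportion_table", "data.frame"))
}

cg_sse <- function(par, x, p) sum((stats::pnorm(x, par[1], par[2]) - p)^2)

cg_nll <- function(par, x, k, n) {
  q <- stats::pnorm(x, par[1], par[2])
  q <- pmin(pmax(q, 1e-12), 1 - 1e-12)
  -sum(k * log(q) + (n - k) * log(1 - q))
}

#' Fit a cumulative Gaussian psychometric function
#'
#' Fits p(c) = Phi((c - PSE) / sigma) to a proportion table. The default is
#' nonlinear least squares on the averaged proportions; `method = "mle"`
#' maximises the Bernoulli likelihood of the (count-weighted) raw data
#' instead. The fitted mean is the point of subjective equality (PSE); the SD
#' is the spread. PSE is bounded to the probe level +/- 15 dB and sigma to
#' [0.1, 30] dB; a fit that lands on a bound is flagged as non-converged
#' rather than raising.
#'
#' @param table a `proportion_table` from [aggregate_proportions()] (columns
#'   `probe_db`, `comparison_db`, `n_trials`, `prop_comparison_louder`)
#' @param method `"lsq"` (default) or `"mle"`
#' @return list of class `psychometric_fit`: `pse_db`, `sigma_db`,
#'   `sse_or_loglik` (SSE for `"lsq"`, log-likelihood for `"mle"`),
#'   `converged`, `n_points`, `method`
#' @export
fit_cumulative_gaussian <- function(table, method = c("lsq", "mle")) {
  method <- match.arg(method)
  x <- table$comparison_db
  p <- table$prop_comparison_louder
  n <- table$n_trials
  if (length(x) < 3L)
    stop2("loudreg_insufficient_data", "need >= 3 comparison levels, got %d", length(x))
  if (stats::var(p) == 0)
    stop2("loudreg_degenerate_data",
          "all proportions equal (%g): no slope information", p[1])
  probe <- table$probe_db[1]
  lo <- c(probe - 15, 0.1)
  hi <- c(probe + 15, 30)
  # moment-style starts: 50% crossing by interpolation, spread from the
  # 16-84% span; plus fallback starts to dodge rare local minima
  cross <- tryCatch(stats::approx(p, x, xout = 0.5, ties = mean)$y,
                    error = function(e) NA_real_)
  s0 <- diff(range(x)) / 4
  starts <- list(c(if (is.finite(cross %||% NA)) cross else probe, s0),
                 c(probe, s0), c(probe, 2 * s0), c(probe - 5, s0), c(probe + 5, s0))
  obj <- if (method == "lsq") function(par) cg_sse(par, x, p)
         else function(par) cg_nll(par, x, round(p * n), n)
  best <- NULL
  for (st in starts) {
    st <- pmin(pmax(st, lo), hi)
    fit <- tryCatch(stats::optim(st, obj, method = "L-BFGS-B",
                                 lower = lo, upper = hi,
                                 control = list(factr = 1e4, maxit = 200)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    stop2("loudreg_degenerate_data", "optimizer failed on all starts")
  on_bound <- any(abs(best$par - lo) < 1e-8) || any(abs(best$par - hi) < 1e-8)
  structure(list(pse_db = best$par[1],
                 sigma_db = best$par[2],
                 sse_or_loglik = if (method == "lsq") best$value else -best$value,
                 converged = best$convergence == 0 && !on_bound,
                 n_points = length(x),
                 method = method),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("<psychometric_fit> PSE = %.3f dB, sigma = %.3f dB (%s, %s, %d levels)\n",
              x$pse_db, x$sigma_db, x$method,
              if (x$converged) "converged" else "NOT converged", x$n_points))
  invisible(x)
}

#' Catch-trial exclusion rule
#'
#' At the two extreme comparison offsets of each block (+/- 3 steps, the only
#' trials with a near-unambiguous correct answer) a response contradicting
#' the physical ordering of probe and comparison counts as an error. Errors
#' are pooled over the session; the subject is excluded when the error rate
#' strictly exceeds 25%.
#'
#' @param trials trial records of one subject's session (needs
#'   `probe_db`, `comparison_db`, `response`)
#' @param threshold exclusion threshold on the error rate, default 0.25
#' @return list: `excluded` (logical), `error_rate`, `n_catch`
#' @export
exclusion_check <- function(trials, threshold = 0.25) {
  ext <- do.call(rbind, lapply(split(trials, trials$probe_db), function(tr) {
    o <- tr$comparison_db - tr$probe_db
    tr[o == max(o) | o == min(o), , drop = FALSE]
  }))
  if (is.null(ext) || nrow(ext) == 0L)
    stop2("loudreg_missing_extremes", "no extreme-offset trials in session")
  ext <- ext[!is.na(ext$response), , drop = FALSE]
  if (nrow(ext) == 0L)
    stop2("loudreg_missing_extremes", "no responded extreme-offset trials in session")
  correct <- ifelse(ext$comparison_db > ext$probe_db, 1L, 0L)
  err <- mean(ext$response != correct)
  list(excluded = err > threshold, error_rate = err, n_catch = nrow(ext))
}
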