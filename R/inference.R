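anova_row <- function(effect, ss, df1, ss_err, df2, ss_total) {
  ms <- ss / df1
  ms_err <- ss_err / df2
  f <- if (ms_err > 0) ms / ms_err else 0
  p <- if (ms_err > 0) stats::pf(f, df1, df2, lower.tail = FALSE) else 1
  data.frame(effect = effect, F = f, df1 = as.integer(df1), df2 = as.integer(df2),
             p = p,
             eta_sq = if (ss_total > 0) ss / ss_total else 0,
             eta_sq_partial = if (ss + ss_err > 0) ss / (ss + ss_err) else 0,
             stringsAsFactors = FALSE)
}

#' Mixed within-between (split-plot) ANOVA
#'
#' Balanced univariate mixed ANOVA with one within-subject factor and one
#' between-subject grouping factor, computed from the classical
#' sums-of-squares decomposition with no sphericity correction. Reports the
#' within main effect (df1 = k-1, df2 = (k-1)(N-g)), the within-by-group
#' interaction (df1 = (k-1)(g-1)), and the between effect (df1 = g-1,
#' df2 = N-g), each with classical eta squared (SS_effect / SS_total) and
#' partial eta squared. With a single group the result is the one-way
#' repeated-measures ANOVA.
#'
#' @param data long data frame: one value per (subject, within level)
#' @param value,subject,within,group column names in `data`; `group` may be
#'   NULL for a pure repeated-measures design
#' @return data frame (`anova_table`): effect, F, df1, df2, p, eta_sq,
#'   eta_sq_partial
#' @export
mixed_anova <- function(data, value = "value", subject = "subject",
                        within = "within", group = NULL) {
  x <- data[[value]]
  s <- factor(data[[subject]])
  wl <- factor(data[[within]])
  gl <- if (is.null(group)) factor(rep("all", nrow(data))) else factor(data[[group]])
  k <- nlevels(wl)
  # balance checks: every subject x level exactly once, one group per subject
  tab <- table(s, wl)
  if (any(tab != 1L))
    stop2("loudreg_unbalanced_design",
          "each subject must contribute exactly one value per within level")
  subj_group <- tapply(as.integer(gl), s, function(v) length(unique(v)))
  if (any(subj_group != 1L))
    stop2("loudreg_unbalanced_design", "subjects must belong to exactly one group")
  g <- nlevels(gl)
  N <- nlevels(s)
  if (N < 2L || any(table(tapply(gl, s, `[`, 1)) < 2L))
    stop2("loudreg_unbalanced_design", "need >= 2 subjects per group")

  gm <- mean(x)
  ss_total <- sum((x - gm)^2)
  m_subj <- tapply(x, s, mean)
  ss_between_subj <- k * sum((m_subj - gm)^2)
  grp_of_subj <- tapply(as.character(gl), s, `[`, 1)
  m_grp <- tapply(x, gl, mean)
  n_grp <- table(grp_of_subj)[names(m_grp)]
  ss_group <- k * sum(n_grp * (m_grp - gm)^2)
  ss_subj_within <- ss_between_subj - ss_group
  m_lvl <- tapply(x, wl, mean)
  ss_within_lvl <- N * sum((m_lvl - gm)^2)
  cell <- tapply(x, list(gl, wl), mean)
  inter_dev <- sweep(sweep(cell, 1, m_grp), 2, m_lvl) + gm
  ss_inter <- sum(as.numeric(n_grp) * inter_dev^2)
  ss_err_within <- ss_total - ss_between_subj - ss_within_lvl - ss_inter
  ss_err_within <- max(ss_err_within, 0)

  df_err_w <- (k - 1) * (N - g)
  rows <- list(anova_row("within", ss_within_lvl, k - 1, ss_err_within,
                         df_err_w, ss_total))
  if (g > 1) {
    rows$ix <- anova_row("within:group", ss_inter, (k - 1) * (g - 1),
                         ss_err_within, df_err_w, ss_total)
    rows$bw <- anova_row("group", ss_group, g - 1, ss_subj_within, N - g, ss_total)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("anova_table", "data.frame")
  out
}

#' One-way between-subjects ANOVA
#'
#' @param values numeric vector of observations
#' @param groups group label per observation (>= 2 groups, >= 2 values each)
#' @return `anova_table` with one effect row (`group`)
#' @export
oneway_anova <- function(values, groups) {
  gl <- factor(groups)
  if (nlevels(gl) < 2L || any(table(gl) < 2L))
    stop2("loudreg_unbalanced_design", "need >= 2 groups with >= 2 values each")
  gm <- mean(values)
  ss_total <- sum((values - gm)^2)
  if (ss_total == 0)
    stop2("loudreg_degenerate_data", "total variance is zero")
  m <- tapply(values, gl, mean)
  n <- table(gl)
  ss_between <- sum(n * (m - gm)^2)
  ss_err <- ss_total - ss_between
  out <- anova_row("group", ss_between, nlevels(gl) - 1, ss_err,
                   length(values) - nlevels(gl), ss_total)
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Pooled-variance two-sample t-test with Cohen's d
#'
#' Two-sided Student t-test assuming equal variances, df = n1 + n2 - 2.
#' Cohen's d uses the pooled SD; `se` is the standard error of the mean
#' difference.
#'
#' @param x,y numeric samples (each n >= 2)
#' @return list of class `t_test_result`: `t`, `df`, `p`, `d`, `se`,
#'   `mean_diff`, `n1`, `n2`
#' @export
student_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 2, n2 >= 2)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df
  if (sp2 == 0)
    stop2("loudreg_degenerate_data", "pooled variance is zero")
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  md <- mean(x) - mean(y)
  tval <- md / se
  structure(list(t = tval, df = as.integer(df),
                 p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE),
                 d = md / sqrt(sp2), se = se, mean_diff = md,
                 n1 = n1, n2 = n2),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, p = %.4g, d = %.3f, s.e. = %.3f\n",
              x$df, x$t, x$p, x$d, x$se))
  invisible(x)
}

#' JZS Bayes factor for a two-sample t statistic
#'
#' Default Bayesian t-test: BF10 comparing the alternative with a Cauchy(0,
#' r) prior on the standardized effect size against the point null, computed
#' from the t statistic via the scale-mixture representation (effect size
#' normal given g, with g inverse-gamma(1/2, r^2/2)) and adaptive quadrature
#' over g at relative tolerance 1e-8. r = 0.707 reproduces the common
#' software default.
#'
#' @param t observed t statistic
#' @param n1,n2 group sizes (>= 2)
#' @param r Cauchy prior scale (> 0), default sqrt(2)/2 = 0.707
#' @return list of class `bf_result`: `bf10`, `r_scale`, `t_input`, `n1`,
#'   `n2`, `integration_error`
#' @export
jzs_bf10 <- function(t, n1, n2, r = 0.707) {
  stopifnot(n1 >= 2, n2 >= 2, r > 0)
  nu <- n1 + n2 - 2
  neff <- n1 * n2 / (n1 + n2)
  # integrand of BF10 over the mixing variable g, in ratio form (marginal
  # likelihood under the alternative divided by the null likelihood) to keep
  # magnitudes near 1
  f <- function(g) {
    ratio <- (1 + t^2 / nu) / (1 + t^2 / ((1 + neff * g) * nu))
    dig <- exp(0.5 * log(r^2 / 2) - lgamma(0.5) - 1.5 * log(g) - r^2 / (2 * g))
    (1 + neff * g)^(-0.5) * ratio^((nu + 1) / 2) * dig
  }
  res <- tryCatch(
    stats::integrate(f, 0, Inf, rel.tol = 1e-8, abs.tol = 0,
                     subdivisions = 500L),
    error = function(e)
      stop2("loudreg_integration_failure", "quadrature failed: %s",
            conditionMessage(e)))
  structure(list(bf10 = res$value, r_scale = r, t_input = t,
                 n1 = n1, n2 = n2, integration_error = res$abs.error),
            class = "bf_result")
}

#' @export
print.bf_result <- function(x, ...) {
  cat(sprintf("BF10 = %.4g (t = %.3f, n = %d/%d, Cauchy r = %.3f)\n",
              x$bf10, x$t_input, x$n1, x$n2, x$r_scale))
  invisible(x)
}
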