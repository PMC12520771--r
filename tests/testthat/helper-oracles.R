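# independent oracles used across test files

# Brute-force grid search for the cumulative-Gaussian SSE minimiser over
# PSE in probe +/- 15 and sigma in [0.1, 30]. A dense full-coverage scan
# (0.05 dB in PSE, ~1.4% log steps in sigma) locates the global basin, then
# two local refinements take the resolution to 2.5e-4 dB — well inside one
# 0.01 dB grid cell.
grid_fit_oracle <- function(table) {
  x <- table$comparison_db
  p <- table$prop_comparison_louder
  probe <- table$probe_db[1]
  best_on <- function(ps, sg) {
    best <- c(NA, NA, Inf)
    for (s in sg) {
      sse <- colSums((pnorm(outer(x, ps, `-`) / s) - p)^2)
      i <- which.min(sse)
      if (sse[i] < best[3]) best <- c(ps[i], s, sse[i])
    }
    best
  }
  b <- best_on(seq(probe - 15, probe + 15, by = 0.05),
               exp(seq(log(0.1), log(30), length.out = 400)))
  for (res in c(0.005, 0.00025)) {
    ps <- seq(max(probe - 15, b[1] - 25 * res), min(probe + 15, b[1] + 25 * res),
              by = res)
    sg <- seq(max(0.1, b[2] - 100 * res), min(30, b[2] + 100 * res), by = res)
    b <- best_on(ps, sg)
  }
  list(pse_db = b[1], sigma_db = b[2], sse = b[3])
}

cg_sse_of <- function(table, pse, sigma)
  sum((pnorm(table$comparison_db, pse, sigma) - table$prop_comparison_louder)^2)

# Monte-Carlo estimate of the observer's "comparison louder" probability by
# sampling percepts directly (independent of the closed-form path).
mc_p_comparison <- function(probe, comp, w, mu, sp, sc, lapse, n = 1e6) {
  probe_percept <- w * probe + (1 - w) * mu + rnorm(n, 0, sp)
  comp_percept <- comp + rnorm(n, 0, sc)
  resp <- as.numeric(comp_percept > probe_percept)
  if (lapse > 0) {
    lapsed <- runif(n) < lapse
    resp[lapsed] <- rbinom(sum(lapsed), 1, 0.5)
  }
  mean(resp)
}

# Fine-grid trapezoid integration of the two-sample JZS Bayes factor over the
# Cauchy effect-size prior, via the non-central t marginal likelihood and the
# substitution delta = r * tan(theta) (constant prior density 1/pi in theta).
jzs_bf10_trapezoid <- function(t, n1, n2, r = 0.707, n_grid = 8001) {
  nu <- n1 + n2 - 2
  neff <- n1 * n2 / (n1 + n2)
  theta <- seq(-pi / 2, pi / 2, length.out = n_grid)
  # dt(ncp=) warns about its own precision (~1e-8 on the density), which is
  # ample for a 4-significant-digit comparison
  f <- suppressWarnings(dt(t, nu, ncp = r * tan(theta) * sqrt(neff)) / pi)
  f[!is.finite(f)] <- 0
  h <- theta[2] - theta[1]
  m1 <- h * (sum(f) - (f[1] + f[n_grid]) / 2)
  m1 / dt(t, nu)
}

# deterministic proportion table from exact cumulative-Gaussian values
noiseless_table <- function(probe = 40, pse = 40, sigma = 2, step = 2) {
  x <- probe + step * (-3:3)
  structure(data.frame(probe_db = probe, comparison_db = x, n_trials = 10,
                       prop_comparison_louder = pnorm(x, pse, sigma)),
            class = c("proportion_table", "data.frame"))
}
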