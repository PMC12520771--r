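fake_fits <- function(subject, pse_by_level, condition = "baseline",
                      converged = TRUE) {
  data.frame(subject = subject, condition = condition,
             probe_db = as.numeric(names(pse_by_level)),
             pse_db = as.numeric(pse_by_level),
             converged = converged, stringsAsFactors = FALSE)
}

test_that("pse_deviations subtracts the physical level and drops bad fits", {
  fits <- fake_fits(1, c(`40` = 44, `80` = 76))
  dev <- pse_deviations(fits)
  expect_equal(dev$deviation_db, c(4, -4))
  fits$converged[2] <- FALSE
  expect_warning(dev2 <- pse_deviations(fits), "non-converged")
  expect_equal(nrow(dev2), 1)
  expect_error(pse_deviations(fake_fits(1, c(`40` = 44), converged = FALSE)),
               class = "loudreg_insufficient_data")
})

test_that("adaptation_index is the OLS slope of deviation against probe level", {
  # exact line: deviations (1-w)(60 - L) with w = 0.8 -> slope -0.2
  L <- c(40, 50, 60, 70, 80)
  dev <- data.frame(probe_db = L, deviation_db = 0.2 * (60 - L))
  ai <- adaptation_index(dev)
  expect_equal(ai$slope, -0.2)
  expect_equal(ai$intercept, 12)
  # all-zero deviations
  expect_equal(adaptation_index(data.frame(probe_db = L, deviation_db = 0))$slope, 0)
  # 5-point hand-computed OLS: {40:+3, 50:+2, 60:0, 70:-1, 80:-3}
  # slope = sum((L-60)(y-0.2)) / sum((L-60)^2) = -150/1000 = -0.15
  # intercept = 0.2 - slope*60 = 9.2
  dev2 <- data.frame(probe_db = L, deviation_db = c(3, 2, 0, -1, -3))
  ai2 <- adaptation_index(dev2)
  expect_equal(ai2$slope, -0.15)
  expect_equal(ai2$intercept, 9.2)
  # slope invariant to a constant shift; intercept absorbs it
  dev3 <- dev2; dev3$deviation_db <- dev3$deviation_db + 5
  ai3 <- adaptation_index(dev3)
  expect_equal(ai3$slope, ai2$slope)
  expect_equal(ai3$intercept, ai2$intercept + 5)
  expect_error(adaptation_index(data.frame(probe_db = 40, deviation_db = 1)),
               class = "loudreg_insufficient_levels")
})

test_that("half-split classification follows the blocks 1-2 / 4-5 rule", {
  fits <- rbind(fake_fits(1, c(`40` = 41, `50` = 50, `60` = 60, `70` = 70, `80` = 79)),
                fake_fits(2, c(`40` = 42, `50` = 50, `60` = 60, `70` = 70, `80` = 78)))
  orders <- list(`1` = c(40, 50, 60, 70, 80),   # 40 first half, 80 second half
                 `2` = c(50, 80, 40, 60, 70))   # 80 first half, 40 middle -> dropped
  summ <- subject_summaries(fits, block_orders = orders)
  hs <- half_split_contrast(summ)
  s1 <- hs[hs$subject == 1, ]
  expect_equal(s1$half[s1$probe_db == 40], "first")
  expect_equal(s1$half[s1$probe_db == 80], "second")
  s2 <- hs[hs$subject == 2, ]
  expect_equal(nrow(s2), 1)                      # 40-block in the middle is dropped
  expect_equal(s2$probe_db, 80)
  expect_equal(s2$half, "first")
  # both target blocks in the middle is impossible with 5 blocks, but a
  # subject with no classifiable block warns
  orders3 <- list(`1` = c(50, 60, 40, 70, 80))
  fits3 <- fake_fits(1, c(`40` = 41, `50` = 50, `60` = 60, `70` = 70, `80` = 79))
  fits3 <- fits3[fits3$probe_db %in% c(40, 50, 60), ]
  summ3 <- subject_summaries(fits3, block_orders = orders3)
  expect_warning(expect_error(half_split_contrast(summ3),
                              class = "loudreg_unclassifiable"),
                 "unclassifiable")
  expect_error(half_split_contrast(summ, block_orders = NULL),
               class = "loudreg_unclassifiable")
})

test_that("within-session anchor learning produces the half-split order effect", {
  # Mechanism check with a deliberately strong learner: quiet blocks heard
  # late in the session follow louder history, so their deviation is pulled
  # up relative to subjects who heard them first.
  pars <- observer_params(w_by_condition = c(baseline = 0.8),
                          anchor_init_db = 60, anchor_lr = 0.01,
                          noise_probe_db = 2, noise_comp_db = 2, lapse = 0)
  devs <- lapply(1:120, function(s) {
    tr <- simulate_session(make_exp1_design("baseline", 500 + s), pars, seed = s)
    tr$subject <- s
    ord <- tr$probe_db[!duplicated(tr$block)]
    pos40 <- match(40, ord)
    if (pos40 == 3) return(NULL)
    fits <- fit_trials(tr[tr$probe_db == 40, ])
    if (!fits$converged[1]) return(NULL)
    data.frame(half = if (pos40 <= 2) "first" else "second",
               dev = fits$pse_db[1] - 40)
  })
  devs <- do.call(rbind, devs)
  m <- tapply(devs$dev, devs$half, mean)
  expect_gt(m[["second"]], m[["first"]])
  # no learning -> no systematic order effect (difference within CI of 0)
  pars0 <- observer_params(w_by_condition = c(baseline = 0.8),
                           anchor_init_db = 60, anchor_lr = 0,
                           noise_probe_db = 2, noise_comp_db = 2, lapse = 0)
  devs0 <- lapply(1:120, function(s) {
    tr <- simulate_session(make_exp1_design("baseline", 500 + s), pars0, seed = s)
    tr$subject <- s
    ord <- tr$probe_db[!duplicated(tr$block)]
    pos40 <- match(40, ord)
    if (pos40 == 3) return(NULL)
    fits <- fit_trials(tr[tr$probe_db == 40, ])
    if (!fits$converged[1]) return(NULL)
    data.frame(half = if (pos40 <= 2) "first" else "second",
               dev = fits$pse_db[1] - 40)
  })
  devs0 <- do.call(rbind, devs0)
  tt <- student_t(devs0$dev[devs0$half == "second"], devs0$dev[devs0$half == "first"])
  expect_lt(abs(tt$t), qt(0.995, tt$df))
})

test_that("context_effects labels cells by context and tracks the anchor", {
  pars <- observer_params(w_by_condition = c(baseline = 0.94, active = 0.88),
                          anchor_lr = 0)
  mk_ctx_fits <- function(ctx, n, lr) {
    p <- pars; p$anchor_lr <- lr
    do.call(rbind, lapply(seq_len(n), function(s) {
      tr <- simulate_session(make_exp3_design(ctx, 900 + s), p, seed = 70 + s)
      tr$subject <- s + ifelse(ctx == "loud", 1000, 0)
      tr$context <- ctx
      fit_trials(tr)
    }))
  }
  # alpha = 0: test deviations equal matched baselines within CI
  fits <- rbind(mk_ctx_fits("quiet", 14, 0), mk_ctx_fits("loud", 14, 0))
  # a subject whose baseline fit failed to converge is reported by default
  # and dropped on request
  expect_error(context_effects(fits), class = "loudreg_missing_phase")
  ctx <- suppressWarnings(context_effects(fits, on_missing = "drop"))
  expect_setequal(unique(ctx$cell),
                  c("baseline_40", "baseline_80", "test_majority", "test_minority"))
  expect_true(all(ctx$probe_db[ctx$context == "quiet" & ctx$cell == "test_majority"] == 40))
  expect_true(all(ctx$probe_db[ctx$context == "loud" & ctx$cell == "test_majority"] == 80))
  # with a frozen anchor the only baseline/test difference is the condition
  # weight (0.94 vs 0.88): test-minority 40 dB in the loud context is pulled
  # up more than its baseline, by (0.94-0.88)*(60-40) = 1.2 dB in expectation
  q40 <- ctx[ctx$context == "loud" & ctx$cell == "test_minority", "deviation_db"]
  b40 <- ctx[ctx$context == "loud" & ctx$cell == "baseline_40", "deviation_db"]
  expect_gt(mean(q40) - mean(b40), 0)
  # alpha > 0: sign predictions from the adapting anchor
  fits_lr <- rbind(mk_ctx_fits("quiet", 14, 0.01), mk_ctx_fits("loud", 14, 0.01))
  ctx_lr <- suppressWarnings(context_effects(fits_lr, on_missing = "drop"))
  cm <- tapply(ctx_lr$deviation_db, list(ctx_lr$context, ctx_lr$cell), mean)
  # loud context: minority 40 dB strongly enhanced
  expect_gt(cm["loud", "test_minority"], cm["loud", "baseline_40"])
  # quiet context: minority 80 dB attenuated below its baseline
  expect_lt(cm["quiet", "test_minority"], cm["quiet", "baseline_80"])
  # missing phase signals
  expect_error(context_effects(fits[fits$phase != "test", ]),
               class = "loudreg_missing_phase")
})
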