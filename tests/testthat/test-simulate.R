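test_that("noise specs are validated against the effect range", {
  m_prob <- binary_generator_model(0.5)
  m_wide <- capacity_model(effect_range(2, 10), cause("g", "generator", 1))
  m_inf <- capacity_model(effect_range(Inf, Inf),
                          cause("g", "generator", 1, Inf))
  expect_error(simulate_trials(m_wide, noise_spec("bernoulli"),
                               design_bernoulli(), 10, seed = 1),
               "\\[0, 1\\]")
  expect_error(simulate_trials(m_inf, noise_spec("scaled-beta"),
                               design_bernoulli(), 10, seed = 1),
               "finite bounds")
  expect_error(simulate_trials(m_prob, noise_spec("gaussian", 0.1),
                               design_bernoulli(), 10, seed = 1),
               "unbounded")
  expect_error(simulate_trials(m_prob, noise_spec("bernoulli"),
                               design_bernoulli(), 0, seed = 1),
               "positive")
})

test_that("simulation is seed-deterministic and mean-correct", {
  m <- binary_generator_model(0.5, "g")
  tab_a <- simulate_trials(m, noise_spec("bernoulli"), design_bernoulli(1),
                           1e5, seed = 99)
  tab_b <- simulate_trials(m, noise_spec("bernoulli"), design_bernoulli(1),
                           1e5, seed = 99)
  expect_identical(as.data.frame(tab_a), as.data.frame(tab_b))
  # binomial oracle: mean within 4 sd of w = 0.5
  expect_lt(abs(mean(tab_a$effect) - 0.5), 4 * sqrt(0.25 / 1e5))

  # all causes clamped to zero: mean effect ~ 0 under scaled-beta noise
  m_c <- capacity_model(effect_range(1, 2), cause("g", "generator", 1))
  t0 <- simulate_trials(m_c, noise_spec("scaled-beta", 50),
                        design_bernoulli(0), 2e4, seed = 3)
  expect_true(all(t0$effect >= -1 & t0$effect <= 2))
  expect_lt(abs(mean(t0$effect)), 4 * sqrt(var(t0$effect) / 2e4) + 0.01)

  # gaussian noise around the linear mean
  m_inf <- capacity_model(effect_range(Inf, Inf),
                          cause("g", "generator", 1.5, Inf))
  tg <- simulate_trials(m_inf, noise_spec("gaussian", 0.5),
                        data.frame(g = 2), 2e4, seed = 4)
  expect_lt(abs(mean(tg$effect) - 3), 4 * 0.5 / sqrt(2e4))
})

test_that("scaled-beta conditional means track the model expectation", {
  m <- capacity_model(effect_range(2, 10),
                      list(cause("g", "generator", 2, 3),
                           cause("r", "reducer", 0.5, 4)))
  asg <- data.frame(g = 3, r = 2)
  mu <- evaluate_model(m, asg)
  tab <- simulate_trials(m, noise_spec("scaled-beta", 20), asg, 1e5, seed = 8)
  se <- sqrt(var(tab$effect) / 1e5)
  expect_lt(abs(mean(tab$effect) - mu), 4 * se)
})

test_that("value-sequence regimes encode the same pattern at different framings", {
  pat <- c(0, 0, 1, 0, 1, 1, 0, 0)
  bin <- generate_value_sequences("binary", 8, seed = 5, pattern = pat)
  nar <- generate_value_sequences("narrow-continuous", 8, seed = 5,
                                  pattern = pat)
  wid <- generate_value_sequences("wide-continuous", 8, seed = 5,
                                  pattern = pat)
  expect_identical(as.numeric(bin), pat)
  # narrow: same pattern after rounding; small jitter
  expect_identical(round(as.numeric(nar)), pat)
  expect_gt(max(abs(nar - pat)), 0)  # genuinely continuous
  # wide: two functionally distinct levels, far apart
  hi <- as.numeric(wid)[pat == 1]; lo <- as.numeric(wid)[pat == 0]
  expect_gt(min(hi), 5)
  expect_lt(max(abs(lo)), 1)
  # thresholding at half the functional gap recovers the pattern everywhere
  for (s in list(bin, nar, wid)) {
    gap <- attr(s, "functional_gap")
    expect_identical(as.numeric(as.numeric(s) > gap / 2), pat)
  }
  expect_error(generate_value_sequences("binary", 3, 1, pattern = c(1, 2, 0)),
               "pattern")
})

test_that("delta_p and causal_power follow their contingency definitions", {
  ct <- contingency_table(80, 20, 20, 80)
  expect_equal(delta_p(ct), 0.6)
  expect_equal(causal_power(ct), 0.75)
  expect_equal(delta_p(contingency_table(30, 70, 30, 70)), 0)
  expect_equal(delta_p(contingency_table(100, 0, 0, 100)), 1)
  expect_equal(causal_power(contingency_table(100, 0, 0, 100)), 1)
  # no background: power equals P(e | c)
  expect_equal(causal_power(contingency_table(60, 40, 0, 100)), 0.6)
  expect_error(delta_p(contingency_table(10, 10, 0, 0)), "cause-absent")
  expect_error(causal_power(contingency_table(10, 0, 50, 0)), "background")
  expect_error(causal_power(contingency_table(10, 90, 90, 10)), "preventive")
  expect_error(contingency_table(-1, 0, 0, 0), "nonnegative")
})

test_that("predicted judgments diverge exactly when the background rate is positive", {
  ct0 <- contingency_table(60, 40, 0, 100)   # zero background
  expect_equal(predicted_judgment(ct0, "noisy-or-and"),
               predicted_judgment(ct0, "linear"))
  ct1 <- contingency_table(80, 20, 20, 80)   # background rate 0.2
  expect_equal(predicted_judgment(ct1, "noisy-or-and"), 0.75)
  expect_equal(predicted_judgment(ct1, "linear"), 0.6)
  expect_gt(predicted_judgment(ct1, "noisy-or-and"),
            predicted_judgment(ct1, "linear"))
})

test_that("fit_weights recovers strengths and flags degenerate designs", {
  m <- binary_generator_model(0.5, "c")
  tab <- simulate_trials(m, noise_spec("bernoulli"), design_bernoulli(0.5),
                         10000, seed = 21)
  fit <- fit_weights(tab, m, noise_spec("bernoulli"), seed = 2)
  expect_true(fit$converged)
  expect_lt(abs(fit$strengths[["c"]] - 0.5), 0.05)

  # null recovery
  m0 <- binary_generator_model(0, "c")
  tab0 <- simulate_trials(m0, noise_spec("bernoulli"), design_bernoulli(0.5),
                          10000, seed = 22)
  fit0 <- fit_weights(tab0, m0, noise_spec("bernoulli"), seed = 2)
  expect_lte(fit0$strengths[["c"]], 0.02)

  # a cause never active is unidentifiable; the varying one is still fitted
  m2 <- binary_generator_model(c(0.4, 0.3), c("on", "off"))
  never_off <- function(n, model) {
    data.frame(on = stats::rbinom(n, 1, 0.5), off = 0)
  }
  tab2 <- simulate_trials(m2, noise_spec("bernoulli"), never_off,
                          2000, seed = 23)
  fit2 <- fit_weights(tab2, m2, noise_spec("bernoulli"), seed = 2)
  expect_identical(fit2$unidentifiable, "off")
  expect_true(is.na(fit2$strengths[["off"]]))
  expect_lt(abs(fit2$strengths[["on"]] - 0.4), 0.1)

  expect_error(fit_weights(tab2[1:5, ], m2, noise_spec("bernoulli")),
               "at least")
})

test_that("gaussian-noise fits recover linear strengths by least squares", {
  m <- capacity_model(effect_range(Inf, Inf),
                      list(cause("g", "generator", 1.2),
                           cause("r", "reducer", 0.7)))
  tab <- simulate_trials(m, noise_spec("gaussian", 0.3),
                         design_bernoulli(0.5), 4000, seed = 31)
  fit <- fit_weights(tab, m, noise_spec("gaussian", 0.3), seed = 2)
  expect_lt(abs(fit$strengths[["g"]] - 1.2), 0.05)
  expect_lt(abs(fit$strengths[["r"]] - 0.7), 0.05)
})

test_that("recovery_experiment is reproducible and consistent in n", {
  m <- binary_generator_model(0.5, "c")
  r1 <- recovery_experiment(m, noise_spec("bernoulli"), design_bernoulli(0.5),
                            n_grid = c(100, 1000), reps = 2, seed = 6)
  r2 <- recovery_experiment(m, noise_spec("bernoulli"), design_bernoulli(0.5),
                            n_grid = c(100, 1000), reps = 2, seed = 6)
  expect_identical(r1, r2)
  expect_lt(r1$rmse[r1$n == 1000], r1$rmse[r1$n == 100] + 0.05)
})
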