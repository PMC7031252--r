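test_that("change-point probability matches direct density arithmetic", {
  expect_equal(change_point_probability(0, 144, 0), 0)
  expect_equal(change_point_probability(0, 144, 1), 1)
  # independent oracle: plain evaluation of the posterior odds
  oracle <- (1 / 360 * 0.125) /
    (1 / 360 * 0.125 + dnorm(0, 0, 12) * (1 - 0.125))
  expect_equal(change_point_probability(0, 144, 0.125), oracle, tolerance = 1e-12)
  expect_equal(round(oracle, 4), 0.0118)
  expect_error(change_point_probability(0, 144, 1.2), "hazard")
  # strictly increasing in |delta| until the posterior saturates at 1
  deltas <- seq(0, 180, by = 5)
  omega <- change_point_probability(deltas, 144, 0.125)
  unsat <- omega < 1 - 1e-12
  expect_true(all(diff(omega[unsat]) > 0))
  expect_true(all(diff(omega) >= 0))
  expect_true(all(omega >= 0 & omega <= 1))
})

test_that("predictive variance inflates as model confidence drops", {
  expect_equal(predictive_variance(1, 144), 144)
  expect_equal(predictive_variance(0.5, 144), 288)
  expect_equal(predictive_variance(0.25, 144), 576)
  expect_true(is.finite(predictive_variance(0, 144)))  # floored, no div-by-zero
  expect_gte(predictive_variance(0.3, 144), 144)
})

test_that("uncertainty update resets, decays and stays in [0, 1)", {
  s2 <- 144
  expect_equal(uncertainty_update(1, 0.9, 50, s2), 0.5)   # certain change-point
  expect_equal(uncertainty_update(1, 0.1, -3, s2), 0.5)   # ... regardless of state
  expect_equal(uncertainty_update(0, 0, 10, s2), 0)       # confident stays confident
  expect_equal(uncertainty_update(0, 0.5, 10, s2), 1 / 3) # tau / (1 + tau)
  set.seed(4)
  tau <- runif(200); om <- runif(200); dl <- runif(200, -180, 180)
  out <- uncertainty_update(om, tau, dl, s2)
  expect_true(all(out >= 0 & out < 1))
})

test_that("learning rate and belief update obey their algebra", {
  expect_equal(learning_rate(1, 0.3), 1)
  expect_equal(learning_rate(0, 0), 0)
  expect_equal(learning_rate(0.2, 0.5), 0.6)
  expect_equal(belief_update(100, 0, 50), 100)
  expect_equal(belief_update(100, 1, 50), 150)
  expect_equal(belief_update(350, 1, 20), 10)  # wraps
  # alpha >= omega always (second term non-negative)
  set.seed(5)
  om <- runif(100); ta <- runif(100)
  expect_true(all(learning_rate(om, ta) >= om))
})

test_that("the learner converges on stable streams and spikes at jumps", {
  cfg <- task_config()
  # constant outcomes: belief pinned to the mean, uncertainty strictly decreasing
  tr <- run_learner(rep(200, 60), 0.025, cfg)
  expect_true(all(tr$belief == 200))
  expect_true(all(diff(tr$tau[-1]) < 0))
  expect_true(all(tr$sigma2 >= cfg$sigma_gen^2))

  # single injected 120-degree jump
  x <- rep(100, 80); x[41:80] <- 220
  trj <- run_learner(x, 0.025, cfg)
  expect_gt(trj$cpp[41], 0.95)
  expect_gt(trj$lrb[41], 0.95)
  expect_lt(max(trj$cpp[30:40]), 0.2)

  # zero-hazard limit: tau follows the closed-form tau/(1+tau) recursion
  tr0 <- run_learner(rep(50, 20), 1e-12, cfg)
  tau_expect <- Reduce(function(t, .) t / (1 + t), seq_len(19),
                       accumulate = TRUE, init = 1)
  expect_equal(tr0$tau, tau_expect, tolerance = 1e-6)
})

test_that("trace invariants hold on a simulated session and are reproducible", {
  task <- simulate_task(task_config(), seed = 31)
  tr <- run_learner(task$outcome, task$hazard)
  expect_true(all(tr$lrb >= 0 & tr$lrb <= 1))
  expect_true(all(tr$lrb >= tr$cpp))
  expect_equal(tr$lrb, tr$cpp + tr$ru)            # alpha = CPP + RU identically
  expect_true(all(tr$ru >= 0 & tr$ru <= 1))
  expect_gt(cor(tr$abs_peb, tr$cpp, method = "spearman"), 0.5)
  expect_identical(tr, run_learner(task$outcome, task$hazard))
  expect_error(run_learner(numeric(0), 0.1), "empty")
})
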