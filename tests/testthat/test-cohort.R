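test_that("dimension scores reproduce the requested correlation structure", {
  ident <- sample_dimension_scores(1000, diag(3), seed = 2)
  ri <- cor(ident[, c("ad", "cit", "sw")])
  expect_true(all(abs(ri[upper.tri(ri)]) < 0.1))

  sc <- sample_dimension_scores(2000, seed = 1)
  r <- cor(sc[, c("ad", "cit", "sw")])
  target <- default_dimension_correlations()
  expect_true(all(abs(r[upper.tri(r)] - target[upper.tri(target)]) < 0.05))
  expect_true(all(r[upper.tri(r)] >= 0.34 - 0.05 & r[upper.tri(r)] <= 0.52 + 0.05))
  expect_true(all(abs(colMeans(sc[, c("ad", "cit", "sw")])) < 0.1))

  expect_identical(sample_dimension_scores(50, seed = 9),
                   sample_dimension_scores(50, seed = 9))
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  expect_error(sample_dimension_scores(10, bad, 1), "positive definite")
})

test_that("effect maps shift agent parameters linearly and recover by OLS", {
  sc <- sample_dimension_scores(500, seed = 3)
  defaults <- agent_params()
  expect_equal(
    map_params(sc, null_effect_map(), defaults)$conf_intercept,
    rep(defaults$conf_intercept, 500)
  )
  eff <- tibble::tibble(dimension = "cit", parameter = "conf_intercept", effect = 3)
  pp <- map_params(sc, eff, defaults)
  subj2 <- which.max(sc$cit)
  expect_equal(pp$conf_intercept[subj2],
               defaults$conf_intercept + 3 * sc$cit[subj2])
  # regression of mapped parameters on scores returns the configured effect
  ols <- lm(pp$conf_intercept ~ sc$ad + sc$cit + sc$sw)
  expect_equal(unname(coef(ols)[["sc$cit"]]), 3, tolerance = 1e-10)
  expect_equal(unname(coef(ols)[["sc$ad"]]), 0, tolerance = 1e-10)
  expect_error(map_params(sc, tibble::tibble(dimension = "xx",
                                             parameter = "coupling",
                                             effect = 1)),
               "unknown")
})

test_that("a degenerate agent reproduces the normative learner exactly", {
  cfg <- task_config()
  task <- simulate_task(cfg, seed = 5)
  tr <- run_learner(task$outcome, task$hazard, cfg)
  par0 <- agent_params(w_cpp = 0, w_ru = 0, w_hit = 0, w_pe = 0, coupling = 0,
                       sw_pe_gain = 0, action_noise_sd = 0, conf_noise_sd = 0)
  beh <- simulate_agent(task, tr, par0, cfg, seed = 1)
  expect_equal(max(circular_distance(beh$bucket, tr$belief)), 0)
  expect_equal(length(unique(beh$confidence)), 1)
})

test_that("coupling and hit feedback shape simulated behaviour as configured", {
  cfg <- task_config()
  task <- simulate_task(cfg, seed = 6)
  tr <- run_learner(task$outcome, task$hazard, cfg)
  # confidence decoupled from evidence, strong coupling: within-agent
  # regression of update magnitude on confidence is negative
  par <- agent_params(w_cpp = 0, w_ru = 0, w_hit = 0, w_pe = 0,
                      coupling = 12, conf_noise_sd = 10, action_noise_sd = 2)
  beh <- simulate_agent(task, tr, par, cfg, seed = 2)
  n <- nrow(beh)
  upd <- circular_distance(beh$bucket[-1], beh$bucket[-n])
  zc <- scale(beh$confidence[-1])[, 1]
  expect_lt(unname(coef(lm(upd ~ zc))[2]), 0)

  par_hit <- agent_params(w_hit = 10, w_cpp = 0, w_ru = 0, w_pe = 0,
                          conf_noise_sd = 2)
  beh2 <- simulate_agent(task, tr, par_hit, cfg, seed = 3)
  conf_next <- beh2$confidence[-1]
  hit_prev <- beh2$hit[-n]
  expect_gt(mean(conf_next[hit_prev]), mean(conf_next[!hit_prev]))

  expect_error(simulate_agent(task[1:10, ], tr, par, cfg, 1), "misaligned")
})

test_that("cohorts have the expected shape, bounds and determinism", {
  coh <- small_cohort()
  expect_equal(nrow(coh$trials), 40 * 300)
  expect_equal(nrow(coh$subjects), 40)
  expect_true(all(coh$trials$confidence >= 1 & coh$trials$confidence <= 100))
  expect_true(all(coh$trials$bucket > 0 & coh$trials$bucket <= 360))
  expect_true(all(coh$trials$points %in% c(-10L, 10L)))
  coh_a <- simulate_cohort(5, seed = 77)
  coh_b <- simulate_cohort(5, seed = 77)
  expect_identical(coh_a$trials, coh_b$trials)
  expect_identical(coh_a$subjects, coh_b$subjects)
})
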