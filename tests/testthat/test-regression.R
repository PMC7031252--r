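make_exact_coupling_data <- function(n_subj = 12, n_trial = 40, d = 4) {
  # Action = 20 - d * z_conf exactly, no noise anywhere
  set.seed(33)
  purrr::map_dfr(seq_len(n_subj), function(s) {
    zc <- scale(rnorm(n_trial))[, 1]
    tibble::tibble(
      subject = s, trial = seq_len(n_trial), z_conf = zc,
      action = 20 - d * zc,
      age = rnorm(1), gender = rbinom(1, 1, 0.5), iq = rnorm(1),
      ad = 0, cit = 0, sw = 0, excluded = FALSE
    )
  })
}

test_that("noiseless linear data is recovered to numerical precision", {
  dat <- make_exact_coupling_data(d = 4)
  fit <- fit_coupling_model(dat)
  est <- tidy(fit)
  expect_equal(est$estimate[est$term == "z_conf"], -4, tolerance = 1e-6)
  expect_equal(est$estimate[est$term == "(Intercept)"], 20, tolerance = 1e-6)
  expect_true(all(c("se", "robust_se", "ci_lo", "ci_hi", "p", "p_bonf") %in%
                    names(est)))
})

test_that("a generated coupling slope is recovered when confidence is evidence-free", {
  # zero evidence weights: confidence is pure noise, so the coupling slope
  # has no confound with the learner's update term. The marginal slope is
  # kappa shrunk by the fraction of trials where the zero-clamp on the
  # magnitude or the 180-degree wrap binds (roughly 0.7-1.0 under this
  # configuration), so the estimate must fall in that analytic band.
  eff <- tibble::tibble(dimension = "cit", parameter = "coupling", effect = -2.5)
  coh <- simulate_cohort(
    120,
    effects = eff,
    defaults = agent_params(w_cpp = 0, w_ru = 0, w_hit = 0, w_pe = 0,
                            coupling = 9, conf_noise_sd = 12,
                            sw_pe_gain = 2, action_noise_sd = 4),
    seed = 301
  )
  adat <- prepare_analysis_data(coh)
  fit <- fit_coupling_model(adat, moderators = "cit", m = 1)
  est <- tidy(fit)
  b_conf <- est$estimate[est$term == "z_conf"]
  b_int <- est$estimate[est$term == "z_conf:cit"]
  expect_lt(b_conf, -0.7 * 9)
  expect_gt(b_conf, -1.05 * 9)
  # CIT reduces kappa by 2.5 deg/SD -> positive interaction (attenuation)
  # in the same shrinkage band
  expect_gt(b_int, 0.5 * 2.5)
  expect_lt(b_int, 1.1 * 2.5)
  expect_gt(percent_change_effect(b_int, b_conf), 0)
})

test_that("level models recover injected confidence effects within 2 SEs", {
  eff <- dplyr::bind_rows(
    tibble::tibble(dimension = "cit", parameter = "conf_intercept", effect = 6),
    tibble::tibble(dimension = "ad", parameter = "conf_intercept", effect = -3)
  )
  coh <- simulate_cohort(150, effects = eff, seed = 302)
  adat <- prepare_analysis_data(coh)
  fit <- fit_level_model(adat, "confidence", moderators = c("ad", "cit", "sw"),
                         m = 3)
  est <- tidy(fit)
  cit <- est[est$term == "cit", ]
  ad <- est[est$term == "ad", ]
  # slack beyond 2 SEs covers the mild attenuation from 1-100 clipping
  expect_lt(abs(cit$estimate - 6), 2 * cit$se + 0.65)
  expect_lt(abs(ad$estimate + 3), 2 * ad$se + 0.65)
  expect_equal(glance(fit)$n_subjects, 150)
})

test_that("evidence models recover the learner's additive update structure", {
  # uncoupled, near-noiseless agent: the generative update is exactly
  # (CPP + RU) * |PE|, so both interaction coefficients recover 1
  coh <- simulate_cohort(
    30,
    defaults = agent_params(coupling = 0, action_noise_sd = 1),
    effects = null_effect_map(),
    seed = 303
  )
  adat0 <- prepare_analysis_data(coh)
  fit <- fit_evidence_model(adat0, "action")
  est <- tidy(fit)
  expect_equal(est$estimate[est$term == "abs_peb:cpp"], 1, tolerance = 0.05)
  expect_equal(est$estimate[est$term == "abs_peb:ru"], 1, tolerance = 0.3)

  adat <- small_analysis_data()
  fitc <- fit_evidence_model(adat, "confidence")
  estc <- tidy(fitc)
  # default weights: CPP, RU, |PE| lower confidence; hits raise it
  expect_lt(estc$estimate[estc$term == "z_cpp"], 0)
  expect_lt(estc$estimate[estc$term == "z_ru"], 0)
  expect_gt(estc$estimate[estc$term == "hit"], 0)

  degen <- adat
  degen$hit <- 1L
  expect_error(fit_evidence_model(degen, "action"), "rank deficient")
})

test_that("separate and joint moderator regimes agree for a single moderator", {
  adat <- small_analysis_data()
  sep <- fit_coupling_model(adat, moderators = "cit", m = 1)
  joint <- fit_coupling_model(adat, moderators = "cit", m = 9)
  expect_equal(tidy(sep)$estimate, tidy(joint)$estimate, tolerance = 1e-10)
  expect_equal(tidy(joint)$p_bonf, pmin(1, 9 * tidy(joint)$p))
})

test_that("results are invariant to subject ordering", {
  adat <- small_analysis_data()
  shuffled <- adat[sample(nrow(adat)), ]
  f1 <- fit_level_model(adat, "confidence", moderators = "cit")
  f2 <- fit_level_model(shuffled, "confidence", moderators = "cit")
  expect_equal(tidy(f1)$estimate, tidy(f2)$estimate, tolerance = 1e-8)
})

test_that("clustered robust SEs match the sandwich oracle and flag edge cases", {
  set.seed(51)
  n <- 400; g <- rep(1:40, each = 10)
  x <- rnorm(n); y <- 1 + 2 * x + rnorm(n, sd = 1 + 0.5 * (g %% 4))
  fit <- lm(y ~ x)
  mine <- robust_se(fit, cluster = g)
  oracle <- sqrt(diag(sandwich::vcovCL(fit, cluster = g, type = "HC0",
                                       cadjust = TRUE)))
  expect_equal(mine$se, oracle, tolerance = 1e-10)

  # merMod route collapses to clustered OLS when the RE variance vanishes
  d <- data.frame(y = y, x = x, g = factor(g))
  mfit <- suppressMessages(lme4::lmer(y ~ x + (1 | g), data = d))
  expect_equal(robust_se(mfit)$se, oracle, tolerance = 1e-6)

  # homoskedastic independent data: robust ~ classical
  set.seed(52)
  yh <- 1 + 2 * x + rnorm(n)
  fh <- lm(yh ~ x)
  ratio <- robust_se(fh, cluster = seq_len(n))$se /
    sqrt(diag(vcov(fh)))
  expect_true(all(ratio > 0.9 & ratio < 1.1))

  # variance growing with x inflates the robust slope SE
  yv <- 1 + 2 * x + rnorm(n, sd = abs(x) + 0.1)
  fv <- lm(yv ~ x)
  expect_gt(robust_se(fv, cluster = seq_len(n))$se[["x"]],
            sqrt(diag(vcov(fv)))[["x"]])

  expect_error(robust_se(fit, cluster = rep(1, n)), "two clusters")
})

test_that("White's test detects variance structure and not its absence", {
  set.seed(61)
  n <- 300
  x1 <- rnorm(n); x2 <- rnorm(n)
  het <- lm(y ~ x1 + x2,
            data = data.frame(x1, x2, y = 1 + x1 + rnorm(n, sd = 0.2 + abs(x1))))
  expect_lt(white_test(het)$p_value, 0.01)

  reject <- replicate(100, {
    yy <- 1 + x1 + rnorm(n)
    white_test(lm(yy ~ x1 + x2))$p_value < 0.05
  })
  expect_lt(mean(reject), 0.12)  # near-nominal under homoskedasticity

  const <- lm(y ~ x1, data = data.frame(x1, y = 2 * x1))
  expect_equal(white_test(const)$statistic, 0)
})

test_that("bonferroni and percent-change follow their definitions", {
  expect_equal(bonferroni(0.01, 9), 0.09)
  expect_equal(bonferroni(0.2, 9), 1)
  expect_equal(bonferroni(c(0.04, 0.5), 1), c(0.04, 0.5))
  expect_error(bonferroni(0.1, 0))
  expect_equal(percent_change_effect(1.30, -8.85), 100 * 1.30 / 8.85)
  expect_equal(percent_change_effect(0, -5), 0)
  expect_warning(out <- percent_change_effect(1, 0), "undefined")
  expect_true(is.na(out))
})
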