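#' Reduced quasi-optimal Bayesian change-point learner
#'
#' @description
#' The learner tracks a point estimate `B` of the generative mean on the
#' circle with a delta rule, `B_{t+1} = wrap(B_t + alpha_t * delta_t)`, where
#' `delta_t` is the signed circular prediction error and the dynamic learning
#' rate combines two sources of uncertainty:
#'
#' * change-point probability `Omega` (CPP) -- the posterior probability that
#'   the latest outcome came from a freshly re-sampled distribution rather
#'   than the current one;
#' * relative uncertainty `tau = 1 - nu` -- uncertainty from imprecise
#'   estimation of the current mean; `nu` is "model confidence" (MC).
#'
#' `alpha_t = Omega_t + (1 - Omega_t) * tau_t`, and the regressor
#' `RU_t = (1 - Omega_t) * tau_t` is the second term on its own.
#'
#' The individual update equations are exported so each can be tested in
#' isolation; [run_learner()] iterates them over an outcome stream.
#'
#' @name normative_model
NULL

#' @describeIn normative_model Posterior change-point probability
#'   `Omega = U*H / (U*H + N(delta; 0, sigma2) * (1 - H))` with `U = 1/360`.
#'   The Gaussian density is evaluated at the signed circular error without a
#'   wrapped-normal correction (errors are far from 180 degrees in practice).
#' @param delta Signed circular prediction error, degrees.
#' @param sigma2 Predictive variance, degrees^2.
#' @param hazard Assumed hazard rate `H` in \[0, 1\].
#' @param config A [task_config()] (supplies the number of circle positions).
#' @export
change_point_probability <- function(delta, sigma2, hazard, config = task_config()) {
  if (any(hazard < 0 | hazard > 1)) {
    stop("hazard must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(all(sigma2 > 0))
  u <- 1 / config$circle_points
  lik_new <- u * hazard
  lik_same <- stats::dnorm(delta, mean = 0, sd = sqrt(sigma2)) * (1 - hazard)
  lik_new / (lik_new + lik_same)
}

#' @describeIn normative_model Variance of the predictive distribution,
#'   `sigma_t^2 = sigma_N^2 + (1 - nu) * sigma_N^2 / nu = sigma_N^2 / nu`;
#'   equals the generative variance when the model is fully confident and
#'   inflates as confidence drops. `nu` is floored at 1e-6.
#' @param nu Model confidence in (0, 1].
#' @param sigma_n2 Generative outcome variance, degrees^2.
#' @export
predictive_variance <- function(nu, sigma_n2) {
  nu <- pmax(nu, 1e-6)
  sigma_n2 + (1 - nu) * sigma_n2 / nu
}

#' @describeIn normative_model Relative-uncertainty update. The next
#'   uncertainty is a variance ratio: expected estimation variance (weighted
#'   over change-point vs. no-change-point, plus the variance induced by not
#'   knowing which occurred) over that quantity plus the outcome noise
#'   `sigma_N^2`. Returns `tau_{t+1}` in \[0, 1); model confidence for the
#'   next trial is `1 - tau_{t+1}`. After a certain change-point
#'   (`omega = 1`) uncertainty resets to 0.5; with `omega = 0` it decays as
#'   `tau / (1 + tau)`.
#' @param omega Change-point probability for the current trial.
#' @param tau Current relative uncertainty (`1 - nu`).
#' @export
uncertainty_update <- function(omega, tau, delta, sigma_n2) {
  nu <- 1 - tau
  num <- omega * sigma_n2 +
    (1 - omega) * tau * sigma_n2 +
    omega * (1 - omega) * (delta * nu)^2
  num / (num + sigma_n2)
}

#' @describeIn normative_model Dynamic learning rate
#'   `alpha = Omega + (1 - Omega) * tau`, in \[0, 1\].
#' @export
learning_rate <- function(omega, tau) {
  omega + (1 - omega) * tau
}

#' @describeIn normative_model Delta-rule belief update with wrapping.
#' @param belief Current belief `B_t`, degrees.
#' @param alpha Learning rate in \[0, 1\].
#' @export
belief_update <- function(belief, alpha, delta) {
  wrap_position(belief + alpha * delta)
}

#' Run the learner over an outcome stream
#'
#' Iterates the update equations across trials. The belief is initialised at
#' the first outcome (so `delta_1 = 0`) and relative uncertainty starts
#' maximal (`tau_1 = 1`). The trace is deterministic given its inputs.
#'
#' @param outcomes Per-trial particle locations, degrees.
#' @param hazards Per-trial assumed hazard rates (scalar or vector); the task
#'   block's true hazard in the standard analysis.
#' @param config A [task_config()].
#' @return A tibble with one row per trial: `trial`, `belief` (B before
#'   seeing the outcome), `peb` (signed delta), `abs_peb`, `cpp`, `mc` (nu),
#'   `tau`, `ru` (`(1-cpp)*tau`), `lrb` (alpha), `sigma2`, `belief_next`.
#' @examples
#' task <- simulate_task(task_config(), seed = 1)
#' trace <- run_learner(task$outcome, task$hazard)
#' cor(abs(trace$peb), trace$cpp, method = "spearman")
#' @export
run_learner <- function(outcomes, hazards, config = task_config()) {
  n <- length(outcomes)
  if (n == 0) stop("empty outcome sequence", call. = FALSE)
  hazards <- rep_len(hazards, n)

  belief <- numeric(n)
  peb <- numeric(n)
  cpp <- numeric(n)
  tau <- numeric(n)
  lrb <- numeric(n)
  sigma2 <- numeric(n)
  belief_next <- numeric(n)

  b <- outcomes[1]
  t_u <- 1
  for (t in seq_len(n)) {
    belief[t] <- b
    d <- signed_circular_error(outcomes[t], b)
    nu <- 1 - t_u
    s2 <- predictive_variance(nu, config$sigma_gen^2)
    om <- change_point_probability(d, s2, hazards[t], config)
    a <- learning_rate(om, t_u)
    peb[t] <- d
    tau[t] <- t_u
    sigma2[t] <- s2
    cpp[t] <- om
    lrb[t] <- a
    b <- belief_update(b, a, d)
    belief_next[t] <- b
    t_u <- uncertainty_update(om, tau[t], d, config$sigma_gen^2)
  }

  tibble::tibble(
    trial = seq_len(n),
    belief = belief,
    peb = peb,
    abs_peb = abs(peb),
    cpp = cpp,
    mc = 1 - tau,
    tau = tau,
    ru = (1 - cpp) * tau,
    lrb = lrb,
    sigma2 = sigma2,
    belief_next = belief_next
  )
}
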