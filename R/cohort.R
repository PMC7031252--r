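#' Default correlation structure of the transdiagnostic dimensions
#'
#' Pairwise correlations of the three symptom dimensions (AD
#' anxious-depression, CIT compulsive behaviour and intrusive thought, SW
#' social withdrawal). The defaults span the moderate range reported for
#' factor scores derived from the 209-item battery: AD-CIT 0.52, AD-SW 0.43,
#' CIT-SW 0.34.
#'
#' @param r_ad_cit,r_ad_sw,r_cit_sw Pairwise correlations.
#' @return A 3x3 correlation matrix with dimnames `ad`, `cit`, `sw`.
#' @export
default_dimension_correlations <- function(r_ad_cit = 0.52,
                                           r_ad_sw = 0.43,
                                           r_cit_sw = 0.34) {
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- r_ad_cit
  r[1, 3] <- r[3, 1] <- r_ad_sw
  r[2, 3] <- r[3, 2] <- r_cit_sw
  dimnames(r) <- list(c("ad", "cit", "sw"), c("ad", "cit", "sw"))
  r
}

#' Sample correlated dimension scores and covariates
#'
#' Draws standardized AD/CIT/SW scores from a multivariate normal with the
#' given correlation matrix, plus independent standardized age and IQ and a
#' Bernoulli(0.42) female indicator (`gender = 1` for female, matching the
#' 42.3% female analysis sample).
#'
#' @param n_subjects Number of subjects.
#' @param correlations 3x3 positive-definite correlation matrix
#'   (rows/columns ad, cit, sw).
#' @param seed Integer seed.
#' @return A tibble: `subject`, `ad`, `cit`, `sw`, `age`, `gender`, `iq`.
#' @examples
#' scores <- sample_dimension_scores(2000, seed = 1)
#' cor(scores[, c("ad", "cit", "sw")])
#' @export
sample_dimension_scores <- function(n_subjects,
                                    correlations = default_dimension_correlations(),
                                    seed = 1L) {
  stopifnot(is.matrix(correlations), nrow(correlations) == 3, ncol(correlations) == 3)
  ch <- tryCatch(chol(correlations), error = function(e) NULL)
  if (is.null(ch)) {
    stop("correlation matrix must be positive definite", call. = FALSE)
  }
  set.seed(seed)
  z <- matrix(stats::rnorm(n_subjects * 3), n_subjects, 3) %*% ch
  tibble::tibble(
    subject = seq_len(n_subjects),
    ad = z[, 1],
    cit = z[, 2],
    sw = z[, 3],
    age = stats::rnorm(n_subjects),
    gender = stats::rbinom(n_subjects, 1, 0.42),
    iq = stats::rnorm(n_subjects)
  )
}

#' Population-default agent parameters
#'
#' Generative behaviour parameters of a synthetic agent. These are artifact
#' constructs (the study they emulate measures, but does not model, the
#' participant's generative process): confidence is built from the same
#' evidence variables the confidence regression tests, and the action update
#' tracks the normative learner's update with confidence-coupled modulation.
#'
#' @param conf_intercept Baseline confidence, scale units (1--100).
#' @param w_cpp,w_ru,w_pe Confidence evidence weights: units of confidence
#'   lost per within-subject SD of change-point probability, relative
#'   uncertainty, and |prediction error|.
#' @param w_hit Confidence units gained after a hit.
#' @param coupling Action-confidence coupling `kappa`: degrees of update
#'   magnitude lost per SD of the agent's own confidence. The default mirrors
#'   the headline within-subject coupling size (8.85 degrees/SD).
#' @param sw_pe_gain Extra action sensitivity to |prediction error|
#'   (dimensionless gain on `|PE^b|`).
#' @param action_noise_sd Motor noise SD on the update magnitude, degrees.
#' @param conf_noise_sd Report noise SD on confidence, scale units.
#' @return A named list of class `predinf_agent_params`.
#' @export
agent_params <- function(conf_intercept = 55,
                         w_cpp = 5,
                         w_ru = 5,
                         w_hit = 5,
                         w_pe = 3,
                         coupling = 8.85,
                         sw_pe_gain = 0,
                         action_noise_sd = 8,
                         conf_noise_sd = 10) {
  stopifnot(action_noise_sd >= 0, conf_noise_sd >= 0)
  structure(
    list(
      conf_intercept = conf_intercept,
      w_cpp = w_cpp, w_ru = w_ru, w_hit = w_hit, w_pe = w_pe,
      coupling = coupling, sw_pe_gain = sw_pe_gain,
      action_noise_sd = action_noise_sd, conf_noise_sd = conf_noise_sd
    ),
    class = "predinf_agent_params"
  )
}

#' Default effect map: how dimensions shift agent parameters
#'
#' Linear effect of +1 SD of each dimension on each agent parameter. The
#' default signs and sizes mirror the reported moderation structure: CIT
#' raises baseline confidence (+6.74 units/SD) while blunting the influence
#' of change-point probability, relative uncertainty and hit feedback on
#' confidence and attenuating action-confidence coupling (-1.57 degrees/SD);
#' AD lowers baseline confidence (-3.42 units/SD); SW increases action
#' updating through extra sensitivity to new prediction errors. Sizes are
#' configuration, not empirical claims.
#'
#' @return A tibble: `dimension`, `parameter`, `effect`.
#' @export
default_effect_map <- function() {
  tibble::tribble(
    ~dimension, ~parameter,       ~effect,
    "cit",      "conf_intercept",  6.74,
    "cit",      "coupling",       -1.57,
    "cit",      "w_cpp",          -1.50,
    "cit",      "w_ru",           -1.50,
    "cit",      "w_hit",          -1.50,
    "ad",       "conf_intercept", -3.42,
    "sw",       "sw_pe_gain",      0.05
  )
}

#' An effect map with every entry zero (null cohort)
#'
#' @return A tibble like [default_effect_map()] with all effects 0.
#' @export
null_effect_map <- function() {
  dplyr::mutate(default_effect_map(), effect = 0)
}

#' Map dimension scores onto per-subject agent parameters
#'
#' `param_i = default + sum_dim effect[dim, param] * score_i[dim]`,
#' deterministically.
#'
#' @param scores Subject table from [sample_dimension_scores()].
#' @param effects Effect map tibble (`dimension`, `parameter`, `effect`).
#' @param defaults Population defaults from [agent_params()].
#' @return A tibble with one row per subject and one column per agent
#'   parameter (plus `subject`).
#' @export
map_params <- function(scores,
                       effects = default_effect_map(),
                       defaults = agent_params()) {
  stopifnot(inherits(defaults, "predinf_agent_params"))
  bad_dim <- setdiff(unique(effects$dimension), c("ad", "cit", "sw"))
  bad_par <- setdiff(unique(effects$parameter), names(defaults))
  if (length(bad_dim) > 0 || length(bad_par) > 0) {
    stop("unknown effect-map entries: ",
         paste(c(bad_dim, bad_par), collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(subject = scores$subject)
  for (p in names(defaults)) {
    val <- rep(defaults[[p]], nrow(scores))
    eff <- effects[effects$parameter == p, , drop = FALSE]
    if (nrow(eff) > 0) {
      for (k in seq_len(nrow(eff))) {
        val <- val + eff$effect[k] * scores[[eff$dimension[k]]]
      }
    }
    out[[p]] <- val
  }
  out
}

conf_reference_moments <- function(par) {
  mu <- par$conf_intercept + 0.5 * par$w_hit
  sd <- sqrt(par$w_cpp^2 + par$w_ru^2 + par$w_pe^2 +
               0.25 * par$w_hit^2 + par$conf_noise_sd^2)
  list(mu = mu, sd = max(sd, 1))
}

#' Simulate one agent's actions and confidence reports
#'
#' Given a task session and the normative learner's trace over the same
#' outcomes, generates the agent's bucket placements and confidence reports
#' trial by trial:
#'
#' * confidence on trial `t+1` is a clipped linear read-out of trial-`t`
#'   evidence: `conf_intercept - w_cpp*z(CPP_t) - w_ru*z(RU_t) +
#'   w_hit*Hit_t - w_pe*z(|PE^b_t|) + noise`, rounded onto 1--100;
#' * the bucket update magnitude from `t` to `t+1` is
#'   `LR^b_t*|PE^b_t| + sw_pe_gain*|PE^b_t| - coupling*z(conf_{t+1}) + noise`,
#'   clamped at zero and applied along the sign of `PE^b_t` with wrapping.
#'
#' Confidence is standardised inside the simulation with a deterministic
#' reference scale derived from the agent's parameters (the empirical
#' within-subject z-score is only available once the session is complete);
#' evidence variables are z-scored over the session's evidence trials. Hits
#' are re-scored from the agent's own bucket, so feedback feeds back into
#' confidence. With all weights, noises, coupling and gain at zero the agent
#' reproduces the normative learner's belief trajectory exactly.
#'
#' @param trials Session tibble from [simulate_task()].
#' @param trace Learner trace from [run_learner()] on the same outcomes.
#' @param params A [agent_params()] (possibly subject-specific values).
#' @param config A [task_config()].
#' @param seed Integer seed.
#' @return A tibble: `trial`, `bucket`, `confidence`, `hit`, `points`.
#' @export
simulate_agent <- function(trials, trace, params, config = task_config(), seed = 1L) {
  n <- nrow(trials)
  if (nrow(trace) != n) stop("trials and trace are misaligned", call. = FALSE)
  stopifnot(inherits(params, "predinf_agent_params") || is.list(params))
  set.seed(seed)

  ev_idx <- seq_len(max(n - 1L, 1L))
  z_cpp <- zscore_vector(trace$cpp[ev_idx])
  z_ru <- zscore_vector(trace$ru[ev_idx])
  z_pe <- zscore_vector(trace$abs_peb[ev_idx])
  ref <- conf_reference_moments(params)
  clip_conf <- function(x) {
    pmin(pmax(round(x), config$confidence_min), config$confidence_max)
  }

  conf_noise <- stats::rnorm(n, 0, params$conf_noise_sd)
  act_noise <- stats::rnorm(n, 0, params$action_noise_sd)

  bucket <- numeric(n)
  confidence <- integer(n)
  hit <- logical(n)
  bucket[1] <- trace$belief[1]
  confidence[1] <- clip_conf(params$conf_intercept + conf_noise[1])

  for (t in seq_len(n)) {
    hit[t] <- circular_distance(trials$outcome[t], bucket[t]) <= config$bucket_halfwidth
    if (t < n) {
      c_next <- clip_conf(
        params$conf_intercept -
          params$w_cpp * z_cpp[t] -
          params$w_ru * z_ru[t] +
          params$w_hit * hit[t] -
          params$w_pe * z_pe[t] +
          conf_noise[t + 1]
      )
      confidence[t + 1] <- c_next
      z_c <- (c_next - ref$mu) / ref$sd
      magnitude <- trace$lrb[t] * trace$abs_peb[t] +
        params$sw_pe_gain * trace$abs_peb[t] -
        params$coupling * z_c +
        act_noise[t]
      magnitude <- max(magnitude, 0)
      bucket[t + 1] <- wrap_position(bucket[t] + sign(trace$peb[t]) * magnitude)
    }
  }

  tibble::tibble(
    trial = trials$trial,
    bucket = bucket,
    confidence = confidence,
    hit = hit,
    points = ifelse(hit, config$points_hit, config$points_miss)
  )
}

#' Simulate a full synthetic cohort
#'
#' Draws `n_subjects` subjects with correlated dimension scores, maps the
#' scores through the effect map onto agent parameters, gives every subject
#' an independent task session (schedule, means, outcomes), runs the
#' normative learner on each outcome stream, and simulates the agent's
#' behaviour. The default cohort size mirrors the 437-participant analysis
#' sample.
#'
#' @param n_subjects Number of subjects (default 437).
#' @param config A [task_config()].
#' @param effects Effect map tibble (default [default_effect_map()]).
#' @param defaults Population-default [agent_params()].
#' @param correlations Dimension correlation matrix.
#' @param seed Master integer seed; per-subject sub-seeds are derived from
#'   it, so a fixed master seed reproduces the dataset exactly.
#' @return A list of class `predinf_cohort` with tibbles:
#'   * `trials`: subject, trial, block, condition, hazard, mean, outcome,
#'     is_cp, bucket, confidence, hit, points;
#'   * `subjects`: dimension scores, covariates and the true per-subject
#'     agent parameters (for recovery checks);
#'   * `trace`: the per-subject learner trace.
#' @examples
#' \donttest{
#' coh <- simulate_cohort(n_subjects = 20, seed = 1)
#' nrow(coh$trials)  # 20 * 300
#' }
#' @export
simulate_cohort <- function(n_subjects = 437L,
                            config = task_config(),
                            effects = default_effect_map(),
                            defaults = agent_params(),
                            correlations = default_dimension_correlations(),
                            seed = 1L) {
  scores <- sample_dimension_scores(n_subjects, correlations, seed = seed)
  params <- map_params(scores, effects, defaults)
  set.seed(seed + 1L)
  sub_seeds <- matrix(
    sample.int(.Machine$integer.max - 3L, n_subjects * 2L),
    ncol = 2L
  )

  sessions <- purrr::map(seq_len(n_subjects), function(i) {
    task <- simulate_task(config, seed = sub_seeds[i, 1])
    trace <- run_learner(task$outcome, task$hazard, config)
    par_i <- params[i, setdiff(names(params), "subject")]
    par_i <- structure(as.list(par_i), class = "predinf_agent_params")
    beh <- simulate_agent(task, trace, par_i, config, seed = sub_seeds[i, 2])
    list(
      trials = dplyr::mutate(
        dplyr::bind_cols(task, beh[, c("bucket", "confidence", "hit", "points")]),
        subject = i, .before = 1
      ),
      trace = dplyr::mutate(trace, subject = i, .before = 1)
    )
  })

  out <- list(
    trials = dplyr::bind_rows(purrr::map(sessions, "trials")),
    subjects = dplyr::left_join(scores, params, by = "subject"),
    trace = dplyr::bind_rows(purrr::map(sessions, "trace"))
  )
  class(out) <- "predinf_cohort"
  out
}

#' @export
print.predinf_cohort <- function(x, ...) {
  cat("<predinf_cohort> ", length(unique(x$trials$subject)), " subjects, ",
      nrow(x$trials), " trial rows\n", sep = "")
  invisible(x)
}
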