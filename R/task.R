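#' Build a change-point schedule
#'
#' Lays out one session: two hazard stretches (stable/volatile, order
#' randomised by `seed`) of `stretch_len` trials each, with exactly the
#' configured number of change-points per stretch. Change-point positions are
#' drawn uniformly without replacement from trials 2..`stretch_len` of each
#' stretch, so neither the session's first trial nor the first trial of a
#' stretch is flagged. Fixed counts -- not per-trial Bernoulli draws --
#' generate the schedule; the hazard value is what the learner assumes.
#'
#' @param config A [task_config()].
#' @param seed Integer seed; the schedule is deterministic given `seed`.
#' @return A tibble with one row per trial: `trial`, `block`, `condition`
#'   (`"stable"`/`"volatile"`), `hazard`, `is_cp`.
#' @examples
#' sched <- build_schedule(task_config(), seed = 1)
#' table(sched$condition, sched$is_cp)
#' @export
build_schedule <- function(config = task_config(), seed = 1L) {
  validate_task_config(config)
  set.seed(seed)
  order_stable_first <- stats::runif(1) < 0.5
  conditions <- if (order_stable_first) c("stable", "volatile") else c("volatile", "stable")
  per_stretch <- purrr::map(conditions, function(cond) {
    hz <- if (cond == "stable") config$hazard_stable else config$hazard_volatile
    k <- if (cond == "stable") config$cp_count_stable else config$cp_count_volatile
    is_cp <- rep(FALSE, config$stretch_len)
    if (k > 0) {
      is_cp[sample(2:config$stretch_len, k)] <- TRUE
    }
    tibble::tibble(condition = cond, hazard = hz, is_cp = is_cp)
  })
  out <- dplyr::bind_rows(per_stretch)
  out$trial <- seq_len(config$n_trials)
  out$block <- ((out$trial - 1L) %/% config$block_len) + 1L
  dplyr::select(out, "trial", "block", "condition", "hazard", "is_cp")
}

#' Sample generative means along a schedule
#'
#' The generative mean is drawn uniformly over the circle's integer positions
#' on the first trial and re-drawn at every change-point; it is constant in
#' between (block breaks do not reset it).
#'
#' @param schedule A schedule from [build_schedule()].
#' @param config A [task_config()].
#' @param seed Integer seed.
#' @return Integer vector of per-trial generative means in 1..360.
#' @export
sample_generative_means <- function(schedule, config = task_config(), seed = 1L) {
  set.seed(seed)
  redraw <- schedule$is_cp
  redraw[1] <- TRUE
  new_means <- sample.int(config$circle_points, sum(redraw), replace = TRUE)
  segment <- cumsum(redraw)
  new_means[segment]
}

#' Sample particle landing locations
#'
#' Each outcome is the generative mean plus independent Gaussian noise with
#' SD `sigma_gen`, wrapped onto the circle and rounded to an integer
#' position.
#'
#' @param means Per-trial generative means (degrees).
#' @param config A [task_config()].
#' @param seed Integer seed.
#' @return Integer vector of outcomes in 1..360.
#' @examples
#' x <- sample_outcomes(rep(180, 5000), task_config(), seed = 7)
#' sd(signed_circular_error(x, 180))  # close to 12
#' @export
sample_outcomes <- function(means, config = task_config(), seed = 1L) {
  set.seed(seed)
  eps <- stats::rnorm(length(means), mean = 0, sd = config$sigma_gen)
  as.integer(wrap_position(round(means + eps)))
}

#' Score a trial
#'
#' A hit occurs iff the circular distance between the outcome and the bucket
#' centre is at most the bucket half-width (boundary inclusive); hits gain
#' `points_hit`, misses lose `|points_miss|`.
#'
#' @param bucket,outcome Positions in degrees (vectorised).
#' @param config A [task_config()].
#' @return A tibble with logical `hit` and integer `points`.
#' @export
score_trial <- function(bucket, outcome, config = task_config()) {
  hit <- circular_distance(outcome, bucket) <= config$bucket_halfwidth
  tibble::tibble(
    hit = hit,
    points = ifelse(hit, config$points_hit, config$points_miss)
  )
}

#' Simulate one task session (environment only)
#'
#' Convenience wrapper chaining [build_schedule()],
#' [sample_generative_means()] and [sample_outcomes()] with sub-seeds derived
#' from `seed`.
#'
#' @param config A [task_config()].
#' @param seed Integer seed.
#' @return A tibble with `trial`, `block`, `condition`, `hazard`, `is_cp`,
#'   `mean`, `outcome`.
#' @export
simulate_task <- function(config = task_config(), seed = 1L) {
  sched <- build_schedule(config, seed = seed)
  mu <- sample_generative_means(sched, config, seed = seed + 1L)
  x <- sample_outcomes(mu, config, seed = seed + 2L)
  dplyr::mutate(sched, mean = mu, outcome = x)
}

#' Write a tidy trial table to CSV
#'
#' @param trials A tidy trial tibble (e.g. from [simulate_cohort()]).
#' @param path Output file.
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}
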