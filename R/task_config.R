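#' Task configuration
#'
#' Builds the configuration of the circular predictive-inference task: 300
#' trials in 4 blocks of 75, two 150-trial hazard stretches (stable, hazard
#' 0.025 with exactly 4 change-points; volatile, hazard 0.125 with exactly
#' 19), Gaussian outcome noise with SD 12 degrees on a 360-point circle,
#' confidence reported on 1--100, and +/-10 points for a hit/miss.
#'
#' The bucket arc half-width is not a task statistic of the original design
#' that we can pin down; it defaults to 25 degrees (a value that puts a
#' normative agent's hit rate mid-range) and any quantity that depends on it
#' inherits that choice.
#'
#' @param n_trials Total trials per session.
#' @param n_blocks Number of blocks (breaks between blocks do not reset the
#'   generative mean).
#' @param block_len Trials per block.
#' @param stretch_len Trials per hazard stretch; two stretches per session.
#' @param hazard_stable,hazard_volatile Assumed per-trial change-point
#'   probabilities of the two conditions (the learner's `H`).
#' @param cp_count_stable,cp_count_volatile Exact number of change-points
#'   placed in each stretch.
#' @param sigma_gen Outcome noise SD, degrees.
#' @param circle_points Number of positions on the circle.
#' @param bucket_halfwidth Bucket arc half-width, degrees (hit iff circular
#'   distance outcome-to-bucket <= half-width, boundary inclusive).
#' @param points_hit,points_miss Points awarded on a hit / miss.
#' @param confidence_min,confidence_max Bounds of the confidence scale.
#' @param confidence_start_options Possible initial positions of the
#'   confidence slider.
#' @return A `predinf_task_config` list with the fields above.
#' @examples
#' cfg <- task_config()
#' cfg$hazard_volatile
#' @export
task_config <- function(n_trials = 300L,
                        n_blocks = 4L,
                        block_len = 75L,
                        stretch_len = 150L,
                        hazard_stable = 0.025,
                        hazard_volatile = 0.125,
                        cp_count_stable = 4L,
                        cp_count_volatile = 19L,
                        sigma_gen = 12,
                        circle_points = 360L,
                        bucket_halfwidth = 25,
                        points_hit = 10L,
                        points_miss = -10L,
                        confidence_min = 1L,
                        confidence_max = 100L,
                        confidence_start_options = c(25L, 75L)) {
  cfg <- list(
    n_trials = as.integer(n_trials),
    n_blocks = as.integer(n_blocks),
    block_len = as.integer(block_len),
    stretch_len = as.integer(stretch_len),
    hazard_stable = hazard_stable,
    hazard_volatile = hazard_volatile,
    cp_count_stable = as.integer(cp_count_stable),
    cp_count_volatile = as.integer(cp_count_volatile),
    sigma_gen = sigma_gen,
    circle_points = as.integer(circle_points),
    bucket_halfwidth = bucket_halfwidth,
    points_hit = as.integer(points_hit),
    points_miss = as.integer(points_miss),
    confidence_min = as.integer(confidence_min),
    confidence_max = as.integer(confidence_max),
    confidence_start_options = as.integer(confidence_start_options)
  )
  class(cfg) <- "predinf_task_config"
  validate_task_config(cfg)
  cfg
}

validate_task_config <- function(cfg) {
  stopifnot(inherits(cfg, "predinf_task_config"))
  hz <- c(cfg$hazard_stable, cfg$hazard_volatile)
  if (any(hz <= 0 | hz >= 1)) {
    stop("hazard rates must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (cfg$sigma_gen < 0) stop("sigma_gen must be >= 0", call. = FALSE)
  if (cfg$stretch_len * 2L != cfg$n_trials) {
    stop("n_trials must equal 2 * stretch_len", call. = FALSE)
  }
  if (cfg$n_blocks * cfg$block_len != cfg$n_trials) {
    stop("n_blocks * block_len must equal n_trials", call. = FALSE)
  }
  if (cfg$cp_count_stable >= cfg$stretch_len ||
      cfg$cp_count_volatile >= cfg$stretch_len) {
    stop("change-point counts must be smaller than stretch_len", call. = FALSE)
  }
  if (cfg$bucket_halfwidth < 0 || cfg$bucket_halfwidth > 180) {
    stop("bucket_halfwidth must lie in [0, 180]", call. = FALSE)
  }
  invisible(cfg)
}

#' Read or write a task configuration as YAML
#'
#' @param path File path.
#' @return `read_task_config()` returns a `predinf_task_config`;
#'   `write_task_config()` invisibly returns `path`.
#' @export
read_task_config <- function(path) {
  fields <- yaml::read_yaml(path)
  do.call(task_config, fields)
}

#' @rdname read_task_config
#' @param config A `predinf_task_config`.
#' @export
write_task_config <- function(config, path) {
  validate_task_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
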