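zscore_vector <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}

#' Within-group z-scores
#'
#' Standardises `values` to mean 0, SD 1 within each level of `grouping`.
#' Groups with zero variance (e.g. a subject who never moved the confidence
#' slider) are set to 0 with a warning.
#'
#' @param values Numeric vector.
#' @param grouping Vector of group labels, same length.
#' @return Numeric vector of z-scores.
#' @examples
#' zscore_within(c(10, 20, 30, 5, 5, 8), rep(c("a", "b"), each = 3))
#' @export
zscore_within <- function(values, grouping) {
  stopifnot(length(values) == length(grouping))
  out <- numeric(length(values))
  degenerate <- character(0)
  for (g in unique(grouping)) {
    idx <- which(grouping == g)
    s <- stats::sd(values[idx])
    if (!is.finite(s) || s == 0) {
      out[idx] <- 0
      degenerate <- c(degenerate, as.character(g))
    } else {
      out[idx] <- (values[idx] - mean(values[idx])) / s
    }
  }
  if (length(degenerate) > 0) {
    warning("zero variance in group(s) ", paste(degenerate, collapse = ", "),
            "; z-scores set to 0", call. = FALSE)
  }
  out
}

#' Per-subject action updates
#'
#' The action on trial `t` is the absolute circular change in bucket
#' position from trial `t` to `t+1`; the signed update is the corresponding
#' minimal signed arc. The last trial of each subject has no update row.
#' Updates that span a block break are flagged (`block_boundary`) and
#' retained by default.
#'
#' @param trials Tidy trial table with `subject`, `trial`, `block`,
#'   `bucket` (sorted or sortable by trial within subject).
#' @return A tibble: `subject`, `trial`, `signed_update`, `action`,
#'   `block_boundary`, one row per trial 1..T-1 per subject.
#' @export
compute_action_updates <- function(trials) {
  trials |>
    dplyr::arrange(.data$subject, .data$trial) |>
    dplyr::group_by(.data$subject) |>
    dplyr::mutate(
      signed_update = signed_circular_error(dplyr::lead(.data$bucket), .data$bucket),
      block_boundary = dplyr::lead(.data$block) != .data$block
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$signed_update)) |>
    dplyr::mutate(action = abs(.data$signed_update)) |>
    dplyr::select("subject", "trial", "signed_update", "action", "block_boundary")
}

#' Human learning rate
#'
#' `LR^h = signed bucket update / signed prediction error`, both as minimal
#' signed arcs; the prediction error is outcome minus bucket on trial `t`.
#' Where the prediction error is exactly zero the ratio is undefined and
#' returned as `NA` (flagged downstream as `zero_pe`), since such trials are
#' unrelated to error-driven learning.
#'
#' @param signed_update Signed bucket change from `t` to `t+1`, degrees.
#' @param pe Signed prediction error on trial `t`, degrees.
#' @return Numeric vector of learning rates with `NA` at `pe == 0`.
#' @export
compute_human_lr <- function(signed_update, pe) {
  stopifnot(length(signed_update) == length(pe))
  ifelse(pe == 0, NA_real_, signed_update / pe)
}

#' Trial-level exclusion mask
#'
#' Flags trials whose human learning rate exceeds the pooled dataset
#' percentile (default 99th, computed over finite `LR^h` after removing
#' zero-prediction-error trials; one-sided upper cut) and trials with zero
#' prediction error. The threshold is a realisation of the data at hand,
#' not a constant.
#'
#' @param lr_h Human learning rates (NA where the prediction error is 0).
#' @param percentile Upper percentile for the outlier cut, in (0, 1).
#' @param exclude_block_boundary Logical flag vector (or FALSE) marking
#'   updates that span block breaks; excluded only if supplied as TRUE
#'   values.
#' @return A tibble: `excluded` (logical), `exclusion_reason`
#'   (`"lr_outlier"`, `"zero_pe"`, `"block_boundary"` or `NA`),
#'   plus attributes `threshold` and `excluded_fraction`.
#' @export
apply_trial_exclusions <- function(lr_h, percentile = 0.99,
                                   exclude_block_boundary = FALSE) {
  stopifnot(percentile > 0, percentile < 1)
  finite <- is.finite(lr_h)
  if (!any(finite)) stop("no finite learning rates; nothing to keep", call. = FALSE)
  threshold <- stats::quantile(lr_h[finite], percentile, names = FALSE)
  reason <- rep(NA_character_, length(lr_h))
  reason[!finite] <- "zero_pe"
  reason[finite & lr_h > threshold] <- "lr_outlier"
  if (!isFALSE(exclude_block_boundary)) {
    bb <- rep_len(exclude_block_boundary, length(lr_h))
    reason[is.na(reason) & bb] <- "block_boundary"
  }
  excluded <- !is.na(reason)
  if (all(excluded)) stop("all trials excluded", call. = FALSE)
  out <- tibble::tibble(excluded = excluded, exclusion_reason = reason)
  attr(out, "threshold") <- threshold
  attr(out, "excluded_fraction") <- mean(excluded)
  out
}

#' Assemble the trial-level analysis table
#'
#' Merges a cohort's trials, learner traces and subject table into the tidy
#' table the regression suite consumes. Each row is an update step `t ->
#' t+1`: the action, the confidence reported on trial `t+1`, trial-`t`
#' evidence (CPP, RU, |PE^b|, Hit), the human learning rate with its
#' exclusion mask, and within-subject z-scores (confidence for the coupling
#' model; evidence predictors for the confidence evidence model), computed
#' over each subject's included trials.
#'
#' @param cohort A `predinf_cohort` from [simulate_cohort()], or a list with
#'   `trials`, `trace`, `subjects` tibbles of the same shape.
#' @param percentile Learning-rate exclusion percentile (pooled), default
#'   0.99.
#' @param exclude_block_boundary Exclude updates spanning block breaks
#'   (default FALSE: retained but flagged).
#' @return A tibble with one row per subject x update step, carrying
#'   attributes `lr_threshold` and `excluded_fraction`.
#' @export
prepare_analysis_data <- function(cohort, percentile = 0.99,
                                  exclude_block_boundary = FALSE) {
  trials <- dplyr::arrange(cohort$trials, .data$subject, .data$trial)
  updates <- compute_action_updates(trials)

  base <- trials |>
    dplyr::group_by(.data$subject) |>
    dplyr::mutate(conf_next = dplyr::lead(.data$confidence)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      pe = signed_circular_error(.data$outcome, .data$bucket),
      hit = as.integer(.data$hit)
    ) |>
    dplyr::inner_join(updates, by = c("subject", "trial")) |>
    dplyr::left_join(
      dplyr::select(cohort$trace, "subject", "trial", "peb", "abs_peb",
                    "cpp", "ru", "lrb"),
      by = c("subject", "trial")
    ) |>
    dplyr::left_join(
      dplyr::select(cohort$subjects, "subject", "ad", "cit", "sw",
                    "age", "gender", "iq"),
      by = "subject"
    )

  base$lr_h <- compute_human_lr(base$signed_update, base$pe)
  mask <- apply_trial_exclusions(
    base$lr_h, percentile,
    if (exclude_block_boundary) base$block_boundary else FALSE
  )
  base <- dplyr::bind_cols(base, mask)

  keep <- !base$excluded
  for (v in c("conf_next", "cpp", "ru", "abs_peb")) {
    z <- rep(NA_real_, nrow(base))
    z[keep] <- zscore_within(base[[v]][keep], base$subject[keep])
    base[[paste0("z_", v)]] <- z
  }
  base <- dplyr::rename(base, z_conf = "z_conf_next")

  out <- dplyr::select(
    base,
    "subject", "trial", "block", "condition", "hazard", "is_cp",
    "action", "signed_update", "block_boundary",
    "conf_next", "z_conf", "pe", "lr_h",
    "peb", "abs_peb", "cpp", "ru", "lrb", "hit",
    "z_cpp", "z_ru", "z_abs_peb",
    "ad", "cit", "sw", "age", "gender", "iq",
    "excluded", "exclusion_reason"
  )
  attr(out, "lr_threshold") <- attr(mask, "threshold")
  attr(out, "excluded_fraction") <- attr(mask, "excluded_fraction")
  out
}
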