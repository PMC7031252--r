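#' One parameter-recovery replicate
#'
#' Simulates a cohort under the default (literature-sign) effect map, runs
#' the full derivation and regression pipeline, and extracts the four
#' configured moderation effects: CIT attenuates action-confidence coupling
#' (positive `z_conf:cit` interaction on a negative coupling slope), CIT
#' raises and AD lowers overall confidence, and SW increases the influence
#' of |PE^b| on action. A recovery is sign-correct when each estimate
#' carries the sign the generator encodes.
#'
#' @param seed Integer master seed for the replicate.
#' @param n_subjects Cohort size (default 437, the analysis-sample size the
#'   generator mirrors).
#' @param config A [task_config()].
#' @param effects Effect map (default [default_effect_map()]).
#' @return A tibble with one row per target effect: `effect`, `model_id`,
#'   `term`, `estimate`, `se`, `p`, `p_bonf`, `expected_sign`,
#'   `sign_correct`.
#' @export
run_recovery_replicate <- function(seed, n_subjects = 437L,
                                   config = task_config(),
                                   effects = default_effect_map()) {
  dims <- c("ad", "cit", "sw")
  coh <- simulate_cohort(n_subjects, config, effects, seed = seed)
  adat <- prepare_analysis_data(coh)
  fits <- list(
    coupling = fit_coupling_model(adat, dims, m = 3),
    level_confidence = fit_level_model(adat, "confidence", dims, m = 3),
    evidence_action = fit_evidence_model(adat, "action", dims, m = 3)
  )
  targets <- tibble::tribble(
    ~effect,                     ~model_id,           ~term,         ~expected_sign,
    "cit_coupling_attenuation",  "coupling",          "z_conf:cit",   1,
    "cit_confidence_level",      "level_confidence",  "cit",          1,
    "ad_confidence_level",       "level_confidence",  "ad",          -1,
    "sw_peb_on_action",          "evidence_action",   "abs_peb:sw",   1
  )
  rows <- purrr::pmap(targets, function(effect, model_id, term, expected_sign) {
    res <- fits[[model_id]]$result
    row <- res[res$term == term, , drop = FALSE]
    tibble::tibble(
      effect = effect, model_id = model_id, term = term,
      estimate = row$estimate, se = row$se, p = row$p, p_bonf = row$p_bonf,
      expected_sign = expected_sign,
      sign_correct = sign(row$estimate) == expected_sign
    )
  })
  dplyr::bind_rows(rows)
}

#' One zero-effect (null) replicate
#'
#' Simulates a cohort with every dimension effect set to zero and returns
#' the Bonferroni-adjusted p-values of all moderator-related terms across
#' the coupling, confidence-level and action-evidence models. Under the
#' null, the rate of adjusted p-values below alpha is at most alpha.
#'
#' @param seed Integer master seed.
#' @param n_subjects Cohort size.
#' @param config A [task_config()].
#' @return A tibble: `model_id`, `term`, `p`, `p_bonf`.
#' @export
run_null_replicate <- function(seed, n_subjects = 100L,
                               config = task_config()) {
  dims <- c("ad", "cit", "sw")
  coh <- simulate_cohort(n_subjects, config, null_effect_map(), seed = seed)
  adat <- prepare_analysis_data(coh)
  fits <- list(
    fit_coupling_model(adat, dims, m = 3),
    fit_level_model(adat, "confidence", dims, m = 3),
    fit_evidence_model(adat, "action", dims, m = 3)
  )
  out <- dplyr::bind_rows(purrr::map(fits, "result"))
  pat <- paste0("(^|:)(", paste(dims, collapse = "|"), ")($|:)")
  out <- out[grepl(pat, out$term), c("model_id", "term", "p", "p_bonf")]
  tibble::as_tibble(out)
}
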