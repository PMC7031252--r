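standardize_between <- function(data, vars) {
  # z-score subject-level variables using one value per subject, so row
  # counts per subject cannot bias the scaling
  subj <- dplyr::distinct(data, .data$subject, .keep_all = TRUE)
  for (v in vars) {
    m <- mean(subj[[v]])
    s <- stats::sd(subj[[v]])
    data[[v]] <- if (is.finite(s) && s > 0) (data[[v]] - m) / s else 0
  }
  data
}

fit_mixed <- function(formula, data) {
  fit <- lme4::lmer(
    formula, data = data, REML = TRUE,
    control = lme4::lmerControl(optimizer = "bobyqa", calc.derivs = FALSE)
  )
  msgs <- fit@optinfo$conv$lme4$messages
  # a boundary (singular) fit is a valid optimum, not an optimizer failure
  real_msgs <- msgs[!grepl("boundary \\(singular\\)", msgs)]
  attr(fit, "predinf_converged") <- fit@optinfo$conv$opt == 0 &&
    length(real_msgs) == 0
  attr(fit, "predinf_singular") <- lme4::isSingular(fit)
  attr(fit, "predinf_messages") <- msgs
  fit
}

new_predinf_fit <- function(model, data, moderators, m, model_id) {
  est <- lme4::fixef(model)
  se <- sqrt(diag(as.matrix(stats::vcov(model))))
  rob <- robust_se(model)
  p <- 2 * stats::pnorm(-abs(est / se))
  res <- tibble::tibble(
    term = names(est),
    estimate = unname(est),
    se = unname(se),
    robust_se = unname(rob$se[names(est)]),
    ci_lo = unname(est - 1.96 * se),
    ci_hi = unname(est + 1.96 * se),
    p = unname(p),
    p_bonf = bonferroni(unname(p), m),
    model_id = model_id
  )
  vc <- as.data.frame(lme4::VarCorr(model))
  structure(
    list(
      model = model,
      result = res,
      ranef = tibble::as_tibble(vc),
      moderators = moderators,
      m_correction = m,
      n_obs = nrow(data),
      n_subjects = length(unique(data$subject)),
      converged = isTRUE(attr(model, "predinf_converged")),
      singular = isTRUE(attr(model, "predinf_singular")),
      messages = attr(model, "predinf_messages"),
      ci_basis = "Wald, normal approximation, classical SE"
    ),
    class = "predinf_fit"
  )
}

prep_fit_data <- function(data, moderators, needed) {
  stopifnot(all(moderators %in% names(data)))
  data <- data[!data$excluded, , drop = FALSE]
  data <- data[stats::complete.cases(data[, needed, drop = FALSE]), , drop = FALSE]
  standardize_between(data, unique(c("age", "iq", moderators)))
}

build_formula <- function(dv, within, moderators, random) {
  covs <- c("age", "gender", "iq")
  inter <- if (length(within) == 0 || length(moderators) == 0) {
    character(0)
  } else {
    unlist(lapply(moderators, function(m) paste(m, within, sep = ":")))
  }
  rhs <- c(within, covs, moderators, inter, random)
  stats::as.formula(paste(dv, "~", paste(rhs, collapse = " + ")))
}

#' Fit the action-confidence coupling model
#'
#' Mixed-effects regression of the trial-wise action update on the
#' within-subject z-scored confidence of the next report, with standardized
#' age/IQ and binary gender as covariates and a random intercept and random
#' confidence slope per subject. Between-subject moderators (questionnaire
#' scores or the three dimensions) enter as standardized main effects plus
#' moderator x confidence interactions; a positive interaction on the
#' negative confidence main effect means attenuated coupling.
#'
#' @param data Analysis table from [prepare_analysis_data()] (excluded
#'   trials are dropped internally).
#' @param moderators Character vector of between-subject score columns;
#'   `NULL` for the basic model. Mirror the two reported regimes by passing
#'   one questionnaire at a time or all three dimensions jointly.
#' @param m Bonferroni multiplier over psychiatric independent variables
#'   (e.g. 9 questionnaires or 3 dimensions). Defaults to
#'   `max(1, length(moderators))`.
#' @param model_id Label stored in the result table.
#' @return A `predinf_fit`; see [tidy.predinf_fit()]. Non-convergence is
#'   reported via the `converged` flag, not an error.
#' @export
fit_coupling_model <- function(data, moderators = NULL,
                               m = max(1L, length(moderators)),
                               model_id = "coupling") {
  needed <- c("action", "z_conf", "age", "gender", "iq", moderators)
  data <- prep_fit_data(data, moderators, needed)
  f <- build_formula("action", "z_conf", moderators, "(1 + z_conf | subject)")
  new_predinf_fit(fit_mixed(f, data), data, moderators, m, model_id)
}

#' Fit a level model (overall confidence or action)
#'
#' Mixed-effects regression of raw confidence (1--100) or the action update
#' on the standardized moderators and covariates, with a random intercept
#' per subject only.
#'
#' @inheritParams fit_coupling_model
#' @param dv `"confidence"` or `"action"`.
#' @return A `predinf_fit`.
#' @export
fit_level_model <- function(data, dv = c("confidence", "action"),
                            moderators = NULL,
                            m = max(1L, length(moderators)),
                            model_id = paste0("level_", dv[1])) {
  dv <- match.arg(dv)
  dv_var <- if (dv == "confidence") "conf_next" else "action"
  needed <- c(dv_var, "age", "gender", "iq", moderators)
  data <- prep_fit_data(data, moderators, needed)
  f <- build_formula(dv_var, character(0), moderators, "(1 | subject)")
  new_predinf_fit(fit_mixed(f, data), data, moderators, m, model_id)
}

#' Fit an evidence-influence model
#'
#' Tests how the learner's trial-`t` evidence drives the next action or
#' confidence report, with a random intercept per subject:
#'
#' * `dv = "action"`: `action ~ |PE^b| + |PE^b|:CPP + |PE^b|:RU +
#'   |PE^b|:Hit` -- every evidence term except `|PE^b|` enters through its
#'   interaction with `|PE^b|`, on the raw scale. Under the normative
#'   learner the update is `(CPP + RU) * |PE^b|`, so the two interaction
#'   coefficients recover 1 for an unbiased agent.
#' * `dv = "confidence"`: `confidence ~ z(|PE^b|) + z(CPP) + z(RU) + Hit`,
#'   predictors z-scored within subject, no `|PE^b|` interactions,
#'   confidence on its raw 1--100 scale.
#'
#' Moderators interact with every evidence term (attenuation shows up as an
#' interaction opposing the main effect's sign).
#'
#' @inheritParams fit_level_model
#' @return A `predinf_fit`.
#' @export
fit_evidence_model <- function(data, dv = c("confidence", "action"),
                               moderators = NULL,
                               m = max(1L, length(moderators)),
                               model_id = paste0("evidence_", dv[1])) {
  dv <- match.arg(dv)
  if (dv == "action") {
    dv_var <- "action"
    within <- c("abs_peb", "abs_peb:cpp", "abs_peb:ru", "abs_peb:hit")
    base_vars <- c("abs_peb", "cpp", "ru", "hit")
  } else {
    dv_var <- "conf_next"
    within <- c("z_abs_peb", "z_cpp", "z_ru", "hit")
    base_vars <- within
  }
  needed <- c(dv_var, base_vars, "age", "gender", "iq", moderators)
  data <- prep_fit_data(data, moderators, needed)
  degenerate <- base_vars[vapply(base_vars, function(v) stats::sd(data[[v]]) == 0,
                                 logical(1))]
  if (length(degenerate) > 0) {
    stop("constant evidence predictor(s): ", paste(degenerate, collapse = ", "),
         "; model is rank deficient", call. = FALSE)
  }
  f <- build_formula(dv_var, within, moderators, "(1 | subject)")
  new_predinf_fit(fit_mixed(f, data), data, moderators, m, model_id)
}

#' Subject-clustered heteroskedasticity-consistent standard errors
#'
#' Sandwich (robust) covariance of the fixed effects, clustered at the
#' subject level, reported alongside the classical model-based SEs. For a
#' fitted linear mixed model the bread is the GLS information
#' `sum_j X_j' V_j^{-1} X_j` and the meat stacks per-subject score
#' contributions built from marginal residuals, with `V_j` assembled from
#' the estimated random-effect covariance and residual variance (inverted
#' via the Woodbury identity); a `J/(J-1)` small-sample factor is applied.
#' For an `lm` fit the same estimator reduces to the standard CR0/CR1
#' cluster sandwich.
#'
#' @param fit A `lmerMod` or `lm` object (or a `predinf_fit`, whose model is
#'   used).
#' @param cluster Cluster labels for `lm` fits; inferred from the (single)
#'   grouping factor for mixed fits.
#' @return A list: `se` (named vector), `vcov`, `n_clusters`.
#' @export
robust_se <- function(fit, cluster = NULL) {
  if (inherits(fit, "predinf_fit")) fit <- fit$model
  if (inherits(fit, "lmerMod")) {
    return(robust_se_mermod(fit))
  }
  if (inherits(fit, "lm")) {
    return(robust_se_lm(fit, cluster))
  }
  stop("robust_se supports lmerMod and lm fits", call. = FALSE)
}

robust_se_mermod <- function(fit) {
  flist <- lme4::getME(fit, "flist")
  if (length(flist) != 1) {
    stop("robust_se expects a single grouping factor", call. = FALSE)
  }
  cl <- flist[[1]]
  j_levels <- levels(droplevels(cl))
  n_cl <- length(j_levels)
  if (n_cl < 2) {
    stop("need at least two clusters for subject-clustered SEs", call. = FALSE)
  }
  x <- lme4::getME(fit, "X")
  y <- lme4::getME(fit, "y")
  beta <- lme4::fixef(fit)
  r <- y - as.vector(x %*% beta)
  zmat <- lme4::getME(fit, "mmList")[[1]]
  g <- as.matrix(lme4::VarCorr(fit)[[1]])
  s2 <- stats::sigma(fit)^2
  # guard a boundary (singular) random-effect covariance
  ridge <- 1e-10 * max(diag(g), s2)
  ginv <- solve(g + diag(ridge, nrow(g)))

  k <- ncol(x)
  bread <- matrix(0, k, k)
  meat <- matrix(0, k, k)
  idx_by_cl <- split(seq_along(cl), cl, drop = TRUE)
  for (idx in idx_by_cl) {
    xj <- x[idx, , drop = FALSE]
    zj <- zmat[idx, , drop = FALSE]
    rj <- r[idx]
    m <- s2 * ginv + crossprod(zj)
    xtz <- crossprod(xj, zj)
    # X_j' V_j^{-1} via Woodbury: (X' - X'Z M^{-1} Z') / s2
    xtvinv <- (t(xj) - xtz %*% solve(m, t(zj))) / s2
    bread <- bread + xtvinv %*% xj
    u <- xtvinv %*% rj
    meat <- meat + tcrossprod(u)
  }
  bread_inv <- solve(bread)
  vc <- bread_inv %*% meat %*% bread_inv * n_cl / (n_cl - 1)
  se <- sqrt(diag(vc))
  names(se) <- colnames(x)
  dimnames(vc) <- list(colnames(x), colnames(x))
  list(se = se, vcov = vc, n_clusters = n_cl)
}

robust_se_lm <- function(fit, cluster) {
  x <- stats::model.matrix(fit)
  r <- stats::residuals(fit)
  if (is.null(cluster)) cluster <- seq_along(r)
  if (length(cluster) != length(r)) {
    stop("cluster must match the number of observations", call. = FALSE)
  }
  n_cl <- length(unique(cluster))
  if (n_cl < 2) {
    stop("need at least two clusters for clustered SEs", call. = FALSE)
  }
  k <- ncol(x)
  meat <- matrix(0, k, k)
  for (idx in split(seq_along(r), cluster)) {
    u <- crossprod(x[idx, , drop = FALSE], r[idx])
    meat <- meat + tcrossprod(u)
  }
  bread_inv <- solve(crossprod(x))
  vc <- bread_inv %*% meat %*% bread_inv * n_cl / (n_cl - 1)
  se <- sqrt(diag(vc))
  names(se) <- colnames(x)
  dimnames(vc) <- list(colnames(x), colnames(x))
  list(se = se, vcov = vc, n_clusters = n_cl)
}

#' White's test for heteroskedasticity
#'
#' Auxiliary regression of the squared residuals on the model's predictors,
#' their squares and pairwise cross-products; the Lagrange-multiplier
#' statistic `n * R^2` is referred to a chi-square with degrees of freedom
#' equal to the number of (linearly independent) auxiliary regressors.
#'
#' @param fit A fitted `lm` or `lmerMod` (or `predinf_fit`); residuals and
#'   the fixed-effects design are taken from it.
#' @return A tibble: `statistic`, `df`, `p_value`.
#' @export
white_test <- function(fit) {
  if (inherits(fit, "predinf_fit")) fit <- fit$model
  if (inherits(fit, "lmerMod")) {
    r <- stats::residuals(fit)
    x <- lme4::getME(fit, "X")
  } else {
    r <- stats::residuals(fit)
    x <- stats::model.matrix(fit)
  }
  x <- x[, colnames(x) != "(Intercept)", drop = FALSE]
  e2 <- r^2
  # degenerate cases: no predictors, constant residuals, or an (up to
  # floating-point noise) exact fit
  exact_fit <- stats::var(r) <= 1e-20 * max(stats::var(r + stats::fitted(fit)), 1e-300)
  if (ncol(x) == 0 || stats::var(e2) == 0 || exact_fit) {
    return(tibble::tibble(statistic = 0, df = NA_integer_, p_value = 1))
  }
  aux <- cbind(x, x^2)
  if (ncol(x) > 1) {
    pairs <- utils::combn(ncol(x), 2)
    cross <- apply(pairs, 2, function(ij) x[, ij[1]] * x[, ij[2]])
    aux <- cbind(aux, cross)
  }
  aux_fit <- stats::lm(e2 ~ aux)
  df <- aux_fit$rank - 1L
  r2 <- summary(aux_fit)$r.squared
  stat <- length(e2) * r2
  tibble::tibble(
    statistic = stat,
    df = df,
    p_value = stats::pchisq(stat, df, lower.tail = FALSE)
  )
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)`, with `m` the number of psychiatric independent
#' variables tested (e.g. 9 questionnaires or 3 dimensions).
#'
#' @param p Raw p-values.
#' @param m Number of comparisons, `>= 1`.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, m) {
  stopifnot(m >= 1)
  pmin(1, m * p)
}

#' Moderation effect as percent change of a main effect
#'
#' `100 * beta_interaction / |beta_main|`: the percentage change in the size
#' of a within-subject effect per +1 SD of the moderator. With a negative
#' main effect (e.g. the coupling slope), a positive interaction is
#' attenuation.
#'
#' @param beta_interaction Moderator x term interaction estimate.
#' @param beta_main Main-effect estimate (must be nonzero).
#' @return Percent change (positive = same direction as `beta_interaction`).
#' @examples
#' percent_change_effect(1.30, -8.85)  # ~ +14.7% (14.7% weaker coupling)
#' @export
percent_change_effect <- function(beta_interaction, beta_main) {
  if (any(beta_main == 0)) {
    warning("main effect is zero; percent change undefined", call. = FALSE)
    return(ifelse(beta_main == 0, NA_real_,
                  100 * beta_interaction / abs(beta_main)))
  }
  100 * beta_interaction / abs(beta_main)
}

#' Tidy and summarise fitted models
#'
#' `tidy()` returns one row per fixed effect with classical and
#' subject-clustered robust SEs, Wald 95% CIs, raw and Bonferroni-adjusted
#' p-values; `glance()` returns a one-row model summary.
#'
#' @param x A `predinf_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy predinf_fit
#' @export
tidy.predinf_fit <- function(x, ...) {
  x$result
}

#' @rdname tidy.predinf_fit
#' @method glance predinf_fit
#' @export
glance.predinf_fit <- function(x, ...) {
  tibble::tibble(
    model_id = x$result$model_id[1],
    n_obs = x$n_obs,
    n_subjects = x$n_subjects,
    sigma = stats::sigma(x$model),
    reml_crit = as.numeric(lme4::REMLcrit(x$model)),
    converged = x$converged,
    singular = x$singular,
    m_correction = x$m_correction
  )
}

#' @export
print.predinf_fit <- function(x, ...) {
  cat("<predinf_fit> ", x$result$model_id[1],
      " | n_obs = ", x$n_obs, ", subjects = ", x$n_subjects,
      if (!x$converged) " | NOT CONVERGED" else "", "\n", sep = "")
  print(x$result)
  invisible(x)
}

#' Write fit results to a tidy CSV
#'
#' @param fits A `predinf_fit` or list of them.
#' @param path Output file.
#' @export
write_results_csv <- function(fits, path) {
  if (inherits(fits, "predinf_fit")) fits <- list(fits)
  tab <- dplyr::bind_rows(purrr::map(fits, generics::tidy))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
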