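#' Plot a session: outcomes, generative mean and learner belief
#'
#' @param trials Session tibble from [simulate_task()] (optionally with
#'   `bucket` from an agent).
#' @param trace Learner trace from [run_learner()] (optional; adds the
#'   belief trajectory).
#' @return A ggplot object.
#' @export
plot_session <- function(trials, trace = NULL) {
  p <- ggplot2::ggplot(trials, ggplot2::aes(x = .data$trial)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$outcome), size = 0.6,
                        alpha = 0.6, colour = "grey40") +
    ggplot2::geom_step(ggplot2::aes(y = .data$mean), colour = "black") +
    ggplot2::geom_vline(
      xintercept = trials$trial[trials$is_cp],
      linetype = "dotted", colour = "red3", alpha = 0.6
    ) +
    ggplot2::labs(x = "trial", y = "circle position (degrees)") +
    ggplot2::theme_minimal()
  if (!is.null(trace)) {
    p <- p + ggplot2::geom_line(
      data = trace, ggplot2::aes(y = .data$belief), colour = "steelblue"
    )
  }
  p
}

#' Plot the learner's latent variables over trials
#'
#' Change-point probability, relative uncertainty and the resulting dynamic
#' learning rate, faceted over trials.
#'
#' @param trace Learner trace from [run_learner()].
#' @return A ggplot object.
#' @export
plot_learner_trace <- function(trace) {
  long <- tidyr::pivot_longer(
    trace[, c("trial", "cpp", "ru", "lrb")],
    cols = c("cpp", "ru", "lrb"),
    names_to = "variable", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$trial, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~variable, ncol = 1,
                        labeller = ggplot2::as_labeller(c(
                          cpp = "change-point probability",
                          ru = "relative uncertainty",
                          lrb = "learning rate"
                        ))) +
    ggplot2::labs(x = "trial", y = NULL) +
    ggplot2::theme_minimal()
}

#' Coefficient (forest) plot for a fitted model
#'
#' Fixed effects with Wald 95% intervals; set `robust = TRUE` to draw
#' intervals from the subject-clustered robust SEs instead.
#'
#' @param object A `predinf_fit`.
#' @param robust Use robust SEs for the intervals.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot predinf_fit
#' @export
autoplot.predinf_fit <- function(object, robust = FALSE, ...) {
  tab <- object$result
  if (robust) {
    tab$ci_lo <- tab$estimate - 1.96 * tab$robust_se
    tab$ci_hi <- tab$estimate + 1.96 * tab$robust_se
  }
  tab <- tab[tab$term != "(Intercept)", , drop = FALSE]
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$estimate,
                                    y = stats::reorder(.data$term, .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_lo, xmax = .data$ci_hi), height = 0.2
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "estimate (95% CI)", y = NULL,
      title = tab$model_id[1],
      subtitle = if (robust) "subject-clustered robust SEs" else "classical SEs"
    ) +
    ggplot2::theme_minimal()
}
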