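#' Plot an individual risk curve
#'
#' Median predicted probability of graft failure with its 95% band; the
#' landmark is marked with a vertical line.
#'
#' @param object A `risk_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.risk_curve <- function(object, ...) {
  lm <- attr(object, "landmark")
  gg <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time))
  if (!all(is.na(object$lower95))) {
    gg <- gg + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower95, ymax = .data$upper95),
      fill = "grey80", alpha = 0.7)
  }
  gg +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = lm, linetype = 3) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Years since transplantation",
                  y = "Predicted probability of graft failure") +
    ggplot2::theme_minimal()
}

#' Plot fitted class trajectories and survival
#'
#' Class-specific mean creatinine trajectories (latent means retranslated to
#' the creatinine scale through the fitted link) over the measurement window.
#'
#' @param object A `graft_jlcm`.
#' @param t_max Right end of the time axis in years (default 1.5 = 18
#'   months, the scheduled measurement window).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.graft_jlcm <- function(object, t_max = 1.5, ...) {
  p <- object$params
  grid <- seq(0.02, t_max, length.out = 60)
  df <- dplyr::bind_rows(lapply(seq_len(p$G), function(g) {
    tibble::tibble(
      class = factor(g),
      time = grid,
      scr = suppressWarnings(link_inverse(class_mean_trajectory(p$beta[g, ], grid), p$link))
    )
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$scr, colour = .data$class)) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::labs(x = "Years since transplantation",
                  y = expression("Serum creatinine (" * mu * "mol/L)"),
                  colour = "Latent class") +
    ggplot2::theme_minimal()
}

#' Plot class-specific predicted and observed event-free survival
#'
#' Model-implied baseline survival per class overlaid with the Kaplan-Meier
#' curves of the modally classified subjects.
#'
#' @param fit A `graft_jlcm` with its training cohort attached.
#' @param horizon Years (default 10).
#' @return A ggplot.
#' @export
plot_class_survival <- function(fit, horizon = 10) {
  p <- fit$params
  grid <- seq(0, horizon, length.out = 101)
  pred <- dplyr::bind_rows(lapply(seq_len(p$G), function(g) {
    tibble::tibble(class = factor(g), time = grid,
                   surv = exp(-weibull_cumhaz(grid, p$zeta[g, ])),
                   kind = "model (baseline)")
  }))
  s <- fit$cohort$subjects
  km <- dplyr::bind_rows(lapply(seq_len(p$G), function(g) {
    idx <- fit$modal_class == g
    if (!any(idx)) return(NULL)
    k <- kaplan_meier(s$event_time[idx], s$event[idx])
    tibble::tibble(class = factor(g),
                   time = c(0, rep(k$time, each = 2), horizon),
                   surv = c(1, 1, rep(k$surv, each = 2)),
                   kind = "Kaplan-Meier (modal classes)")
  }))
  ggplot2::ggplot(dplyr::bind_rows(pred, km),
                  ggplot2::aes(x = .data$time, y = .data$surv,
                               colour = .data$class, linetype = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Years since transplantation", y = "Graft failure-free probability",
                  colour = "Latent class", linetype = NULL) +
    ggplot2::theme_minimal()
}
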