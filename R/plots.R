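# ggplot2 views of the result objects.

#' @export
autoplot.km_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Fraction surviving") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier plot of risk groups
#'
#' @param outcomes Outcomes tibble (`id`, `time`, `event`).
#' @param group Group label per row of `outcomes`.
#' @return A ggplot.
#' @export
plot_km_groups <- function(outcomes, group) {
  check_outcomes(outcomes)
  dat <- bind_rows(map(split(seq_len(nrow(outcomes)), group), function(idx) {
    cv <- km_curve(outcomes$time[idx], outcomes$event[idx])
    cv$group <- group[idx[1]]
    as_tibble(cv)
  }))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$surv,
                                    colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Fraction surviving", colour = "Risk group") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mm_report <- function(object, ...) {
  cmp <- object$comparison
  cmp$combo <- factor(cmp$combo, levels = cmp$combo[order(cmp$test_c)])
  ggplot2::ggplot(cmp, ggplot2::aes(x = .data$combo, y = .data$test_c)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$test_ci_lo,
                                        ymax = .data$test_ci_hi), width = 0.25) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(0.4, max(0.7, max(cmp$test_ci_hi, na.rm = TRUE)))) +
    ggplot2::labs(x = "Model", y = "Test c-index") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mm_signature <- function(object, ...) {
  uni <- attr(object, "univariate")
  if (is.null(uni)) abort("signature carries no univariate scan to plot")
  uni$selected <- uni$feature %in% object$feature
  ggplot2::ggplot(uni, ggplot2::aes(x = .data$log_hr, y = -log10(.data$p),
                                    colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "Univariate log(HR)", y = "-log10 p", colour = "Selected") +
    ggplot2::theme_minimal()
}
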