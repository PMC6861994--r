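#' Tidy a Wilcoxon signed-rank result
#'
#' @param x An `enbal_wsr` object.
#' @param ... Unused.
#' @return One-row tibble: `statistic`, `p.value`, `n`, `n.zero`, `method`.
#' @export
tidy.enbal_wsr <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, p.value = x$p_value,
    n = x$n, n.zero = x$n_zero, method = x$method
  )
}

#' @rdname tidy.enbal_wsr
#' @export
glance.enbal_wsr <- function(x, ...) tidy.enbal_wsr(x)

#' Tidy a simulated cohort
#'
#' Returns the weekly measured-weight trajectories in long form.
#'
#' @param x An `enbal_sim` object.
#' @param ... Unused.
#' @return Tibble: `participant_id`, `week`, `weight`.
#' @export
tidy.enbal_sim <- function(x, ...) x$weekly

#' One-row summary of a simulated cohort
#'
#' @param x An `enbal_sim` object.
#' @param ... Unused.
#' @return Tibble: `n`, `weeks`, `adherence_mean`, `mean_pct_loss`,
#'   `recovered_adherence`.
#' @export
glance.enbal_sim <- function(x, ...) {
  tibble::tibble(
    n = x$settings$n, weeks = x$settings$weeks,
    adherence_mean = x$settings$adherence_mean,
    mean_pct_loss = mean(pct_weight_loss(x)),
    recovered_adherence = recover_adherence(x)
  )
}

#' Plot simulated weight trajectories
#'
#' Spaghetti plot of weekly measured weights with the cohort median
#' overlaid.
#'
#' @param object An `enbal_sim` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.enbal_sim <- function(object, ...) {
  med <- object$weekly |>
    dplyr::group_by(.data$week) |>
    dplyr::summarise(weight = stats::median(.data$weight), .groups = "drop")
  ggplot2::ggplot(object$weekly,
                  ggplot2::aes(.data$week, .data$weight,
                               group = .data$participant_id)) +
    ggplot2::geom_line(alpha = 0.25) +
    ggplot2::geom_line(data = med, ggplot2::aes(group = NULL),
                       linewidth = 1.2, colour = "firebrick") +
    ggplot2::labs(x = "Week", y = "Weight (kg)",
                  title = "Simulated 12-week weight trajectories",
                  subtitle = "Cohort median in red") +
    ggplot2::theme_minimal()
}

#' Plot a pre/post outcome summary
#'
#' Dot-and-segment plot of baseline and final medians per outcome, faceted
#' so differently scaled outcomes stay readable.
#'
#' @param object An `enbal_outcomes` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.enbal_outcomes <- function(object, ...) {
  long <- object |>
    dplyr::select("outcome", "baseline_median", "final_median") |>
    tidyr::pivot_longer(-"outcome", names_to = "stage", values_to = "median") |>
    dplyr::mutate(stage = sub("_median", "", .data$stage))
  ggplot2::ggplot(long, ggplot2::aes(.data$stage, .data$median, group = 1)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~outcome, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Median",
                  title = "Outcome medians, baseline vs final") +
    ggplot2::theme_minimal()
}

#' Plot a goal schedule
#'
#' @param object An `enbal_schedule` from [build_goal_schedule()].
#' @param ... Unused.
#' @return A ggplot of per-period kg targets.
#' @export
autoplot.enbal_schedule <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(factor(.data$period), .data$kg_target)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Period", y = "Weight-loss target (kg)",
                  title = sprintf("Goal schedule (baseline %.1f kg)",
                                  attr(object, "baseline_weight"))) +
    ggplot2::theme_minimal()
}
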