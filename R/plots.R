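#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   geom_col geom_tile scale_x_log10 scale_y_log10 labs facet_wrap
#'   position_dodge
NULL

#' @export
ggplot2::autoplot

#' Plot a trajectory
#'
#' All 12 state variables against time, one facet per variable, on a log
#' time axis.
#'
#' @param object an `"eb_trajectory"`.
#' @param vars variables to show (default all 12).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot eb_trajectory
#' @export
autoplot.eb_trajectory <- function(object, vars = .state_names, ...) {
  long <- tidyr::pivot_longer(object[, c("time", vars)],
                              -"time", names_to = "variable",
                              values_to = "value")
  long$variable <- factor(long$variable, levels = .state_names)
  ggplot(long[long$time > 0, ], aes(x = .data$time, y = .data$value)) +
    geom_line() +
    facet_wrap(~variable, scales = "free_y") +
    scale_x_log10() +
    labs(x = "time (min)", y = "count (m.p.c.)")
}

#' Plot response coefficients
#'
#' Ranked absolute elasticities of the stationary ATP level, split by
#' response sign.
#'
#' @param object an `"eb_response"` from [response_coefficients()].
#' @param top show only the `top` largest magnitudes.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot eb_response
#' @export
autoplot.eb_response <- function(object, top = 20, ...) {
  d <- dplyr::filter(object, .data$elasticity != 0)
  d <- dplyr::slice_max(d, abs(.data$elasticity), n = top)
  d$parameter <- stats::reorder(d$parameter, abs(d$elasticity))
  d$response <- ifelse(d$elasticity > 0, "positive", "negative")
  ggplot(d, aes(x = abs(.data$elasticity), y = .data$parameter)) +
    geom_col() +
    facet_wrap(~response, scales = "free_y") +
    labs(x = "|elasticity| of stationary ATP", y = NULL)
}

#' Plot a one-parameter steady-state scan
#'
#' @param object an `"eb_scan"` from [scan_parameter()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot eb_scan
#' @export
autoplot.eb_scan <- function(object, ...) {
  ggplot(object, aes(x = .data$fold, y = .data$a_percent)) +
    geom_line() +
    geom_point(size = 0.8) +
    scale_x_log10() +
    labs(x = paste0("fold-change of ", attr(object, "parameter")),
         y = "stationary ATP (% of reference)")
}

#' Plot a two-parameter steady-state scan
#'
#' @param object an `"eb_scan2d"` from [scan_parameter_pair()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot eb_scan2d
#' @export
autoplot.eb_scan2d <- function(object, ...) {
  nms <- attr(object, "parameters")
  ggplot(object, aes(x = .data$fold1, y = .data$fold2,
                     fill = .data$a_percent)) +
    geom_tile() +
    scale_x_log10() +
    scale_y_log10() +
    labs(x = paste0("fold-change of ", nms[1]),
         y = paste0("fold-change of ", nms[2]),
         fill = "ATP (%)")
}

#' Plot a copy-number sweep
#'
#' ATP-drop duration and trajectory minimum against the initial fold-change.
#'
#' @param object an `"eb_sweep"` from [copy_number_sweep()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot eb_sweep
#' @export
autoplot.eb_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::tibble(fold = object$fold, T_drop_min = object$T_drop,
                   a_min = object$a_min),
    -"fold", names_to = "metric", values_to = "value")
  ggplot(long, aes(x = .data$fold, y = .data$value)) +
    geom_line() +
    facet_wrap(~metric, scales = "free_y") +
    scale_x_log10() +
    labs(x = paste0("initial ", attr(object, "which_rte"), " fold-change"),
         y = NULL)
}

#' Plot an ATP budget comparison
#'
#' Reference and perturbed per-process ATP consumption side by side on a log
#' scale.
#'
#' @param object an `"eb_budget_comparison"` from [budget_comparison()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot eb_budget_comparison
#' @export
autoplot.eb_budget_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(object[, c("category", "reference",
                                         "perturbed")],
                              -"category", names_to = "condition",
                              values_to = "rate")
  long$category <- factor(long$category, levels = rev(.budget_categories))
  ggplot(long, aes(x = .data$rate, y = .data$category,
                   fill = .data$condition)) +
    geom_col(position = position_dodge()) +
    scale_x_log10() +
    labs(x = "ATP consumption (m.p.c./min)", y = NULL, fill = NULL)
}
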