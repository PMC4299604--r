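#' Plot methods
#'
#' `autoplot()` methods for the package's result types: the log-log response
#' curve of a fitted power-law gate (data, fit line and the unrepressed
#' ceiling), a Hill inducer fit, a truth table as a digital bar panel, a
#' dynamics trace, and a crosstalk fold matrix as a heat map.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @name autoplot-methods
NULL

#' @rdname autoplot-methods
#' @exportS3Method ggplot2::autoplot
autoplot.powerlaw_fit <- function(object, ...) {
  d <- object$data
  xs <- exp(seq(log(min(d$input)), log(max(d$input)), length.out = 200))
  curve <- tibble::tibble(input = xs, output = gate_output(object$gate, xs))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$input, y = .data$output)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = object$gate$y_max, linetype = "dashed") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "input promoter activity (au)",
                  y = "output promoter activity (au)",
                  title = sprintf("power-law gate: b = %.2f, R2 = %.3f",
                                  object$coefficients$estimate[2], object$r.squared))
}

#' @rdname autoplot-methods
#' @exportS3Method ggplot2::autoplot
autoplot.gate_response <- function(object, ...) {
  xs <- exp(seq(log(object$x_floor * 0.1 + 1e-9), log(object$x_floor * 1e3 + 1),
                length.out = 200))
  curve <- tibble::tibble(input = xs, output = gate_output(object, xs))
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$input, y = .data$output)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$y_max, linetype = "dashed") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "input promoter activity (au)", y = "output activity (au)")
}

#' @rdname autoplot-methods
#' @exportS3Method ggplot2::autoplot
autoplot.hill_fit <- function(object, ...) {
  d <- object$data
  pos <- d$concentration[d$concentration > 0]
  xs <- c(0, exp(seq(log(min(pos)), log(max(pos)), length.out = 200)))
  curve <- tibble::tibble(concentration = xs,
                          output = inducer_to_activity(object$model, xs))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$concentration, y = .data$output)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::labs(x = "inducer concentration", y = "promoter activity (au)")
}

#' @rdname autoplot-methods
#' @exportS3Method ggplot2::autoplot
autoplot.truth_table <- function(object, ...) {
  ins <- setdiff(names(object), c("activity", "expected", "call"))
  d <- dplyr::mutate(
    tibble::as_tibble(object),
    state = apply(object[, ins, drop = FALSE], 1, paste, collapse = "")
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$state, y = .data$activity,
                                  fill = .data$expected)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "black", `FALSE` = "grey70"),
                               name = "expected ON") +
    ggplot2::labs(x = "input state", y = "output activity (au)",
                  title = sprintf("%s gate, digital margin %.1f",
                                  attr(object, "logic"), attr(object, "margin")))
}

#' @rdname autoplot-methods
#' @exportS3Method ggplot2::autoplot
autoplot.dynamics_trace <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time, y = .data$level)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::geom_vline(xintercept = attr(object, "delay_tau"), linetype = "dotted") +
    ggplot2::labs(x = "time (min)", y = "reporter level (au)")
}

#' @rdname autoplot-methods
#' @exportS3Method ggplot2::autoplot
autoplot.crosstalk_matrix <- function(object, ...) {
  d <- tibble::as_tibble(as.table(object$folds), .name_repair = "minimal")
  names(d) <- c("guide", "promoter", "fold")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$promoter, y = .data$guide,
                                  fill = log10(.data$fold))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log10 fold") +
    ggplot2::labs(x = "promoter", y = "sgRNA")
}
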