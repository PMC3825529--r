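#' Diagnostic plots
#'
#' ggplot2 views of the tabular results: contact force and penetration over
#' a simulated manipulation, and per-fragment reduction errors.
#'
#' @name plots
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulation log
#'
#' Contact force magnitude and maximum penetration against trajectory time.
#'
#' @param object A `simulation_log`.
#' @param ... Unused.
#' @export
autoplot.simulation_log <- function(object, ...) {
  df <- tibble::tibble(
    time = rep(object$time, 2),
    value = c(object$force_mag, object$max_penetration),
    quantity = rep(c("contact force [N]", "max penetration [mm]"),
                   each = nrow(object)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$quantity), ncol = 1,
                        scales = "free_y") +
    ggplot2::labs(x = "trajectory time [s]", y = NULL,
                  title = "Quasi-static manipulation") +
    ggplot2::theme_minimal()
}

#' Plot a reduction report
#'
#' Per-fragment translation and rotation error after reassembly.
#'
#' @param object A `reduction_report`.
#' @param ... Unused.
#' @export
autoplot.reduction_report <- function(object, ...) {
  df <- tibble::tibble(
    label = factor(rep(object$label, 2)),
    value = c(object$trans_err_mm, object$rot_err_deg),
    quantity = rep(c("translation error [mm]", "rotation error [deg]"),
                   each = nrow(object)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$quantity), scales = "free_y") +
    ggplot2::labs(x = "fragment", y = NULL,
                  title = "Reduction error vs ground truth") +
    ggplot2::theme_minimal()
}

#' Scatter view of a point shell
#'
#' Projects the shell onto a coordinate plane, coloured by the out-of-plane
#' normal component; a quick sanity view of surface extraction and painting.
#'
#' @param shell A `point_shell`.
#' @param plane `"xy"`, `"xz"` or `"yz"`.
#' @param marked Optional `marked_surface` to highlight.
#' @export
plot_shell <- function(shell, plane = c("xy", "xz", "yz"), marked = NULL) {
  plane <- match.arg(plane)
  ax <- switch(plane, xy = c("x", "y", "nz"), xz = c("x", "z", "ny"),
               yz = c("y", "z", "nx"))
  df <- tibble::tibble(u = shell[[ax[1]]], v = shell[[ax[2]]],
                       n = shell[[ax[3]]],
                       marked = if (is.null(marked)) FALSE else
                         shell$point_id %in% marked$marked_ids)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$n,
                                     shape = .data$marked), size = 0.8) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste0(substr(plane, 1, 1), " [mm]"),
                  y = paste0(substr(plane, 2, 2), " [mm]"),
                  colour = "normal", shape = "painted") +
    ggplot2::theme_minimal()
}
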