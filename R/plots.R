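# ggplot2 methods for the main result types.

#' Plot a competition scan
#'
#' Holoenzyme amounts (or normalized rates) for every species against the
#' control quantity, mirroring the familiar holoenzymes-vs-competitor
#' titration layout.
#'
#' @param object A `sigma_scan` from [competition_scan()].
#' @param y Which observable to draw: `"total_holo"`, `"free_holo"`,
#'   `"free_sigma"` or `"normalized_rate"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sigma_scan
#' @export
autoplot.sigma_scan <- function(object, y = c("total_holo", "free_holo",
                                              "free_sigma",
                                              "normalized_rate"), ...) {
  y <- match.arg(y)
  if (!y %in% names(object)) {
    abort(sprintf("scan has no '%s' column (rerun with promoters).", y))
  }
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$control, y = .data[[y]],
                               colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = attr(object, "control"), y = y,
                  title = sprintf("competition scan (%s model)",
                                  attr(object, "level"))) +
    ggplot2::theme_minimal()
}

#' Plot a titration fit
#'
#' Data points with the fitted curve evaluated on a fine grid.
#'
#' @param object A `titration_fit`.
#' @param n_curve Number of curve evaluation points.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot titration_fit
#' @export
autoplot.titration_fit <- function(object, n_curve = 200, ...) {
  d <- as_tibble(object$data)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "total sigma (M)", y = "response") +
    ggplot2::theme_minimal()
  if (!is.null(object$predict_fn)) {
    xs <- exp(seq(log(min(d$x)), log(max(d$x)), length.out = n_curve))
    fitted <- tryCatch(object$predict_fn(xs), error = function(e) NULL)
    if (is.numeric(fitted) && length(fitted) == length(xs)) {
      p <- p + ggplot2::geom_line(
        data = tibble(x = xs, y = fitted),
        ggplot2::aes(x = .data$x, y = .data$y), colour = "steelblue"
      )
    } else if (is.data.frame(fitted)) {
      fitted$y <- fitted$holo / attr(object$data, "core_total")
      p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                           colour = .data$species)) +
        ggplot2::geom_point() +
        ggplot2::geom_line(data = fitted) +
        ggplot2::scale_x_log10() +
        ggplot2::labs(x = "total sigma per species (M)",
                      y = "holoenzyme fraction of core") +
        ggplot2::theme_minimal()
    }
  }
  p
}

#' Plot the pool composition of a solved state
#'
#' Stacked per-species bar chart of where sigmas sit: free, in free or
#' DNA-bound holoenzyme, promoter-bound, retained in elongation, or
#' sequestered by anti-sigma.
#'
#' @param object A `holo_state`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot holo_state
#' @export
autoplot.holo_state <- function(object, ...) {
  long <- tidy(object, long = TRUE)
  long <- long[!long$pool %in% c("total_holo", "elongating_cores"), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$species, y = .data$amount,
                                     fill = .data$pool)) +
    ggplot2::geom_col() +
    ggplot2::labs(y = sprintf("sigma pools (%s)", object$context$unit_mode)) +
    ggplot2::theme_minimal()
}
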