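#' Plot time-activity curves
#'
#' @param ... Named curves (data frames with `t_s`, `value`); the names
#'   label the legend.
#' @return A ggplot of concentration (kBq/mL) against time (s).
#' @examples
#' idif <- synthetic_idif()
#' tac <- model_tac(idif, kinetic_params())
#' plot_tac(IDIF = idif, tumour = tac)
#' @export
plot_tac <- function(...) {
  curves <- list(...)
  if (is.null(names(curves)) || any(names(curves) == "")) {
    names(curves) <- paste0("curve", seq_along(curves))
  }
  df <- dplyr::bind_rows(
    purrr::imap(curves, function(cv, nm) {
      tibble::tibble(t_s = cv$t_s, value = cv$value, curve = nm)
    })
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$t_s, .data$value,
                                   colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "activity (kBq/mL)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot Monte Carlo scheme statistics
#'
#' Point-range plot of the per-schedule mean fitted K1 with its 95%
#' confidence interval, with an optional horizontal line at the target K1.
#'
#' @param object A `scheme_stats` tibble.
#' @param target_k1 Optional target K1 to draw as a reference line.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scheme_stats <- function(object, target_k1 = NULL, ...) {
  p <- ggplot2::ggplot(
    object,
    ggplot2::aes(x = stats::reorder(.data$schedule_id, .data$mean_k1),
                 y = .data$mean_k1, ymin = .data$ci_lo, ymax = .data$ci_hi)
  ) +
    ggplot2::geom_pointrange() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "fitted K1 (mL/ccm/min)") +
    ggplot2::theme_minimal()
  if (!is.null(target_k1)) {
    p <- p + ggplot2::geom_hline(yintercept = target_k1, linetype = 2)
  }
  p
}

#' Plot a compartment-model fit against its data
#'
#' @param object A `tac_fit`.
#' @param framed_tac The framed data the model was fitted to.
#' @param ... Unused.
#' @return A ggplot of observed frame values and fitted predictions at the
#'   frame midpoints.
#' @export
autoplot.tac_fit <- function(object, framed_tac, ...) {
  df <- tibble::tibble(
    t_s = framed_tac$t_s,
    observed = framed_tac$value,
    fitted = object$fitted
  )
  long <- tidyr::pivot_longer(df, c("observed", "fitted"),
                              names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$t_s, .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_point(data = ~ dplyr::filter(.x, .data$series == "observed")) +
    ggplot2::geom_line(data = ~ dplyr::filter(.x, .data$series == "fitted")) +
    ggplot2::labs(x = "time (s)", y = "activity (kBq/mL)", colour = NULL) +
    ggplot2::theme_minimal()
}
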