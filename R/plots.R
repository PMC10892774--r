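# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_hline
#'   geom_line geom_abline geom_smooth labs theme_minimal facet_wrap
#'   position_stack geom_ribbon
NULL

#' @export
ggplot2::autoplot

#' Component decomposition bar chart of a residue scan
#'
#' Stacked per-component bars with the total contribution overlaid as
#' points; the 2 kcal/mol hotspot threshold is drawn as a dashed line.
#'
#' @param object An `ala_scan` tibble.
#' @param threshold Hotspot threshold line (default 2; `NULL` to omit).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ala_scan <- function(object, threshold = 2, ...) {
  long <- tidy(object) |> filter(.data$component != "dd_g_total")
  totals <- as_tibble(object) |>
    mutate(residue = paste0(.data$residue_name, .data$resno))
  p <- ggplot(long, aes(x = .data$residue, y = .data$value,
                        fill = .data$component)) +
    geom_col(position = position_stack()) +
    geom_point(data = totals,
               aes(x = .data$residue, y = .data$dd_g_total), fill = NA,
               inherit.aes = FALSE, shape = 21) +
    facet_wrap(~side, scales = "free_x") +
    labs(x = NULL, y = "contribution (kcal/mol)", fill = NULL) +
    theme_minimal()
  if (!is.null(threshold)) {
    p <- p + geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p
}

#' Predicted-versus-experimental scatter with the least-squares line
#'
#' @param object A `binding_correlation` from [correlation_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.binding_correlation <- function(object, ...) {
  ggplot(object$data, aes(x = .data$dg_exp, y = .data$dg_calc)) +
    geom_point() +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                linetype = "dashed", colour = "grey40") +
    labs(x = expression(Delta * G[exp] ~ "(kcal/mol)"),
         y = expression(Delta * G[calc] ~ "(kcal/mol)"),
         subtitle = sprintf("Pearson r = %.2f, Spearman rho = %.2f (n = %d)",
                            object$pearson, object$spearman, object$n)) +
    theme_minimal()
}

#' Interaction-energy trace with the k-sigma noise band
#'
#' @param object An `ie_series`.
#' @param k Band half-width in standard deviations (default 3).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ie_series <- function(object, k = 3, ...) {
  df <- tibble(frame = seq_len(object$n), energy = object$values)
  m <- mean(df$energy); s <- stats::sd(df$energy)
  ggplot(df, aes(x = .data$frame, y = .data$energy)) +
    geom_ribbon(aes(ymin = m - k * s, ymax = m + k * s), fill = "grey90") +
    geom_line() +
    geom_hline(yintercept = m, linetype = "dashed") +
    labs(x = "frame", y = expression(E[int] ~ "(kcal/mol)")) +
    theme_minimal()
}

#' RMSD trace of an ensemble selection
#'
#' @param rmsd A tibble from [rmsd_series()] (or several bound together
#'   with a `selection` label column).
#' @return A ggplot object.
#' @export
plot_rmsd_series <- function(rmsd) {
  p <- ggplot(rmsd, aes(x = .data$frame, y = .data$rmsd))
  if ("selection" %in% names(rmsd)) {
    p <- p + geom_line(aes(colour = .data$selection))
  } else {
    p <- p + geom_line()
  }
  p + labs(x = "frame", y = "RMSD (Å)") + theme_minimal()
}
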