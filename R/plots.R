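# Diagnostic plots. Each result type gets an autoplot() method returning a
# ggplot the caller can restyle.

#' Plot the sensitivity decomposition of one output
#'
#' Bar chart of per-component sensitivity indices, coloured by interaction
#' order, with the residual index appended.
#'
#' @param object An `hdmr_sensitivity`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hdmr_sensitivity <- function(object, ...) {
  df <- tidy(object)
  df <- bind_rows(df, tibble(component = "(residual)", order = NA_integer_,
                             variables = "", S = object$S_resid))
  df$component <- factor(df$component, levels = df$component)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$S,
                                   fill = factor(.data$order))) +
    ggplot2::geom_col() +
    ggplot2::labs(
      title = sprintf("Sensitivity decomposition: output %s", object$output_id),
      x = NULL, y = "sensitivity index S", fill = "order"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a network weight matrix as a heat map
#'
#' Rows are outputs, columns inputs; called edges (weight >= tau) are
#' outlined.
#'
#' @param object An `hdmr_network`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hdmr_network <- function(object, ...) {
  W <- object$W
  df <- as_tibble(as.data.frame(as.table(W)), .name_repair = "minimal")
  names(df) <- c("output", "input", "weight")
  df$edge <- !is.na(df$weight) & df$weight >= object$tau
  ggplot2::ggplot(df, ggplot2::aes(x = .data$input, y = .data$output,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = df[df$edge, ], fill = NA, colour = "red",
                       linewidth = 0.6) +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(
      title = sprintf("Aggregated total sensitivities (tau = %g)", object$tau),
      x = "input node", y = "output node", fill = "T"
    ) +
    ggplot2::theme_minimal()
}

#' Plot predicted against observed values of a forward FEOM
#'
#' @param object An `hdmr_prediction_metrics`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hdmr_prediction_metrics <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(
      title = sprintf("Forward FEOM: output %s%s", object$output_id,
                      if (!object$R_undefined) {
                        sprintf(" (R = %.3f)", object$R)
                      } else {
                        ""
                      }),
      x = "observed", y = "predicted"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the score distribution of an inverse FEOM
#'
#' The two class-conditional histograms of the continuous model output;
#' clear separation around the 0.5 threshold indicates a reliable
#' classifier.
#'
#' @param object An `hdmr_classification`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hdmr_classification <- function(object, ...) {
  df <- object$labels
  has_truth <- !all(is.na(df$truth))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$score))
  p <- if (has_truth) {
    p + ggplot2::geom_histogram(
      ggplot2::aes(fill = factor(.data$truth)), bins = 40,
      position = "identity", alpha = 0.6
    )
  } else {
    p + ggplot2::geom_histogram(bins = 40)
  }
  p +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = 2) +
    ggplot2::labs(
      title = sprintf("Inverse FEOM scores: perturbed node %s",
                      object$output_id),
      x = "continuous model output", y = "count", fill = "condition"
    ) +
    ggplot2::theme_minimal()
}
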