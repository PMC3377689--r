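# broom-style tidiers: tidy() returns one row per estimated quantity,
# glance() a one-row model summary.

#' Tidy an HDMR model into one row per basis-term coefficient
#'
#' @param x An `hdmr_model`.
#' @param ... Unused.
#' @return A tibble with columns `component`, `order`, `term`, `estimate`.
#' @export
tidy.hdmr_model <- function(x, ...) {
  comps <- x$components
  if (nrow(comps) == 0) {
    return(tibble(component = character(), order = integer(),
                  term = character(), estimate = numeric()))
  }
  bind_rows(lapply(seq_len(nrow(comps)), function(i) {
    tibble(
      component = comps$id[i], order = comps$order[i],
      term = comps$term_labels[[i]], estimate = comps$weights[[i]]
    )
  }))
}

#' One-row summary of an HDMR model
#'
#' @param x An `hdmr_model`.
#' @param ... Unused.
#' @return A tibble with output id, sample size, component counts per
#'   order, f0, residual variance and the selection alpha.
#' @export
glance.hdmr_model <- function(x, ...) {
  ord <- factor(x$components$order, levels = 1:3)
  tibble(
    output_id = x$output_id,
    n = x$fit_meta$n,
    n_components = nrow(x$components),
    n_first_order = sum(ord == 1),
    n_second_order = sum(ord == 2),
    n_third_order = sum(ord == 3),
    f0 = x$f0,
    residual_variance = x$residual_variance,
    alpha = x$fit_meta$alpha
  )
}

#' Tidy a sensitivity report into one row per component index
#'
#' @param x An `hdmr_sensitivity`.
#' @param ... Unused.
#' @return A tibble with `component`, `order`, `variables`, `S`.
#' @export
tidy.hdmr_sensitivity <- function(x, ...) {
  tibble(
    component = x$components$id,
    order = x$components$order,
    variables = vapply(x$components$vars, paste, character(1),
                       collapse = ","),
    S = x$components$S
  )
}

#' One-row summary of a sensitivity report
#'
#' @param x An `hdmr_sensitivity`.
#' @param ... Unused.
#' @return A tibble with the total variance, summed component indices,
#'   residual index and order totals.
#' @export
glance.hdmr_sensitivity <- function(x, ...) {
  tibble(
    output_id = x$output_id,
    sigma2 = x$sigma2,
    sum_S = sum(x$components$S),
    S_resid = x$S_resid,
    order1 = x$order_totals[["order1"]],
    order2 = x$order_totals[["order2"]],
    order3 = x$order_totals[["order3"]],
    n = x$n
  )
}

#' Tidy a network into its edge list
#'
#' @param x An `hdmr_network`.
#' @param ... Unused.
#' @return The edge tibble (`input`, `output`, `weight`, `condition`).
#' @export
tidy.hdmr_network <- function(x, ...) {
  x$edges
}

#' One-row summary of a network
#'
#' @param x An `hdmr_network`.
#' @param ... Unused.
#' @return A tibble with node count, threshold, edge count and maximum
#'   weight.
#' @export
glance.hdmr_network <- function(x, ...) {
  tibble(
    n_nodes = length(x$nodes),
    tau = x$tau,
    n_edges = nrow(x$edges),
    max_weight = suppressWarnings(max(x$W, na.rm = TRUE))
  )
}
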