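# Variance-based sensitivity analysis of a fitted expansion. Each component
# f_k receives S_k = cov(f_k, y) / var(y) under the population (1/n)
# convention; with the residual index S_resid = cov(eps, y) / var(y) the
# decomposition sums to exactly 1. Under independently sampled inputs the
# cross-covariances vanish and S_k reduces to var(f_k) / var(y); under
# correlated inputs each component absorbs its full row of pairwise
# covariances (including with the residual), which is the unique linear
# allocation that keeps the decomposition exact.

#' Decompose output variance into component sensitivity indices
#'
#' Evaluates every component function of the model over a table, and
#' attributes to each the share `cov(f_k, y) / var(y)` of the output
#' variance (population 1/n convention). The residual index
#' `cov(eps, y) / var(y)` completes the decomposition to exactly 1.
#' Negative indices are possible (and reported) under correlated inputs.
#'
#' @param model An `hdmr_model`.
#' @param data Samples-by-nodes data frame containing the model's output
#'   and input variables; mapped through the model's stored normalization
#'   unless already normalized.
#' @return An `hdmr_sensitivity`: per-component indices (tibble `components`
#'   with `id`, `order`, `vars`, `S`), `sigma2` (total variance of the
#'   normalized output), `S_resid`, per-input totals `T`, and `order_totals`.
#' @export
compute_sensitivities <- function(model, data) {
  stopifnot(inherits(model, "hdmr_model"))
  assert_data_frame(data)
  assert_nodes_present(data, model$output_id)
  if (nrow(data) < 2) abort("need at least 2 samples")
  if (!isTRUE(attr(data, "normalized")) && !is.null(model$norm)) {
    data <- suppressWarnings(apply_normalization(data, model$norm))
  }
  y <- data[[model$output_id]]
  sigma2 <- var_pop(y)
  if (sigma2 <= 0) {
    abort("constant output has no variance to decompose")
  }
  comps <- model$components
  if (nrow(comps) > 0) {
    F <- component_values(model, data)
    S <- apply(F, 2, cov_pop, b = y) / sigma2
    pred <- model$f0 + rowSums(F)
  } else {
    S <- numeric(0)
    pred <- rep(model$f0, length(y))
  }
  eps <- y - pred
  S_resid <- cov_pop(eps, y) / sigma2
  inputs <- model$fit_meta$inputs %||% unique(unlist(comps$vars))
  T_tot <- vapply(inputs, function(v) {
    sum(S[vapply(comps$vars, function(vs) v %in% vs, logical(1))])
  }, numeric(1))
  order_totals <- vapply(1:3, function(o) sum(S[comps$order == o]), numeric(1))
  names(order_totals) <- paste0("order", 1:3)
  structure(
    list(
      output_id = model$output_id,
      condition_id = attr(data, "condition_id") %||%
        model$fit_meta$condition_id,
      sigma2 = sigma2,
      components = tibble(
        id = comps$id, order = comps$order, vars = comps$vars, S = unname(S)
      ),
      S_resid = S_resid,
      T = T_tot,
      order_totals = order_totals,
      n = length(y),
      attribution = "S_k = cov(f_k, y) / var(y); population 1/n convention"
    ),
    class = "hdmr_sensitivity"
  )
}

#' Per-input total sensitivities and order totals
#'
#' `T_i` sums the indices of every component whose variable tuple contains
#' input i, so a second-order index contributes fully to both participants
#' (the totals may sum to more than the component indices do). Order totals
#' partition the summed component indices by interaction order.
#'
#' @param report An `hdmr_sensitivity`.
#' @return A list with `T` (named per-input totals) and `order_totals`.
#' @export
summarize_totals <- function(report) {
  stopifnot(inherits(report, "hdmr_sensitivity"))
  comps <- report$components
  inputs <- names(report$T)
  T_tot <- vapply(inputs, function(v) {
    sum(comps$S[vapply(comps$vars, function(vs) v %in% vs, logical(1))])
  }, numeric(1))
  order_totals <- vapply(1:3, function(o) sum(comps$S[comps$order == o]),
                         numeric(1))
  names(order_totals) <- paste0("order", 1:3)
  list(T = T_tot, order_totals = order_totals)
}

#' @export
print.hdmr_sensitivity <- function(x, ...) {
  cat(sprintf(
    "<hdmr_sensitivity> output '%s' (n = %d), sigma^2 = %.4g\n",
    x$output_id, x$n, x$sigma2
  ))
  cat(sprintf("  sum S = %.4f, S_resid = %.4f  [%s]\n",
              sum(x$components$S), x$S_resid, x$attribution))
  if (length(x$T) > 0) {
    top <- sort(x$T, decreasing = TRUE)
    top <- top[top != 0]
    if (length(top) > 0) {
      cat("  totals: ",
          paste(sprintf("%s = %.3f", names(top), top), collapse = ", "), "\n")
    }
  }
  invisible(x)
}

#' Write a sensitivity report to disk
#'
#' Per-component indices go to a TSV (component id, order, variables, S);
#' the summary (total variance, residual index, per-input totals, order
#' totals) goes to a JSON file next to it.
#'
#' @param report An `hdmr_sensitivity`.
#' @param path Base path; `.tsv` and `.json` suffixes are appended.
#' @return The two paths, invisibly.
#' @export
write_sensitivity_report <- function(report, path) {
  tsv <- paste0(path, ".tsv")
  json <- paste0(path, ".json")
  tab <- tibble(
    id = report$components$id,
    order = report$components$order,
    variables = vapply(report$components$vars, paste, character(1),
                       collapse = ","),
    S = report$components$S
  )
  readr::write_tsv(tab, tsv)
  jsonlite::write_json(
    list(
      output_id = report$output_id,
      condition_id = report$condition_id,
      sigma2 = report$sigma2,
      S_resid = report$S_resid,
      T = as.list(report$T),
      order_totals = as.list(report$order_totals),
      n = report$n,
      attribution = report$attribution
    ),
    json, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(c(tsv = tsv, json = json))
}
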