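# Fully Equivalent Operational Model (FEOM) use of fitted expansions:
# forward prediction of an unmeasured node from the rest of the network
# state, and inverse classification of the experimental condition from the
# observed state of a pairwise-comparison model.

#' Held-out prediction accuracy of a forward FEOM
#'
#' Predicts the output node over a test table and summarises accuracy as
#' the Pearson correlation between predicted and observed values plus the
#' fraction of points whose relative error |pred - obs| / |obs| (on the
#' original measurement scale) falls within each tolerance. Rows with an
#' observed value of exactly 0 are excluded from the tolerance fractions
#' and counted separately.
#'
#' @param model An `hdmr_model`.
#' @param test Data frame with the model's output and input variables, on
#'   the original scale.
#' @param tolerances Relative-error tolerances. Default 1%, 5%, 10%, 20%.
#' @return An `hdmr_prediction_metrics` list: `R` (NA with
#'   `R_undefined = TRUE` when the observations or predictions are
#'   constant), `within_tolerance` (named, non-decreasing fractions),
#'   `n_test`, `n_zero_obs`, and the per-row `predictions` tibble.
#' @export
evaluate_prediction <- function(model, test,
                                tolerances = c(0.01, 0.05, 0.10, 0.20)) {
  stopifnot(inherits(model, "hdmr_model"))
  assert_data_frame(test, "test")
  assert_nodes_present(test, model$output_id, "test")
  if (nrow(test) < 2) abort("need at least 2 test samples")
  obs <- test[[model$output_id]]
  pred <- predict(model, test, scale = "original")
  undefined <- var_pop(obs) <= 0 || var_pop(pred) <= 0
  R <- if (undefined) NA_real_ else cor(pred, obs)
  nz <- obs != 0
  rel <- abs(pred[nz] - obs[nz]) / abs(obs[nz])
  tolerances <- sort(tolerances)
  within <- vapply(tolerances, function(t) mean(rel <= t), numeric(1))
  names(within) <- paste0(format(100 * tolerances, trim = TRUE), "%")
  structure(
    list(
      output_id = model$output_id,
      R = R,
      R_undefined = undefined,
      within_tolerance = within,
      n_test = length(obs),
      n_zero_obs = sum(!nz),
      predictions = tibble(observed = obs, predicted = pred)
    ),
    class = "hdmr_prediction_metrics"
  )
}

#' @export
print.hdmr_prediction_metrics <- function(x, ...) {
  cat(sprintf("<hdmr_prediction_metrics> output '%s', n = %d\n",
              x$output_id, x$n_test))
  if (x$R_undefined) {
    cat("  R undefined (constant observations or predictions)\n")
  } else {
    cat(sprintf("  R = %.4f (R^2 = %.4f)\n", x$R, x$R^2))
  }
  cat("  within tolerance:",
      paste(sprintf("%s: %.3f", names(x$within_tolerance),
                    x$within_tolerance), collapse = ", "), "\n")
  if (x$n_zero_obs > 0) {
    cat(sprintf("  (%d zero-valued observations excluded)\n", x$n_zero_obs))
  }
  invisible(x)
}

#' Classify experimental condition with an inverse FEOM
#'
#' An inverse FEOM is an HDMR model fitted on a pairwise-comparison dataset
#' with the perturbed node (Boolean 0/1 by construction) as the output. Its
#' continuous prediction is thresholded at 0.5 to assign each sample to a
#' condition; with known labels the accuracy is the fraction correctly
#' grouped.
#'
#' @param model An `hdmr_model` whose output is the perturbed node of a
#'   pairwise table.
#' @param samples Data frame of observed node values (original scale)
#'   containing all model inputs.
#' @param truth Optional known 0/1 condition labels.
#' @return An `hdmr_classification`: tibble `labels` with per-sample
#'   continuous `score` and Boolean `label`, plus `accuracy` (NA without
#'   `truth`) and the fixed `threshold` 0.5.
#' @export
classify_inverse <- function(model, samples, truth = NULL) {
  stopifnot(inherits(model, "hdmr_model"))
  assert_data_frame(samples, "samples")
  score <- predict(model, samples, scale = "original")
  label <- as.integer(score > 0.5)
  accuracy <- if (!is.null(truth)) {
    if (length(truth) != length(label)) {
      abort("`truth` must have one label per sample")
    }
    mean(label == truth)
  } else {
    NA_real_
  }
  structure(
    list(
      output_id = model$output_id,
      labels = tibble(score = score, label = label,
                      truth = if (!is.null(truth)) truth else NA_integer_),
      accuracy = accuracy,
      threshold = 0.5
    ),
    class = "hdmr_classification"
  )
}

#' @export
print.hdmr_classification <- function(x, ...) {
  cat(sprintf("<hdmr_classification> perturbed node '%s', n = %d\n",
              x$output_id, nrow(x$labels)))
  if (!is.na(x$accuracy)) {
    cat(sprintf("  accuracy = %.3f at threshold %.1f\n",
                x$accuracy, x$threshold))
  }
  invisible(x)
}

#' ROC curve of an inverse FEOM over score thresholds
#'
#' @param classification An `hdmr_classification` with known truth labels.
#' @param thresholds Score thresholds; default a grid over the score range.
#' @return A tibble with `threshold`, `tpr`, `fpr`, `accuracy`.
#' @export
roc_points <- function(classification, thresholds = NULL) {
  stopifnot(inherits(classification, "hdmr_classification"))
  lab <- classification$labels
  if (all(is.na(lab$truth))) abort("ROC requires known truth labels")
  thresholds <- thresholds %||%
    seq(min(lab$score), max(lab$score), length.out = 101)
  pos <- lab$truth == 1
  tibble(
    threshold = thresholds,
    tpr = vapply(thresholds, function(t) mean(lab$score[pos] > t), numeric(1)),
    fpr = vapply(thresholds, function(t) mean(lab$score[!pos] > t), numeric(1)),
    accuracy = vapply(thresholds, function(t) {
      mean(as.integer(lab$score > t) == lab$truth)
    }, numeric(1))
  )
}
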