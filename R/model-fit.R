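# HDMR model fitting: candidate component functions are screened by a
# forward, order-by-order nested-model F-test (model reduction); the
# surviving components are then refit jointly by (weighted) least squares
# around the output mean.

default_degrees <- function() c(k = 3L, l = 2L, m = 1L)

candidate_degrees <- function(order, degrees) {
  switch(order,
    rep(degrees[["k"]], 1),
    rep(degrees[["l"]], 2),
    rep(degrees[["m"]], 3)
  )
}

#' Enumerate candidate component functions
#'
#' Order-1 candidates are all inputs. Under the hierarchical policy,
#' higher-order candidates are drawn only from inputs already carrying a
#' significant first-order component (cooperative interactions are, in
#' practice, observed between nodes that already act independently); the
#' exhaustive policy enumerates all tuples. Ordering is deterministic and
#' lexicographic.
#'
#' @param inputs Character vector of input node names.
#' @param max_order Highest component order to enumerate (1, 2, or 3).
#' @param policy `"hierarchical"` or `"exhaustive"`.
#' @param selected_first_order Inputs with significant first-order terms
#'   (required by the hierarchical policy for orders >= 2).
#' @return A tibble with columns `order`, `vars` (list column), `id`.
#' @export
enumerate_candidates <- function(inputs, max_order = 2,
                                 policy = c("hierarchical", "exhaustive"),
                                 selected_first_order = NULL) {
  policy <- match.arg(policy)
  if (!max_order %in% 1:3) abort("`max_order` must be 1, 2, or 3")
  inputs <- sort(inputs)
  rows <- list(tibble(order = 1L, vars = as.list(inputs)))
  pool <- if (policy == "hierarchical") {
    sort(intersect(inputs, selected_first_order %||% character(0)))
  } else {
    inputs
  }
  for (ord in 2:3) {
    if (max_order < ord || length(pool) < ord) next
    combos <- utils::combn(pool, ord, simplify = FALSE)
    rows[[length(rows) + 1]] <- tibble(order = as.integer(ord), vars = combos)
  }
  out <- bind_rows(rows)
  out$id <- vapply(out$vars, candidate_id, character(1))
  out
}

# Fit y on X by QR, returning rank and residual sum of squares.
rss_fit <- function(X, y) {
  fit <- lm.fit(X, y)
  list(rank = fit$rank, rss = sum(fit$residuals^2), coef = fit$coefficients)
}

#' Select significant component functions by forward F-test model reduction
#'
#' Candidates are visited in the supplied order. Each candidate's basis
#' terms are tentatively added to the current model; the F statistic on the
#' reduction in residual sum of squares (numerator df = number of added
#' independent terms, denominator df = n minus all fitted terms minus 1) is
#' compared to `alpha`, and the candidate is kept only when
#' p < alpha. Every tested candidate is logged.
#'
#' @param data Normalized samples-by-nodes data frame.
#' @param output_id Output node name.
#' @param candidates Candidate tibble from [enumerate_candidates()].
#' @param bases Named list of `hdmr_basis` for all candidate variables.
#' @param degrees Named degree vector `c(k = , l = , m = )`.
#' @param alpha Significance level in (0, 1).
#' @param prior Optional tibble of already-selected candidates whose terms
#'   form the base model (used when selection proceeds order by order).
#' @return A list with `selected` (tibble of kept candidates) and `log`
#'   (tibble of every test: id, order, n_terms, F, p, included).
#' @export
f_test_select <- function(data, output_id, candidates, bases,
                          degrees = default_degrees(), alpha = 0.01,
                          prior = NULL) {
  assert_data_frame(data)
  assert_nodes_present(data, output_id)
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie strictly in (0, 1)")
  y <- data[[output_id]]
  n <- length(y)
  X <- matrix(1, nrow = n, ncol = 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(prior) && nrow(prior) > 0) {
    for (i in seq_len(nrow(prior))) {
      Tm <- evaluate_terms(bases, prior$vars[[i]],
                           candidate_degrees(prior$order[i], degrees), data)
      X <- cbind(X, Tm)
    }
  }
  base <- rss_fit(X, y)
  rank_cur <- base$rank
  rss_cur <- base$rss
  log_rows <- vector("list", nrow(candidates))
  included <- logical(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    vars <- candidates$vars[[i]]
    degs <- candidate_degrees(candidates$order[i], degrees)
    Tm <- evaluate_terms(bases, vars, degs, data)
    fit <- rss_fit(cbind(X, Tm), y)
    df1 <- fit$rank - rank_cur
    df2 <- n - fit$rank
    if (df2 <= 0) {
      abort(sprintf(
        "no residual degrees of freedom (n = %d, %d fitted terms): use fewer terms or more samples",
        n, fit$rank
      ))
    }
    if (df1 <= 0) {
      # candidate terms are collinear with the current model; cannot test
      log_rows[[i]] <- tibble(
        id = candidates$id[i], order = candidates$order[i],
        n_terms = ncol(Tm), F_statistic = NA_real_, p_value = NA_real_,
        included = FALSE
      )
      next
    }
    tiny <- 1e-12 * max(1, sum(y^2))
    if (rss_cur <= tiny) {
      # current model already interpolates the data; nothing left to explain
      Fstat <- 0
      p <- 1
    } else if (fit$rss <= tiny) {
      Fstat <- Inf
      p <- 0
    } else {
      Fstat <- max(0, (rss_cur - fit$rss) / df1) / (fit$rss / df2)
      p <- pf(Fstat, df1, df2, lower.tail = FALSE)
    }
    keep <- p < alpha
    if (keep) {
      X <- cbind(X, Tm)
      rank_cur <- fit$rank
      rss_cur <- fit$rss
      included[i] <- TRUE
    }
    log_rows[[i]] <- tibble(
      id = candidates$id[i], order = candidates$order[i],
      n_terms = ncol(Tm), F_statistic = Fstat, p_value = p, included = keep
    )
  }
  list(selected = candidates[included, ], log = bind_rows(log_rows))
}

#' Jointly estimate component weights by (weighted) least squares
#'
#' The zeroth-order term f0 is the (weighted) output mean. Each selected
#' component's basis-product columns are centered on their training means so
#' every component function has exactly zero (weighted) training mean; the
#' weights then solve one joint least-squares problem on the centered
#' output.
#'
#' @param data Normalized samples-by-nodes data frame.
#' @param output_id Output node name.
#' @param selected Tibble of selected candidates (`order`, `vars`).
#' @param bases Named list of `hdmr_basis`.
#' @param degrees Named degree vector.
#' @param sample_weights Optional non-negative sample weights.
#' @return An `hdmr_model` (no selection log or normalization attached; see
#'   [fit_hdmr()] for the full pipeline).
#' @export
fit_least_squares <- function(data, output_id, selected, bases,
                              degrees = default_degrees(),
                              sample_weights = NULL) {
  assert_data_frame(data)
  assert_nodes_present(data, output_id)
  y <- data[[output_id]]
  n <- length(y)
  w <- sample_weights %||% rep(1, n)
  if (length(w) != n || any(w < 0) || sum(w) <= 0) {
    abort("`sample_weights` must be non-negative, length n, not all zero")
  }
  f0 <- wmean(y, w)
  comp_rows <- list()
  blocks <- list()
  if (!is.null(selected) && nrow(selected) > 0) {
    for (i in seq_len(nrow(selected))) {
      vars <- selected$vars[[i]]
      degs <- candidate_degrees(selected$order[i], degrees)
      Tm <- evaluate_terms(bases, vars, degs, data)
      mu <- apply(Tm, 2, wmean, w = w)
      blocks[[i]] <- sweep(Tm, 2, mu)
      comp_rows[[i]] <- tibble(
        id = candidate_id(vars), order = selected$order[i],
        vars = list(vars), degrees = list(degs),
        term_labels = list(colnames(Tm)), term_means = list(unname(mu))
      )
    }
  }
  if (length(blocks) == 0) {
    components <- tibble(
      id = character(), order = integer(), vars = list(), degrees = list(),
      term_labels = list(), term_means = list(), weights = list()
    )
    resid <- y - f0
  } else {
    X <- do.call(cbind, blocks)
    fit <- lm.wfit(X, y - f0, w)
    if (fit$rank < ncol(X)) {
      aliased <- colnames(X)[is.na(fit$coefficients)]
      abort(sprintf(
        "rank-deficient design: collinear term%s %s",
        if (length(aliased) > 1) "s" else "",
        paste0("'", aliased, "'", collapse = ", ")
      ))
    }
    coefs <- fit$coefficients
    components <- bind_rows(comp_rows)
    sizes <- vapply(components$term_labels, length, integer(1))
    ends <- cumsum(sizes)
    starts <- ends - sizes + 1L
    components$weights <- lapply(seq_along(sizes), function(i) {
      unname(coefs[starts[i]:ends[i]])
    })
    resid <- fit$residuals
  }
  structure(
    list(
      output_id = output_id,
      f0 = f0,
      components = components,
      bases = bases,
      selection_log = NULL,
      residual_variance = sum(w * resid^2) / sum(w),
      norm = attr(data, "hdmr_norm"),
      fit_meta = list(
        n = n, alpha = NA_real_, degrees = degrees,
        weighted = !is.null(sample_weights)
      )
    ),
    class = "hdmr_model"
  )
}

#' Fit one RS-HDMR input-output mapping
#'
#' Full pipeline for a single output node: normalization check, orthonormal
#' basis construction per input, candidate enumeration, order-by-order
#' F-test model reduction, and a final joint least-squares refit of every
#' surviving component. The result is deterministic given the data and
#' configuration.
#'
#' @param data Samples-by-nodes data frame (normalized to the unit interval;
#'   an unnormalized table is normalized internally and the transform
#'   stored with the model).
#' @param output_id The output node; all other columns (or `inputs`) act as
#'   inputs.
#' @param inputs Optional explicit input set (default: every other node).
#' @param max_order Highest component order (1-3). Default 2.
#' @param degrees Named degree vector `c(k, l, m)`: polynomial degree of
#'   first-order components and of each factor of second- and third-order
#'   products. Default `c(k = 3, l = 2, m = 1)`.
#' @param alpha F-test significance level for component inclusion.
#'   Default 0.01.
#' @param policy Candidate policy for orders >= 2, `"hierarchical"`
#'   (default) or `"exhaustive"`.
#' @param sample_weights Optional non-negative per-sample weights.
#' @return An `hdmr_model`: `f0` (output mean on the normalized scale),
#'   `components` (selected component functions with weights), `bases`,
#'   `selection_log`, `residual_variance`, the stored normalization
#'   transform, and fit metadata.
#' @export
fit_hdmr <- function(data, output_id, inputs = NULL, max_order = 2,
                     degrees = default_degrees(), alpha = 0.01,
                     policy = c("hierarchical", "exhaustive"),
                     sample_weights = NULL) {
  policy <- match.arg(policy)
  assert_data_frame(data)
  assert_nodes_present(data, output_id)
  if (!isTRUE(attr(data, "normalized"))) {
    data <- normalize_unit_interval(data)
  } else if (is.null(attr(data, "hdmr_norm"))) {
    attr(data, "hdmr_norm") <- tibble(
      node = names(data), min = 0, max = 1
    )
  }
  inputs <- inputs %||% setdiff(names(data), output_id)
  assert_nodes_present(data, inputs)
  inputs <- sort(setdiff(inputs, output_id))
  if (length(inputs) == 0) abort("no input nodes available")
  degrees <- degrees_complete(degrees)
  max_deg <- max(degrees[["k"]],
                 if (max_order >= 2) degrees[["l"]] else 0L,
                 if (max_order >= 3) degrees[["m"]] else 0L)
  bases <- lapply(inputs, function(v) {
    build_orthonormal_basis(data[[v]], max_deg, variable_id = v)
  })
  names(bases) <- inputs
  cand1 <- enumerate_candidates(inputs, max_order = 1)
  sel <- f_test_select(data, output_id, cand1, bases, degrees, alpha)
  selected <- sel$selected
  logs <- list(sel$log)
  first_order <- vapply(selected$vars, `[[`, character(1), 1)
  for (ord in 2:3) {
    if (max_order < ord) break
    cand <- enumerate_candidates(
      inputs, max_order = ord, policy = policy,
      selected_first_order = first_order
    )
    cand <- cand[cand$order == ord, ]
    if (nrow(cand) == 0) next
    sel <- f_test_select(data, output_id, cand, bases, degrees, alpha,
                         prior = selected)
    selected <- bind_rows(selected, sel$selected)
    logs[[length(logs) + 1]] <- sel$log
  }
  model <- fit_least_squares(data, output_id, selected, bases, degrees,
                             sample_weights)
  model$selection_log <- bind_rows(logs)
  model$fit_meta$alpha <- alpha
  model$fit_meta$max_order <- max_order
  model$fit_meta$policy <- policy
  model$fit_meta$inputs <- inputs
  model$fit_meta$condition_id <- attr(data, "condition_id")
  model
}

degrees_complete <- function(degrees) {
  d <- default_degrees()
  if (is.null(names(degrees))) names(degrees) <- names(d)[seq_along(degrees)]
  d[names(degrees)] <- as.integer(degrees)
  d
}

# Evaluate every component function of a model on (normalized) data.
# Returns an n x n_components matrix; components have exactly zero mean on
# the training sample by construction.
component_values <- function(model, data) {
  comps <- model$components
  out <- matrix(0, nrow = nrow(data), ncol = nrow(comps),
                dimnames = list(NULL, comps$id))
  for (i in seq_len(nrow(comps))) {
    Tm <- evaluate_terms(model$bases, comps$vars[[i]], comps$degrees[[i]], data)
    out[, i] <- sweep(Tm, 2, comps$term_means[[i]]) %*% comps$weights[[i]]
  }
  out
}

#' Predict an output node from network state (forward FEOM)
#'
#' Evaluates the fitted expansion f0 + sum of component functions. Inputs on
#' the original measurement scale are mapped through the model's stored
#' normalization (values outside the training range are clamped to \[0, 1\]
#' with a warning); a table flagged as already normalized is used as is.
#'
#' @param object An `hdmr_model`.
#' @param newdata Data frame containing all model input variables.
#' @param scale Return predictions on the `"original"` measurement scale
#'   (default) or the `"normalized"` unit scale.
#' @param ... Unused.
#' @return Numeric vector of predictions, one per row of `newdata`.
#' @export
predict.hdmr_model <- function(object, newdata,
                               scale = c("original", "normalized"), ...) {
  scale <- match.arg(scale)
  assert_data_frame(newdata, "newdata")
  required <- unique(unlist(object$components$vars))
  missing <- setdiff(required, names(newdata))
  if (length(missing) > 0) {
    abort(sprintf("missing required input variable%s %s",
                  if (length(missing) > 1) "s" else "",
                  paste0("'", missing, "'", collapse = ", ")))
  }
  if (!isTRUE(attr(newdata, "normalized")) && !is.null(object$norm)) {
    norm_in <- object$norm[object$norm$node != object$output_id, ]
    newdata <- apply_normalization(newdata, norm_in)
  }
  pred <- rep(object$f0, nrow(newdata))
  if (nrow(object$components) > 0) {
    pred <- pred + rowSums(component_values(object, newdata))
  }
  if (scale == "original" && !is.null(object$norm)) {
    row <- object$norm[object$norm$node == object$output_id, ]
    if (nrow(row) == 1) {
      pred <- row$min + pred * (row$max - row$min)
    }
  }
  pred
}

#' @export
print.hdmr_model <- function(x, ...) {
  cat(sprintf("<hdmr_model> output '%s' (n = %d)\n", x$output_id, x$fit_meta$n))
  cat(sprintf("  f0 = %.4f (normalized scale), residual variance = %.4g\n",
              x$f0, x$residual_variance))
  if (nrow(x$components) == 0) {
    cat("  no significant component functions (zeroth-order model)\n")
  } else {
    tab <- table(factor(x$components$order, levels = 1:3))
    cat(sprintf("  components: %d first-, %d second-, %d third-order\n",
                tab[1], tab[2], tab[3]))
    cat("  ", paste(x$components$id, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize an HDMR model to JSON
#'
#' A versioned document holding the output id, f0, normalization transform,
#' bases, component functions, selection log and fit metadata; restored by
#' [model_from_json()].
#'
#' @param model An `hdmr_model`.
#' @param path Optional file to write.
#' @return The JSON string (invisibly when `path` is given).
#' @export
model_to_json <- function(model, path = NULL) {
  comps <- model$components
  payload <- list(
    format = "hdmrnet-model",
    version = 1L,
    output_id = model$output_id,
    f0 = model$f0,
    residual_variance = model$residual_variance,
    norm = if (!is.null(model$norm)) as.list(model$norm),
    bases = lapply(unname(model$bases), function(b) list(
      variable_id = b$variable_id, degree = b$degree,
      coeffs = lapply(seq_len(nrow(b$coeffs)), function(r) b$coeffs[r, ]),
      training_n = b$training_n
    )),
    components = lapply(seq_len(nrow(comps)), function(i) list(
      id = comps$id[i], order = comps$order[i],
      vars = comps$vars[[i]], degrees = comps$degrees[[i]],
      term_labels = comps$term_labels[[i]],
      term_means = comps$term_means[[i]], weights = comps$weights[[i]]
    )),
    selection_log = if (!is.null(model$selection_log)) {
      as.list(model$selection_log[, c("id", "order", "n_terms",
                                      "F_statistic", "p_value", "included")])
    },
    fit_meta = model$fit_meta[setdiff(names(model$fit_meta), "condition_id")]
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(17),
                           null = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Restore an HDMR model from JSON
#'
#' @param json A JSON string or path to a file written by [model_to_json()].
#' @return An `hdmr_model`.
#' @export
model_from_json <- function(json) {
  if (length(json) == 1 && !grepl("^\\s*\\{", json) && file.exists(json)) {
    json <- paste(readLines(json, warn = FALSE), collapse = "\n")
  }
  p <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  if (!identical(p$format, "hdmrnet-model")) {
    abort("not an hdmrnet model document")
  }
  bases <- lapply(p$bases, function(b) structure(list(
    variable_id = b$variable_id, degree = as.integer(b$degree),
    coeffs = do.call(rbind, lapply(b$coeffs, unlist)),
    training_n = as.integer(b$training_n)
  ), class = "hdmr_basis"))
  names(bases) <- vapply(bases, function(b) b$variable_id, character(1))
  comps <- p$components
  components <- tibble(
    id = vapply(comps, `[[`, character(1), "id"),
    order = vapply(comps, function(c) as.integer(c$order), integer(1)),
    vars = lapply(comps, function(c) unlist(c$vars)),
    degrees = lapply(comps, function(c) as.integer(unlist(c$degrees))),
    term_labels = lapply(comps, function(c) unlist(c$term_labels)),
    term_means = lapply(comps, function(c) unlist(c$term_means)),
    weights = lapply(comps, function(c) unlist(c$weights))
  )
  norm <- if (!is.null(p$norm)) {
    tibble(node = unlist(p$norm$node), min = unlist(p$norm$min),
           max = unlist(p$norm$max))
  }
  meta <- p$fit_meta
  meta$degrees <- degrees_complete(unlist(meta$degrees))
  structure(
    list(
      output_id = p$output_id, f0 = p$f0, components = components,
      bases = bases,
      selection_log = if (!is.null(p$selection_log)) {
        as_tibble(lapply(p$selection_log, unlist))
      },
      residual_variance = p$residual_variance, norm = norm, fit_meta = meta
    ),
    class = "hdmr_model"
  )
}
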