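# Network assembly: one HDMR mapping per node per condition, per-input total
# sensitivities aggregated across conditions by their maximum, and edges
# called where the aggregated weight reaches a significance threshold tau.
# Rows of the weight matrix are outputs, columns are inputs.

#' Fit an HDMR mapping for every node of a table
#'
#' Each node in turn is treated as the output with all remaining nodes as
#' inputs. A node whose fit fails is recorded in the run log rather than
#' aborting the whole condition.
#'
#' @param data Samples-by-nodes data frame (one condition).
#' @param ... Passed to [fit_hdmr()] (`max_order`, `degrees`, `alpha`, ...).
#' @return An `hdmr_fit_set`: a named list with one `list(model, report)`
#'   per node, plus attributes `failed` (named list of error messages) and
#'   `run_log` (tibble: node, n_components, S_resid, status).
#' @export
fit_all_nodes <- function(data, ...) {
  assert_data_frame(data)
  if (ncol(data) < 2) abort("need at least 2 nodes")
  if (!isTRUE(attr(data, "normalized"))) {
    data <- normalize_unit_interval(data)
  }
  nodes <- names(data)
  fits <- list()
  failed <- list()
  log_rows <- list()
  for (nd in nodes) {
    res <- tryCatch({
      model <- fit_hdmr(data, nd, ...)
      report <- compute_sensitivities(model, data)
      list(model = model, report = report)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[[nd]] <- conditionMessage(res)
      log_rows[[nd]] <- tibble(
        node = nd, n_components = NA_integer_, S_resid = NA_real_,
        status = paste("failed:", conditionMessage(res))
      )
    } else {
      fits[[nd]] <- res
      log_rows[[nd]] <- tibble(
        node = nd, n_components = nrow(res$model$components),
        S_resid = res$report$S_resid, status = "ok"
      )
    }
  }
  structure(fits, failed = failed, run_log = bind_rows(log_rows),
            class = "hdmr_fit_set")
}

reports_of <- function(x) {
  if (inherits(x, "hdmr_fit_set")) {
    return(lapply(unclass(x), `[[`, "report"))
  }
  if (inherits(x, "hdmr_sensitivity")) return(list(x))
  x
}

#' Aggregate per-condition sensitivity totals into a network
#'
#' The weight of a candidate connection input -> output is the maximum,
#' over all supplied conditions, of the input's total sensitivity T in the
#' report whose output is that node. Pairwise-comparison reports (inverse
#' FEOMs of a perturbed node) contribute only edges incident to the
#' perturbed node, which is their output.
#'
#' @param reports A named list of conditions; each condition is an
#'   `hdmr_fit_set` or a list of `hdmr_sensitivity` reports.
#' @param pairwise_reports Optional named list of pairwise-comparison
#'   reports (same shapes).
#' @param tau Edge-calling threshold on the aggregated weight.
#'   Default 0.1.
#' @return An `hdmr_network`: node set, weight matrix `W` (rows = outputs,
#'   columns = inputs, diagonal `NA`), `tau`, per-entry `provenance`
#'   (condition achieving the maximum), and the called `edges` tibble.
#' @export
aggregate_network <- function(reports, pairwise_reports = NULL, tau = 0.1) {
  conditions <- lapply(reports, reports_of)
  if (is.null(names(conditions)) || any(!nzchar(names(conditions)))) {
    names(conditions) <- paste0("condition", seq_along(conditions))
  }
  all_reports <- unlist(conditions, recursive = FALSE)
  nodes <- sort(unique(unlist(lapply(all_reports, function(r) {
    c(r$output_id, names(r$T))
  }))))
  for (cond in conditions) {
    universe <- sort(unique(unlist(lapply(cond, function(r) {
      c(r$output_id, names(r$T))
    }))))
    if (!setequal(universe, nodes)) {
      abort("all conditions must share the same node universe")
    }
  }
  W <- matrix(-Inf, length(nodes), length(nodes),
              dimnames = list(output = nodes, input = nodes))
  prov <- matrix(NA_character_, length(nodes), length(nodes),
                 dimnames = dimnames(W))
  take <- function(cond_id, report, restrict_to_output = FALSE) {
    out <- report$output_id
    for (v in names(report$T)) {
      if (v == out) next
      if (report$T[[v]] > W[out, v]) {
        W[out, v] <<- report$T[[v]]
        prov[out, v] <<- cond_id
      }
    }
  }
  for (ci in seq_along(conditions)) {
    for (r in conditions[[ci]]) take(names(conditions)[ci], r)
  }
  if (!is.null(pairwise_reports)) {
    pw <- lapply(pairwise_reports, reports_of)
    if (is.null(names(pw)) || any(!nzchar(names(pw)))) {
      names(pw) <- paste0("pairwise", seq_along(pw))
    }
    for (ci in seq_along(pw)) {
      for (r in pw[[ci]]) {
        if (!all(c(r$output_id, names(r$T)) %in% nodes)) {
          abort("pairwise reports must stay within the node universe")
        }
        # only edges incident to the perturbed node (the pairwise output)
        take(names(pw)[ci], r)
      }
    }
  }
  W[!is.finite(W)] <- NA_real_
  diag(W) <- NA_real_
  graph <- structure(
    list(nodes = nodes, W = W, tau = tau, provenance = prov, edges = NULL),
    class = "hdmr_network"
  )
  threshold_network(graph, tau)
}

#' Re-threshold a network's edge set
#'
#' Edges are exactly the input -> output pairs whose aggregated weight is
#' at least `tau`; weights are untouched, so edge sets are nested in `tau`.
#'
#' @param graph An `hdmr_network`.
#' @param tau Threshold, >= 0.
#' @return The graph with an updated `edges` tibble and `tau`.
#' @export
threshold_network <- function(graph, tau) {
  stopifnot(inherits(graph, "hdmr_network"))
  if (!is.numeric(tau) || tau < 0) abort("`tau` must be >= 0")
  W <- graph$W
  idx <- which(!is.na(W) & W >= tau, arr.ind = TRUE)
  edges <- tibble(
    input = colnames(W)[idx[, 2]],
    output = rownames(W)[idx[, 1]],
    weight = W[idx],
    condition = graph$provenance[idx]
  )
  edges <- arrange(edges, .data$input, .data$output)
  graph$tau <- tau
  graph$edges <- edges
  graph
}

#' Edge list of a thresholded network
#'
#' @param graph An `hdmr_network`.
#' @return A tibble with columns `input`, `output`, `weight`, `condition`.
#' @export
network_edges <- function(graph) {
  stopifnot(inherits(graph, "hdmr_network"))
  graph$edges
}

#' Number of edges as a function of the threshold
#'
#' Profiles the edge count over a grid of thresholds, supporting empirical
#' threshold choice.
#'
#' @param graph An `hdmr_network`.
#' @param taus Thresholds to profile; default a grid over \[0, max weight\].
#' @return A tibble with columns `tau` and `n_edges` (non-increasing).
#' @export
edge_tau_profile <- function(graph, taus = NULL) {
  stopifnot(inherits(graph, "hdmr_network"))
  w <- graph$W[!is.na(graph$W)]
  taus <- taus %||% seq(0, max(w, 0), length.out = 41)
  tibble(
    tau = taus,
    n_edges = vapply(taus, function(t) sum(w >= t), integer(1))
  )
}

#' Export a network to disk
#'
#' `adjacency-tsv` writes the full weight matrix with node headers;
#' `edge-list-sif` writes one `input<TAB>hdmr<TAB>output` line per called
#' edge; `json` includes weights, tau and per-edge provenance.
#'
#' @param graph An `hdmr_network`.
#' @param path Output file path.
#' @param format One of `"adjacency-tsv"`, `"edge-list-sif"`, `"json"`.
#' @param normalize_weights Scale weights so the largest equals 1 (for
#'   cross-method comparison). Default `FALSE`.
#' @return `path`, invisibly.
#' @export
export_network <- function(graph, path,
                           format = c("adjacency-tsv", "edge-list-sif", "json"),
                           normalize_weights = FALSE) {
  stopifnot(inherits(graph, "hdmr_network"))
  format <- match.arg(format)
  W <- graph$W
  if (normalize_weights) {
    mx <- max(W, na.rm = TRUE)
    if (is.finite(mx) && mx > 0) W <- W / mx
  }
  if (format == "adjacency-tsv") {
    tab <- as_tibble(as.data.frame(W))
    tab <- tibble(output = rownames(W)) %>% dplyr::bind_cols(tab)
    readr::write_tsv(tab, path)
  } else if (format == "edge-list-sif") {
    lines <- sprintf("%s\thdmr\t%s", graph$edges$input, graph$edges$output)
    writeLines(lines, path)
  } else {
    jsonlite::write_json(
      list(
        nodes = graph$nodes,
        tau = graph$tau,
        weights = apply(W, 1, identity, simplify = FALSE),
        edges = list(
          input = graph$edges$input, output = graph$edges$output,
          weight = graph$edges$weight, condition = graph$edges$condition
        )
      ),
      path, auto_unbox = TRUE, digits = NA, null = "null", na = "null"
    )
  }
  invisible(path)
}

#' Symmetrized view of a directed network
#'
#' Takes the elementwise maximum of the two directions, for comparison with
#' undirected inference methods.
#'
#' @param graph An `hdmr_network`.
#' @return The graph with `W` symmetrized and edges re-called at its `tau`.
#' @export
symmetrize_network <- function(graph) {
  stopifnot(inherits(graph, "hdmr_network"))
  graph$W <- pmax(graph$W, t(graph$W), na.rm = TRUE)
  diag(graph$W) <- NA_real_
  threshold_network(graph, graph$tau)
}

#' @export
print.hdmr_network <- function(x, ...) {
  cat(sprintf("<hdmr_network> %d nodes, tau = %g, %d edge%s\n",
              length(x$nodes), x$tau, nrow(x$edges),
              if (nrow(x$edges) == 1) "" else "s"))
  invisible(x)
}
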