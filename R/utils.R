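# Internal helpers shared across modules.

# Population (1/n) covariance; matches Monte-Carlo integration over the
# empirical measure used everywhere in the package.
cov_pop <- function(a, b) mean(a * b) - mean(a) * mean(b)

var_pop <- function(a) cov_pop(a, a)

# Weighted mean with weights normalised to sum 1.
wmean <- function(x, w) sum(x * w) / sum(w)

# Deterministic candidate identifier, e.g. "Erk" or "Mek:Raf".
candidate_id <- function(vars) paste(vars, collapse = ":")

assert_data_frame <- function(x, arg = "data") {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame of samples by nodes.", arg))
  }
}

node_names <- function(x) names(x)

# Stop with a friendly message if a node is missing from a table.
assert_nodes_present <- function(x, nodes, arg = "data") {
  missing <- setdiff(nodes, names(x))
  if (length(missing) > 0) {
    abort(sprintf(
      "node%s %s not found in `%s`",
      if (length(missing) > 1) "s" else "",
      paste0("'", missing, "'", collapse = ", "), arg
    ))
  }
}
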