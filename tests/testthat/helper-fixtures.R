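# Fixtures are generated in code at test time.

# Mark a table as already normalized with the identity transform, for tests
# that construct unit-interval data directly.
as_norm <- function(df) {
  df <- tibble::as_tibble(df)
  attr(df, "normalized") <- TRUE
  attr(df, "hdmr_norm") <- tibble::tibble(node = names(df), min = 0, max = 1)
  df
}

# Independent U(0,1) table with named columns.
runif_table <- function(n, nodes, seed = 1) {
  set.seed(seed)
  as_norm(stats::setNames(
    as.data.frame(matrix(stats::runif(n * length(nodes)), n)), nodes
  ))
}

# Orthonormal shifted-Legendre polynomials on [0,1] (analytic), used as an
# independent oracle for basis construction and synthetic truths.
legendre1 <- function(u) sqrt(3) * (2 * u - 1)
legendre2 <- function(u) sqrt(5) * (6 * u^2 - 6 * u + 1)
legendre3 <- function(u) sqrt(7) * (20 * u^3 - 30 * u^2 + 12 * u - 1)

# Minimal hand-built sensitivity report for network arithmetic oracles.
fake_report <- function(output, T, components = NULL, S_resid = 0, n = 100) {
  structure(
    list(
      output_id = output, condition_id = NULL, sigma2 = 1,
      components = components %||% tibble::tibble(
        id = names(T), order = 1L, vars = as.list(names(T)), S = unname(T)
      ),
      S_resid = S_resid, T = T,
      order_totals = c(order1 = sum(T), order2 = 0, order3 = 0),
      n = n, attribution = "test"
    ),
    class = "hdmr_sensitivity"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
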