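# Data-adaptive orthonormal polynomial bases. For each input variable the
# monomials x, x^2, ... are orthonormalized against the constant under the
# empirical inner product <f, g> = (1/n) sum f(x_t) g(x_t), i.e. Monte-Carlo
# integration over the sample measure. Component functions are weighted sums
# of these polynomials and, at higher order, of their tensor products.

RANK_TOL <- 1e-10

#' Build the orthonormal polynomial basis for one input variable
#'
#' Modified Gram-Schmidt (with one re-orthogonalization pass) of the
#' monomials against the constant, under the empirical sample measure. The
#' returned polynomials satisfy mean(phi_r) = 0, mean(phi_r^2) = 1 and
#' mean(phi_r phi_s) = 0 (r != s) over the training sample to near machine
#' precision. Sign convention: the leading coefficient of each polynomial is
#' positive.
#'
#' @param x Numeric vector of training samples for one variable.
#' @param degree Maximum polynomial degree k (>= 1).
#' @param variable_id Optional variable name stored with the basis.
#' @return An object of class `hdmr_basis`: a list with `variable_id`,
#'   `degree`, `coeffs` (degree x (degree+1) matrix; row r holds the
#'   coefficients of phi_r on 1, x, ..., x^degree) and `training_n`.
#' @export
build_orthonormal_basis <- function(x, degree, variable_id = NA_character_) {
  if (!is.numeric(x) || anyNA(x)) abort("`x` must be numeric with no missing values")
  if (degree < 1 || degree != round(degree)) abort("`degree` must be an integer >= 1")
  n <- length(x)
  n_distinct <- length(unique(x))
  if (var_pop(x) <= 0) {
    abort(sprintf(
      "zero-variance samples for variable '%s': cannot build a basis", variable_id
    ))
  }
  if (n_distinct < degree + 1) {
    abort(sprintf(
      "degree %d needs at least %d distinct values; variable '%s' has %d",
      degree, degree + 1, variable_id, n_distinct
    ))
  }
  d <- as.integer(degree)
  # monomial values: column j+1 is x^j
  M <- outer(x, 0:d, `^`)
  # coefficient rows in the monomial basis; row 1 is the constant
  C <- diag(d + 1)
  V <- M # V[, r] holds the sample values of basis r (pre/post orthogonalization)
  scale0 <- sqrt(pmax(colMeans(M^2), .Machine$double.eps))
  for (r in seq_len(d) + 1L) {
    for (pass in 1:2) {
      for (s in seq_len(r - 1L)) {
        proj <- mean(V[, r] * V[, s])
        V[, r] <- V[, r] - proj * V[, s]
        C[r, ] <- C[r, ] - proj * C[s, ]
      }
    }
    nrm <- sqrt(mean(V[, r]^2))
    if (nrm < RANK_TOL * scale0[r]) {
      abort(sprintf(
        "rank deficiency at degree %d for variable '%s': samples do not support the requested degree",
        r - 1L, variable_id
      ))
    }
    V[, r] <- V[, r] / nrm
    C[r, ] <- C[r, ] / nrm
    # sign convention: positive leading coefficient
    if (C[r, r] < 0) {
      C[r, ] <- -C[r, ]
      V[, r] <- -V[, r]
    }
  }
  structure(
    list(
      variable_id = variable_id,
      degree = d,
      coeffs = C[-1, , drop = FALSE],
      training_n = n
    ),
    class = "hdmr_basis"
  )
}

#' Evaluate the basis polynomials of one variable
#'
#' @param basis An `hdmr_basis`.
#' @param x Numeric vector of points.
#' @param degree Evaluate only the first `degree` polynomials (default: all).
#' @return A length(x) x degree matrix; column r holds phi_r(x).
#' @export
eval_basis <- function(basis, x, degree = basis$degree) {
  stopifnot(inherits(basis, "hdmr_basis"))
  if (degree > basis$degree) {
    abort(sprintf(
      "basis for '%s' was built to degree %d; degree %d requested",
      basis$variable_id, basis$degree, degree
    ))
  }
  M <- outer(x, 0:basis$degree, `^`)
  out <- M %*% t(basis$coeffs[seq_len(degree), , drop = FALSE])
  colnames(out) <- paste0(basis$variable_id, "_", seq_len(degree))
  out
}

#' @export
print.hdmr_basis <- function(x, ...) {
  cat(sprintf(
    "<hdmr_basis> variable '%s', degree %d, built on %d samples\n",
    x$variable_id, x$degree, x$training_n
  ))
  invisible(x)
}

# Deterministic enumeration of the degree tuples of one component function.
# Order 1 with degrees k: r = 1..k. Order 2 with degrees (l, l'): pairs
# (p, q), p over the first variable, q over the second, q varying fastest.
# Order 3: triples (p, q, r), r fastest, then q, then p.
term_degree_grid <- function(degrees) {
  grids <- lapply(rev(degrees), seq_len)
  g <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  as.matrix(g[, rev(seq_along(degrees)), drop = FALSE])
}

#' Evaluate the basis-product terms of one component function
#'
#' Order-1 components use the variable's basis polynomials directly; order-2
#' and order-3 components use all tensor products of the factors' bases, in
#' a deterministic enumeration (last factor's degree index varying fastest).
#'
#' @param bases Named list of `hdmr_basis`, one per variable.
#' @param vars Character vector of 1-3 variable names.
#' @param degrees Integer vector, per-factor maximum degrees (same length as
#'   `vars`).
#' @param data Data frame (or named list) holding the variables' values on
#'   the normalized scale.
#' @return An n x n_terms matrix of basis-product values, with term labels
#'   as column names.
#' @export
evaluate_terms <- function(bases, vars, degrees, data) {
  order <- length(vars)
  if (!order %in% 1:3) abort("component order must be 1, 2, or 3")
  if (length(degrees) != order) abort("`degrees` must match `vars` in length")
  missing <- setdiff(vars, names(bases))
  if (length(missing) > 0) {
    abort(sprintf("no basis for variable%s %s",
                  if (length(missing) > 1) "s" else "",
                  paste0("'", missing, "'", collapse = ", ")))
  }
  phi <- lapply(seq_len(order), function(i) {
    eval_basis(bases[[vars[i]]], data[[vars[i]]], degrees[i])
  })
  if (order == 1) return(phi[[1]])
  grid <- term_degree_grid(degrees)
  out <- matrix(1, nrow = nrow(phi[[1]]), ncol = nrow(grid))
  labels <- character(nrow(grid))
  for (t in seq_len(nrow(grid))) {
    for (i in seq_len(order)) {
      out[, t] <- out[, t] * phi[[i]][, grid[t, i]]
    }
    labels[t] <- paste(paste0(vars, "_", grid[t, ]), collapse = ":")
  }
  colnames(out) <- labels
  out
}

#' Serialize a basis set to JSON
#'
#' @param bases A named list of `hdmr_basis` objects (or a single one).
#' @return A JSON string (variable_id, degree, coefficient rows, training_n).
#' @export
basis_to_json <- function(bases) {
  if (inherits(bases, "hdmr_basis")) bases <- list(bases)
  payload <- lapply(bases, function(b) {
    list(
      variable_id = b$variable_id,
      degree = b$degree,
      coeffs = apply(b$coeffs, 1, identity, simplify = FALSE),
      training_n = b$training_n
    )
  })
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(17))
}

#' Restore a basis set from JSON
#'
#' @param json A JSON string produced by [basis_to_json()].
#' @return A named list of `hdmr_basis` objects.
#' @export
basis_from_json <- function(json) {
  payload <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  out <- lapply(payload, function(b) {
    coeffs <- do.call(rbind, lapply(b$coeffs, unlist))
    structure(
      list(
        variable_id = b$variable_id,
        degree = as.integer(b$degree),
        coeffs = coeffs,
        training_n = as.integer(b$training_n)
      ),
      class = "hdmr_basis"
    )
  })
  names(out) <- vapply(out, function(b) b$variable_id, character(1))
  out
}
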