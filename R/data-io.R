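# Condition tables: delimited text, header row of node names, one row per
# sample (cell). Normalization, pairwise-comparison construction, and the
# noise / resampling robustness protocols.

# Run code with a private RNG stream, restoring the caller's stream after.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

detect_delim <- function(line) {
  if (grepl("\t", line)) "\t" else ","
}

#' Read one condition's samples-by-nodes table
#'
#' Reads a delimited text file (comma or tab, auto-detected) whose header row
#' names the network nodes and whose body holds one numeric row per sample.
#'
#' @param path Path to a CSV/TSV file.
#' @param condition_id Optional label for the experimental condition; stored
#'   as an attribute and carried through the pipeline.
#' @return A tibble of samples by nodes with attributes `condition_id`,
#'   `normalized = FALSE` and the detected delimiter.
#' @export
read_condition_table <- function(path, condition_id = NULL) {
  if (!file.exists(path)) abort(sprintf("file '%s' does not exist", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("parse error in '%s': file is empty", path))
  delim <- detect_delim(lines[[1]])
  header <- strsplit(lines[[1]], delim, fixed = TRUE)[[1]]
  header <- trimws(header)
  if (all(!is.na(suppressWarnings(as.numeric(header))))) {
    abort(sprintf("parse error in '%s': header row of node names is missing", path))
  }
  dup <- header[duplicated(header)]
  if (length(dup) > 0) {
    abort(sprintf(
      "parse error in '%s': duplicate node name%s %s",
      path, if (length(dup) > 1) "s" else "",
      paste0("'", unique(dup), "'", collapse = ", ")
    ))
  }
  if (length(lines) < 2) {
    abort(sprintf("parse error in '%s': no data rows below the header", path))
  }
  body <- strsplit(lines[-1], delim, fixed = TRUE)
  n_col <- length(header)
  vals <- matrix(NA_real_, nrow = length(body), ncol = n_col)
  for (i in seq_along(body)) {
    row <- trimws(body[[i]])
    if (length(row) != n_col) {
      abort(sprintf(
        "parse error in '%s': row %d has %d fields, expected %d",
        path, i, length(row), n_col
      ))
    }
    num <- suppressWarnings(as.numeric(row))
    if (anyNA(num)) {
      j <- which(is.na(num))[1]
      abort(sprintf(
        "parse error in '%s': non-numeric value '%s' at row %d, column '%s'",
        path, row[j], i, header[j]
      ))
    }
    vals[i, ] <- num
  }
  out <- as_tibble(as.data.frame(vals))
  names(out) <- header
  attr(out, "condition_id") <- condition_id %||% basename(path)
  attr(out, "normalized") <- FALSE
  attr(out, "delim") <- delim
  out
}

#' Write a condition table
#'
#' Writes in the same dialect (delimiter) the table was read with, defaulting
#' to comma.
#'
#' @param x A samples-by-nodes data frame.
#' @param path Output file path.
#' @param delim Field delimiter; `NULL` reuses the delimiter recorded when
#'   the table was read.
#' @return `path`, invisibly.
#' @export
write_condition_table <- function(x, path, delim = NULL) {
  assert_data_frame(x)
  delim <- delim %||% attr(x, "delim") %||% ","
  readr::write_delim(as_tibble(x), path, delim = delim)
  invisible(path)
}

#' Rescale every node linearly onto the unit interval
#'
#' Each column is mapped by its own (min, max) onto \[0, 1\]. The per-node
#' ranges are stored so that new points (test sets, prediction inputs) can be
#' mapped with the identical transform via [apply_normalization()].
#'
#' @param x A samples-by-nodes data frame, not yet normalized.
#' @return The rescaled tibble with attributes `normalized = TRUE` and
#'   `hdmr_norm` (a tibble of node, min, max).
#' @export
normalize_unit_interval <- function(x) {
  assert_data_frame(x)
  if (isTRUE(attr(x, "normalized"))) {
    abort("table is already normalized")
  }
  out <- as_tibble(x)
  mins <- vapply(out, min, numeric(1))
  maxs <- vapply(out, max, numeric(1))
  constant <- maxs - mins <= 0
  if (any(constant)) {
    abort(sprintf(
      "zero-variance node%s %s: constant columns cannot support a basis",
      if (sum(constant) > 1) "s" else "",
      paste0("'", names(out)[constant], "'", collapse = ", ")
    ))
  }
  for (j in seq_along(out)) {
    out[[j]] <- (out[[j]] - mins[j]) / (maxs[j] - mins[j])
  }
  norm <- tibble(node = names(out), min = unname(mins), max = unname(maxs))
  attr(out, "condition_id") <- attr(x, "condition_id")
  attr(out, "pairwise") <- attr(x, "pairwise")
  attr(out, "normalized") <- TRUE
  attr(out, "hdmr_norm") <- norm
  out
}

#' Map new data through a stored normalization transform
#'
#' Applies the frozen per-node (min, max) ranges from a training table.
#' Values falling outside the training range are clamped to \[0, 1\] with a
#' warning (the expansion is only defined on the sampled range).
#'
#' @param x A samples-by-nodes data frame on the original scale.
#' @param norm A normalization transform, e.g. `attr(train, "hdmr_norm")`.
#' @param clamp Clamp out-of-range values to \[0, 1\]? Default `TRUE`.
#' @return The mapped tibble, `normalized = TRUE`.
#' @export
apply_normalization <- function(x, norm, clamp = TRUE) {
  assert_data_frame(x)
  out <- as_tibble(x)
  n_clamped <- 0L
  for (i in seq_len(nrow(norm))) {
    nd <- norm$node[i]
    if (!nd %in% names(out)) next
    v <- (out[[nd]] - norm$min[i]) / (norm$max[i] - norm$min[i])
    if (clamp) {
      oob <- v < 0 | v > 1
      n_clamped <- n_clamped + sum(oob)
      v <- pmin(pmax(v, 0), 1)
    }
    out[[nd]] <- v
  }
  if (n_clamped > 0) {
    warn(sprintf(
      "%d value%s outside the training range were clamped to [0, 1]",
      n_clamped, if (n_clamped > 1) "s" else ""
    ))
  }
  attr(out, "normalized") <- TRUE
  attr(out, "hdmr_norm") <- norm
  out
}

#' Invert a unit-interval normalization
#'
#' @param x A normalized samples-by-nodes data frame.
#' @param norm The stored transform (defaults to the table's own).
#' @return A tibble on the original measurement scale.
#' @export
denormalize <- function(x, norm = attr(x, "hdmr_norm")) {
  assert_data_frame(x)
  if (is.null(norm)) abort("no stored normalization transform to invert")
  out <- as_tibble(x)
  for (i in seq_len(nrow(norm))) {
    nd <- norm$node[i]
    if (!nd %in% names(out)) next
    out[[nd]] <- norm$min[i] + out[[nd]] * (norm$max[i] - norm$min[i])
  }
  attr(out, "normalized") <- FALSE
  attr(out, "hdmr_norm") <- NULL
  out
}

#' Build a pairwise-comparison dataset from a control and a perturbed condition
#'
#' Concatenates the two tables and overwrites the perturbed node's column
#' with Boolean class labels reflecting the exogenous perturbation: for an
#' activating cue the control rows get 0 (low) and the perturbed rows 1
#' (high); for an inhibiting cue the perturbed rows get 0 and the control
#' rows 1, since inhibition drives the target low.
#'
#' @param control,perturbed Condition tables sharing identical node names.
#' @param node The experimentally targeted node.
#' @param direction `"activated"` or `"inhibited"`.
#' @return A tibble with the perturbed node's column equal to the class
#'   labels, plus attributes `pairwise` (node, direction) and `class_labels`.
#' @export
make_pairwise <- function(control, perturbed, node,
                          direction = c("activated", "inhibited")) {
  direction <- match.arg(direction)
  assert_data_frame(control, "control")
  assert_data_frame(perturbed, "perturbed")
  if (!setequal(names(control), names(perturbed))) {
    abort("control and perturbed tables must share identical node names")
  }
  assert_nodes_present(control, node, "control")
  perturbed <- as_tibble(perturbed)[names(control)]
  n_ctrl <- nrow(control)
  n_pert <- nrow(perturbed)
  out <- bind_rows(as_tibble(control), perturbed)
  labels <- if (direction == "activated") {
    c(rep(0, n_ctrl), rep(1, n_pert))
  } else {
    c(rep(1, n_ctrl), rep(0, n_pert))
  }
  out[[node]] <- labels
  attr(out, "pairwise") <- list(node = node, direction = direction)
  attr(out, "class_labels") <- labels
  attr(out, "condition_id") <- paste0(
    attr(control, "condition_id") %||% "control", "_vs_",
    attr(perturbed, "condition_id") %||% direction
  )
  attr(out, "normalized") <- FALSE
  out
}

#' Randomly partition samples into a training and a test set
#'
#' @param x A samples-by-nodes data frame.
#' @param fraction Fraction of rows assigned to the training set, in (0, 1).
#' @param seed Integer seed; the same seed reproduces the same partition.
#' @return A list with elements `train` and `test`, disjoint row subsets
#'   whose union is the input.
#' @export
split_train_test <- function(x, fraction, seed) {
  assert_data_frame(x)
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction >= 1) {
    abort("`fraction` must lie strictly between 0 and 1")
  }
  n <- nrow(x)
  n_train <- round(fraction * n)
  if (n_train < 2 || n - n_train < 2) {
    abort("partition would leave fewer than 2 rows in train or test")
  }
  idx <- with_seed(seed, sample.int(n, n_train))
  x <- as_tibble(x)
  list(train = x[sort(idx), ], test = x[-sort(idx), ])
}

#' Perturb a table with Gaussian measurement noise
#'
#' Additive mode replaces each value m by m + eta with
#' eta ~ N(0, (scale * s_j)^2), s_j being column j's sample standard
#' deviation, so the noise level tracks each node's natural spread.
#' Multiplicative mode replaces m by m * (1 + eta), eta ~ N(0, scale^2).
#'
#' @param x A samples-by-nodes data frame.
#' @param mode `"additive"` or `"multiplicative"`.
#' @param scale Dimensionless noise fraction c, >= 0.
#' @param seed Integer seed for reproducibility.
#' @return The perturbed tibble.
#' @export
add_noise <- function(x, mode = c("additive", "multiplicative"), scale, seed) {
  mode <- match.arg(mode)
  assert_data_frame(x)
  if (!is.numeric(scale) || scale < 0) abort("`scale` must be >= 0")
  out <- as_tibble(x)
  if (scale == 0) return(out)
  n <- nrow(out)
  with_seed(seed, {
    for (j in seq_along(out)) {
      if (mode == "additive") {
        out[[j]] <- out[[j]] + rnorm(n, 0, scale * sd(out[[j]]))
      } else {
        out[[j]] <- out[[j]] * (1 + rnorm(n, 0, scale))
      }
    }
  })
  out
}

#' Subsample or jitter-oversample a table
#'
#' Subsampling draws `round(factor * n)` rows without replacement (the 25%
#' truncation robustness protocol). Oversampling replicates each row `factor`
#' times, adding independent N(0, jitter_sd^2) jitter to every replicated
#' value so the original row is the centroid of its replicates.
#'
#' @param x A samples-by-nodes data frame.
#' @param mode `"subsample"` or `"oversample"`.
#' @param factor Subsample fraction in (0, 1\] or positive integer
#'   replication factor.
#' @param jitter_sd Jitter standard deviation for oversampling (original
#'   units). Default 0.
#' @param seed Integer seed.
#' @return The resampled tibble.
#' @export
resample_table <- function(x, mode = c("subsample", "oversample"), factor,
                           jitter_sd = 0, seed = 1L) {
  mode <- match.arg(mode)
  assert_data_frame(x)
  x <- as_tibble(x)
  n <- nrow(x)
  if (mode == "subsample") {
    if (!is.numeric(factor) || factor <= 0 || factor > 1) {
      abort("subsample `factor` must lie in (0, 1]")
    }
    k <- round(factor * n)
    if (k < 1) abort("subsample would retain no rows")
    idx <- with_seed(seed, sample.int(n, k))
    return(x[sort(idx), ])
  }
  if (!is.numeric(factor) || factor < 1 || factor != round(factor)) {
    abort("oversample `factor` must be a positive integer")
  }
  factor <- as.integer(factor)
  idx <- rep(seq_len(n), each = factor)
  out <- x[idx, ]
  if (jitter_sd > 0) {
    with_seed(seed, {
      for (j in seq_along(out)) {
        out[[j]] <- out[[j]] + rnorm(nrow(out), 0, jitter_sd)
      }
    })
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
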