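test_that("condition tables round-trip through disk", {
  tab <- tibble::tibble(A = c(1.5, 2.5), B = c(3, 4.25))
  path <- withr::local_tempfile(fileext = ".csv")
  write_condition_table(tab, path)
  back <- read_condition_table(path, condition_id = "c1")
  expect_equal(as.data.frame(back), as.data.frame(tab), ignore_attr = TRUE)
  expect_identical(attr(back, "condition_id"), "c1")
  expect_false(attr(back, "normalized"))

  # tab-delimited dialect is detected and reused on write
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "1\t2", "3\t4"), path2)
  tsv <- read_condition_table(path2)
  expect_equal(tsv$B, c(2, 4))
  path3 <- withr::local_tempfile(fileext = ".tsv")
  write_condition_table(tsv, path3)
  expect_match(readLines(path3)[1], "A\tB")
})

test_that("an eleven-node signaling panel reads with all nodes", {
  nodes <- c("Akt", "Jnk", "Raf", "Erk", "p38", "Mek", "PKA", "PLCg",
             "PKC", "PIP2", "PIP3")
  set.seed(4)
  tab <- stats::setNames(as.data.frame(matrix(rexp(5 * 11), 5)), nodes)
  path <- withr::local_tempfile(fileext = ".csv")
  write_condition_table(tab, path)
  back <- read_condition_table(path)
  expect_identical(ncol(back), 11L)
  expect_identical(names(back), nodes)
})

test_that("malformed files raise parse errors naming the location", {
  empty <- withr::local_tempfile(fileext = ".csv")
  file.create(empty)
  expect_error(read_condition_table(empty), "empty")

  noheader <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1,2", "3,4"), noheader)
  expect_error(read_condition_table(noheader), "header")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("A,A", "1,2"), dup)
  expect_error(read_condition_table(dup), "duplicate")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("A,B", "1,2", "3,oops"), bad)
  expect_error(read_condition_table(bad), "row 2, column 'B'")

  headonly <- withr::local_tempfile(fileext = ".csv")
  writeLines("A,B", headonly)
  expect_error(read_condition_table(headonly), "no data rows")
})

test_that("normalization rescales each node onto [0,1] and is invertible", {
  tab <- tibble::tibble(a = c(0, 5, 10), b = c(0.2, 0.9, 0.5))
  norm <- normalize_unit_interval(tab)
  expect_equal(norm$a, c(0, 0.5, 1))
  expect_true(isTRUE(attr(norm, "normalized")))
  # a column already spanning [0,1] is unchanged
  tab2 <- tibble::tibble(u = c(0, 0.25, 1))
  expect_equal(normalize_unit_interval(tab2)$u, tab2$u)
  # invertible through the stored transform
  back <- denormalize(norm)
  expect_equal(back$a, tab$a, tolerance = 1e-12)
  expect_equal(back$b, tab$b, tolerance = 1e-12)
  # double normalization is refused
  expect_error(normalize_unit_interval(norm), "already normalized")
})

test_that("zero-variance nodes are rejected by name", {
  tab <- tibble::tibble(ok = c(1, 2, 3), Mek = c(3, 3, 3))
  expect_error(normalize_unit_interval(tab), "'Mek'")
})

test_that("stored transforms map and clamp new points", {
  train <- tibble::tibble(a = c(0, 10))
  norm <- attr(normalize_unit_interval(train), "hdmr_norm")
  new <- tibble::tibble(a = c(-5, 5, 15))
  expect_warning(out <- apply_normalization(new, norm), "clamped")
  expect_equal(out$a, c(0, 0.5, 1))
})

test_that("pairwise construction overwrites the perturbed node with labels", {
  set.seed(11)
  ctrl <- tibble::tibble(PKA = runif(6), Erk = runif(6))
  pert <- tibble::tibble(PKA = runif(4) + 3, Erk = runif(4))
  pw <- make_pairwise(ctrl, pert, "PKA", "activated")
  expect_equal(nrow(pw), 10)
  expect_equal(pw$PKA, c(rep(0, 6), rep(1, 4)))
  expect_equal(attr(pw, "class_labels"), pw$PKA)
  # inhibition swaps the label roles: perturbed rows are low
  pwi <- make_pairwise(ctrl, pert, "PKA", "inhibited")
  expect_equal(pwi$PKA, c(rep(1, 6), rep(0, 4)))
  # class counts equal the input tables' row counts exactly
  expect_equal(unname(table(pw$PKA)), c(6L, 4L), ignore_attr = TRUE)
  # same table twice gives 2n rows, n per class
  pw2 <- make_pairwise(ctrl, ctrl, "PKA", "activated")
  expect_equal(nrow(pw2), 12)
  expect_equal(sum(pw2$PKA == 1), 6)
  expect_error(make_pairwise(ctrl, pert, "XYZ", "activated"), "XYZ")
  expect_error(
    make_pairwise(ctrl, tibble::tibble(PKA = 1:3, Jnk = 1:3), "PKA"),
    "identical node names"
  )
})

test_that("train/test splits partition rows deterministically", {
  tab <- tibble::tibble(a = 1:10, b = 10:1)
  sp <- split_train_test(tab, 0.7, seed = 42)
  expect_equal(nrow(sp$train), 7)
  expect_equal(nrow(sp$test), 3)
  # brute-force set arithmetic: disjoint and exhaustive
  expect_length(intersect(sp$train$a, sp$test$a), 0)
  expect_setequal(c(sp$train$a, sp$test$a), tab$a)
  sp2 <- split_train_test(tab, 0.7, seed = 42)
  expect_identical(sp, sp2)
  expect_error(split_train_test(tab, 1.0, seed = 1), "between 0 and 1")
  expect_error(split_train_test(tab, 0.95, seed = 1), "fewer than 2")
})

test_that("additive noise follows the per-node scaled normal distribution", {
  set.seed(9)
  tab <- tibble::tibble(a = rnorm(1e5, 10, 2), b = runif(1e5))
  noisy <- add_noise(tab, "additive", scale = 0.1, seed = 7)
  for (j in c("a", "b")) {
    expect_equal(sd(noisy[[j]] - tab[[j]]), 0.1 * sd(tab[[j]]),
                 tolerance = 0.05)
  }
  # zero noise is the identity, any mode
  expect_identical(add_noise(tab, "additive", 0, seed = 1), tab)
  expect_identical(add_noise(tab, "multiplicative", 0, seed = 1), tab)
  # multiplicative noise is relative to the value itself
  m <- add_noise(tab, "multiplicative", scale = 0.05, seed = 3)
  expect_equal(sd(m$a / tab$a - 1), 0.05, tolerance = 0.05)
  # bitwise reproducible under the same seed
  expect_identical(add_noise(tab, "additive", 0.1, seed = 7), noisy)
})

test_that("resampling implements the subsample and oversample protocols", {
  set.seed(5)
  tab <- tibble::tibble(a = runif(400), b = runif(400))
  sub <- resample_table(tab, "subsample", 0.25, seed = 2)
  expect_equal(nrow(sub), 100)
  expect_true(all(sub$a %in% tab$a))
  over <- resample_table(tibble::tibble(a = runif(95)), "oversample", 10,
                         jitter_sd = 0.01, seed = 2)
  expect_equal(nrow(over), 950)
  # identity at factor 1 with no jitter
  expect_equal(as.data.frame(resample_table(tab, "oversample", 1, 0, 1)),
               as.data.frame(tab))
  # jittered replicates have the original row as centroid (in expectation)
  one <- tibble::tibble(a = 0.5)
  reps <- resample_table(one, "oversample", 2000, jitter_sd = 0.05, seed = 8)
  expect_equal(mean(reps$a), 0.5, tolerance = 0.005)
  expect_error(resample_table(tab, "subsample", 1.5, seed = 1), "factor")
  expect_error(resample_table(tab, "oversample", 2.5, seed = 1), "integer")
})
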