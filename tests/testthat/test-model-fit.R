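test_that("candidate enumeration matches binomial counts", {
  expect_equal(nrow(enumerate_candidates(c("a", "b", "c"), 1)), 3)
  ten <- paste0("n", sprintf("%02d", 1:10))
  # exhaustive order 2: 10 + choose(10, 2)
  expect_equal(nrow(enumerate_candidates(ten, 2, "exhaustive")), 10 + 45)
  # hierarchical with 3 significant first-order inputs: 10 + choose(3, 2)
  hier <- enumerate_candidates(ten, 2, "hierarchical",
                               selected_first_order = ten[1:3])
  expect_equal(nrow(hier), 13)
  # deterministic lexicographic ordering
  expect_identical(hier$id[1:3], c("n01", "n02", "n03"))
  expect_identical(hier$id[11], "n01:n02")
  ex3 <- enumerate_candidates(ten, 3, "exhaustive")
  expect_equal(nrow(ex3), 10 + 45 + choose(10, 3))
})

test_that("least squares recovers generating coefficients exactly", {
  set.seed(41)
  d <- runif_table(800, c("x1", "x2"))
  bases <- lapply(names(d), function(v) build_orthonormal_basis(d[[v]], 3, v))
  names(bases) <- names(d)
  sel <- tibble::tibble(order = c(1L, 1L, 2L),
                        vars = list("x1", "x2", c("x1", "x2")))
  degrees <- c(k = 3L, l = 2L, m = 1L)
  T1 <- evaluate_terms(bases, "x1", 3, d)
  T2 <- evaluate_terms(bases, "x2", 3, d)
  T12 <- evaluate_terms(bases, c("x1", "x2"), c(2, 2), d)
  w_true <- list(c(1.0, -0.3, 0.2), c(0.7, 0, 0.1), c(0.5, 0, 0, -0.2))
  d$y <- 0.4 + drop(T1 %*% w_true[[1]] + T2 %*% w_true[[2]] +
                      T12 %*% w_true[[3]])
  d <- as_norm(d)
  m <- fit_least_squares(d, "y", sel, bases, degrees)
  for (i in 1:3) expect_equal(m$components$weights[[i]], w_true[[i]],
                              tolerance = 1e-6)
  expect_lt(m$residual_variance, 1e-12)
  # training mean of (prediction - observation) vanishes
  expect_lt(abs(mean(predict(m, d, scale = "normalized") - d$y)), 1e-8)
})

test_that("least squares equals the brute-force normal equations", {
  set.seed(43)
  d <- runif_table(50, c("x1", "x2"))
  d$y <- rnorm(50)
  d <- as_norm(d)
  bases <- lapply(c("x1", "x2"), function(v) {
    build_orthonormal_basis(d[[v]], 3, v)
  })
  names(bases) <- c("x1", "x2")
  sel <- tibble::tibble(order = c(1L, 1L), vars = list("x1", "x2"))
  m <- fit_least_squares(d, "y", sel, bases)
  # oracle: solve the normal equations directly on centered columns
  X <- cbind(evaluate_terms(bases, "x1", 3, d),
             evaluate_terms(bases, "x2", 3, d))
  Xc <- sweep(X, 2, colMeans(X))
  beta <- solve(crossprod(Xc), crossprod(Xc, d$y - mean(d$y)))
  expect_equal(unlist(m$components$weights), drop(beta), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("a constant output collapses to its mean", {
  d <- runif_table(60, "x1")
  d$y <- rep(2.5, 60)
  d <- as_norm(d)
  bases <- list(x1 = build_orthonormal_basis(d$x1, 3, "x1"))
  sel <- tibble::tibble(order = 1L, vars = list("x1"))
  m <- fit_least_squares(d, "y", sel, bases)
  expect_equal(m$f0, 2.5)
  expect_equal(m$components$weights[[1]], rep(0, 3), tolerance = 1e-10)
  expect_lt(m$residual_variance, 1e-20)
})

test_that("rank-deficient designs are refused with the collinear terms named", {
  d <- runif_table(50, "x1")
  d$x2 <- d$x1 # duplicate input
  d$y <- d$x1 + rnorm(50, 0, 0.1)
  d <- as_norm(d)
  bases <- lapply(c("x1", "x2"), function(v) {
    build_orthonormal_basis(d[[v]], 2, v)
  })
  names(bases) <- c("x1", "x2")
  sel <- tibble::tibble(order = c(1L, 1L), vars = list("x1", "x2"))
  expect_error(fit_least_squares(d, "y", sel, bases, c(k = 2, l = 2, m = 1)),
               "collinear")
})

test_that("F-test selection keeps real effects and honours its limits", {
  set.seed(47)
  d <- runif_table(1000, c("x1", "x2", "x3"))
  d$y <- legendre1(d$x1) # exact first-order signal, no noise on x1 path
  d <- as_norm(d)
  bases <- lapply(c("x1", "x2", "x3"), function(v) {
    build_orthonormal_basis(d[[v]], 3, v)
  })
  names(bases) <- c("x1", "x2", "x3")
  cand <- enumerate_candidates(c("x1", "x2", "x3"), 1)
  sel <- f_test_select(d, "y", cand, bases, alpha = 0.01)
  expect_true("x1" %in% sel$selected$id)
  expect_equal(nrow(sel$log), 3)
  # alpha near 1 admits everything testable against leftover noise
  d$y2 <- legendre1(d$x1) + rnorm(1000, 0, 0.5)
  sel_all <- f_test_select(d, "y2", cand, bases, alpha = 0.999999)
  expect_equal(sum(sel_all$log$included), 3)
  # vanishing residual degrees of freedom is an explicit error
  tiny <- as_norm(runif_table(4, c("x1", "x2", "x3")))
  tiny$y <- runif(4)
  tiny_b <- lapply(c("x1", "x2", "x3"), function(v) {
    build_orthonormal_basis(tiny[[v]], 3, v)
  })
  names(tiny_b) <- c("x1", "x2", "x3")
  expect_error(f_test_select(tiny, "y", cand, tiny_b, alpha = 0.01),
               "more samples")
})

test_that("fit_hdmr orchestrates the stages deterministically", {
  spec <- make_benchmark_spec("additive", seed = 5)
  d <- sample_synthetic(spec, 600)
  m1 <- fit_hdmr(d, "y", max_order = 2)
  m2 <- fit_hdmr(d, "y", max_order = 2)
  expect_identical(as.character(model_to_json(m1)),
                   as.character(model_to_json(m2)))
  # f0 is the sample mean of the (normalized) output
  dn <- normalize_unit_interval(d)
  expect_lt(abs(m1$f0 - mean(dn$y)), 1e-10)
  # components unique by (order, vars)
  expect_false(any(duplicated(m1$components$id)))
  # every tested candidate is logged with its F statistic and p value
  expect_true(all(c("F_statistic", "p_value", "included") %in%
                    names(m1$selection_log)))
  expect_error(fit_hdmr(d[1:3, ], "y"), "distinct values|more samples")
})

test_that("selected components never increase the training RSS", {
  spec <- make_benchmark_spec("cooperative", seed = 6)
  d <- normalize_unit_interval(sample_synthetic(spec, 800))
  m <- fit_hdmr(d, "y", max_order = 2)
  lg <- m$selection_log[m$selection_log$included, ]
  # included candidates all have positive F (a positive RSS reduction)
  expect_true(all(lg$F_statistic > 0))
  # full model residual variance is below the output variance
  expect_lt(m$residual_variance, var(d$y))
})

test_that("prediction equals the term-by-term summation oracle", {
  spec <- make_benchmark_spec("cooperative", seed = 8)
  d <- sample_synthetic(spec, 700)
  m <- fit_hdmr(d, "y", max_order = 2)
  dn <- suppressWarnings(apply_normalization(d, m$norm))
  pred <- predict(m, d, scale = "normalized")
  # oracle: explicit loop over components and terms
  manual <- rep(m$f0, nrow(d))
  for (i in seq_len(nrow(m$components))) {
    Tm <- evaluate_terms(m$bases, m$components$vars[[i]],
                         m$components$degrees[[i]], dn)
    Tm <- sweep(Tm, 2, m$components$term_means[[i]])
    manual <- manual + drop(Tm %*% m$components$weights[[i]])
  }
  expect_equal(pred, manual, tolerance = 1e-10)
  # original-scale predictions are the denormalized expansion
  row <- m$norm[m$norm$node == "y", ]
  expect_equal(predict(m, d), row$min + pred * (row$max - row$min),
               tolerance = 1e-10)
})

test_that("prediction handles boundary and degenerate cases", {
  spec <- make_benchmark_spec("additive", seed = 9)
  d <- sample_synthetic(spec, 500)
  m <- fit_hdmr(d, "y", max_order = 1)
  # out-of-range inputs are clamped with a warning, prediction stays finite
  far <- d[1:3, ]
  far$x1 <- c(-10, 5, 100)
  expect_warning(p <- predict(m, far), "clamped")
  expect_true(all(is.finite(p)))
  expect_error(predict(m, d[, c("x4", "x5", "y")]), "missing required input")
  # zero-component model predicts f0 everywhere
  null_d <- runif_table(300, c("a", "b", "y"), seed = 10)
  mn <- fit_hdmr(null_d, "y", alpha = 1e-6, max_order = 1)
  if (nrow(mn$components) == 0) {
    expect_equal(unique(predict(mn, null_d, scale = "normalized")), mn$f0)
  }
})

test_that("models survive a JSON round trip", {
  spec <- make_benchmark_spec("cooperative", seed = 12)
  d <- sample_synthetic(spec, 500)
  m <- fit_hdmr(d, "y", max_order = 2)
  path <- withr::local_tempfile(fileext = ".json")
  model_to_json(m, path)
  back <- model_from_json(path)
  expect_equal(predict(back, d), predict(m, d), tolerance = 1e-12)
  expect_equal(back$f0, m$f0)
  expect_equal(back$components$weights, m$components$weights)
})

test_that("noiseless expansions are recovered once n exceeds 10x terms", {
  set.seed(53)
  d <- runif_table(200, c("x1", "x2"))
  d$y <- 0.2 + 0.8 * legendre1(d$x1) + 0.3 * legendre2(d$x2)
  d <- as_norm(d)
  m <- fit_hdmr(d, "y", max_order = 1)
  expect_lt(m$residual_variance, 1e-12)
  fresh <- runif_table(100, c("x1", "x2"), seed = 99)
  truth <- 0.2 + 0.8 * legendre1(fresh$x1) + 0.3 * legendre2(fresh$x2)
  expect_equal(predict(m, as_norm(fresh), scale = "normalized"), truth,
               tolerance = 1e-6)
})
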