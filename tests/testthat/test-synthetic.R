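test_that("presets define the documented generating structures", {
  add <- make_benchmark_spec("additive", seed = 1)
  expect_true(all(vapply(add$truth$y$vars, length, integer(1)) == 1))
  coop <- make_benchmark_spec("cooperative", seed = 1)
  expect_true(any(vapply(coop$truth$y$vars, length, integer(1)) == 2))
  chain <- make_benchmark_spec("indirect-chain", seed = 1)
  # the source has zero direct weight on the output
  expect_false("x1" %in% unlist(chain$truth$y$vars))
  expect_equal(nrow(chain$links), 1)
  chain_d <- make_benchmark_spec("indirect-chain", seed = 1,
                                 direct_link = TRUE)
  expect_true("x1" %in% unlist(chain_d$truth$y$vars))
  # identical preset + seed gives identical specs
  expect_identical(make_benchmark_spec("cooperative", seed = 9),
                   make_benchmark_spec("cooperative", seed = 9))
  expect_error(make_benchmark_spec("nonsense"), "arg")
  # declaring a chain whose source also acts directly is refused
  expect_error(
    synthetic_spec(
      nodes = c("a", "b", "y"),
      links = tibble::tibble(from = "a", to = "b", intercept = 0,
                             slope = 1, noise_sd = 0.1),
      truth = list(y = tibble::tibble(vars = list("a"), degrees = list(1L),
                                      weight = 1)),
      chains = list(c(source = "a", intermediate = "b", output = "y"))
    ),
    "zero direct weight"
  )
})

test_that("sampling is reproducible and respects degenerate settings", {
  spec <- make_benchmark_spec("additive", seed = 3)
  d1 <- sample_synthetic(spec, 100)
  d2 <- sample_synthetic(spec, 100)
  expect_equal(as.data.frame(d1), as.data.frame(d2))
  # zero weights and zero noise give a constant output at f0
  flat <- synthetic_spec(
    nodes = c("x1", "y"),
    truth = list(y = tibble::tibble(vars = list("x1"), degrees = list(1L),
                                    weight = 0)),
    f0 = c(y = 0.5), noise_sd = c(y = 0)
  )
  df <- sample_synthetic(flat, 50, seed = 2)
  expect_equal(df$y, rep(0.5, 50))
  expect_error(sample_synthetic(spec, 1), "at least 2")
})

test_that("independent-uniform inputs are empirically uncorrelated", {
  spec <- make_benchmark_spec("additive", seed = 5)
  d <- sample_synthetic(spec, 1e5)
  C <- cor(d[, paste0("x", 1:5)])
  expect_lt(max(abs(C[upper.tri(C)])), 0.01)
})

test_that("the Gaussian copula reproduces the requested dependence", {
  R <- matrix(c(1, 0.8, 0.8, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  spec <- synthetic_spec(nodes = c("a", "b"),
                         distribution = list(type = "gaussian-copula",
                                             corr = R))
  d <- sample_synthetic(spec, 2e4, seed = 11)
  # margins stay uniform
  expect_lt(abs(mean(d$a) - 0.5), 0.01)
  # oracle: Spearman's rho of a Gaussian copula is (6/pi) asin(rho/2)
  expect_equal(cor(d$a, d$b, method = "spearman"),
               (6 / pi) * asin(0.8 / 2), tolerance = 0.03)
  bad <- matrix(c(1, 2, 2, 1), 2, dimnames = dimnames(R))
  expect_error(
    synthetic_spec(nodes = c("a", "b"),
                   distribution = list(type = "gaussian-copula", corr = bad)),
    "semi-definite"
  )
})

test_that("perturbations shift the node and propagate downstream", {
  spec <- make_benchmark_spec("perturbation-pair", seed = 7)
  tabs <- sample_synthetic(spec, 2000)
  expect_named(tabs, c("control", "P_shifted"))
  expect_equal(mean(tabs$P_shifted$P) - mean(tabs$control$P), 2,
               tolerance = 0.05)
  # the downstream reporter moves by slope * shift
  expect_equal(mean(tabs$P_shifted$D) - mean(tabs$control$D), 0.8 * 2,
               tolerance = 0.05)
  # in the null preset the perturbed node is disconnected: D is unmoved
  null_spec <- make_benchmark_spec("perturbation-null", seed = 7)
  null_tabs <- sample_synthetic(null_spec, 2000)
  expect_lt(abs(mean(null_tabs$P_shifted$D) - mean(null_tabs$control$D)),
            0.05)
})

test_that("analytic indices follow the closed-form variance ratios", {
  # single unit-weight term, no noise: S = 1
  one <- synthetic_spec(
    nodes = c("u", "y"),
    truth = list(y = tibble::tibble(vars = list("u"), degrees = list(1L),
                                    weight = 1)),
    noise_sd = c(y = 0)
  )
  expect_equal(analytic_sensitivities(one)$components$S, 1)
  # y = 2 u1 + u2: weights (1/sqrt(3), 1/(2 sqrt(3))) on the linear basis
  two <- synthetic_spec(
    nodes = c("u1", "u2", "y"),
    truth = list(y = tibble::tibble(
      vars = list("u1", "u2"), degrees = list(1L, 1L),
      weight = c(1 / sqrt(3), 1 / (2 * sqrt(3)))
    )),
    f0 = c(y = 1.5), noise_sd = c(y = 0)
  )
  an <- analytic_sensitivities(two)
  expect_equal(an$components$S, c(0.8, 0.2), tolerance = 1e-12)
  expect_equal(unname(an$T$T), c(0.8, 0.2), tolerance = 1e-12)
  # noise variance equal to signal variance halves the summed indices
  half <- synthetic_spec(
    nodes = c("u", "y"),
    truth = list(y = tibble::tibble(vars = list("u"), degrees = list(1L),
                                    weight = 1)),
    noise_sd = c(y = 1)
  )
  an_half <- analytic_sensitivities(half)
  expect_equal(sum(an_half$components$S), 0.5)
  expect_equal(an_half$noise_index$S, 0.5)
  # closed forms are refused under correlated sampling
  chain <- make_benchmark_spec("indirect-chain", seed = 1)
  expect_error(analytic_sensitivities(chain), "unsupported|correlated")
})

test_that("specs serialize to JSON", {
  spec <- make_benchmark_spec("cooperative", seed = 13)
  path <- withr::local_tempfile(fileext = ".json")
  spec_to_json(spec, path)
  parsed <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_identical(parsed$format, "hdmrnet-synthetic-spec")
  expect_identical(unlist(parsed$nodes), spec$nodes)
  expect_equal(parsed$noise_sd$y, unname(spec$noise_sd["y"]))
})

test_that("end-to-end: fitted indices recover the analytic truth", {
  spec <- make_benchmark_spec("cooperative", seed = 15)
  d <- sample_synthetic(spec, 5000)
  m <- fit_hdmr(d, "y", max_order = 2)
  rep <- compute_sensitivities(m, d)
  an <- analytic_sensitivities(spec)
  est <- setNames(rep$components$S, rep$components$id)
  for (i in seq_len(nrow(an$components))) {
    expect_equal(unname(est[an$components$id[i]]), an$components$S[i],
                 tolerance = 0.05)
  }
  # exactly the true terms are selected in this run
  expect_setequal(rep$components$id, an$components$id)
})
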