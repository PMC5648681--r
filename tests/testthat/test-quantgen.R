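sim_nested <- function(vb, vm, vr, K = 8, S = 4, D = 4, seed = 1,
                       mu = 0, beta = 0) {
  set.seed(seed)
  pop <- rep(paste0("P", seq_len(K)), each = S * D)
  sire <- paste0(pop, "_s", rep(rep(seq_len(S), each = D), K))
  x <- rnorm(K * S * D, 50, 5)
  y <- mu + rep(rnorm(K, 0, sqrt(vb)), each = S * D) +
    rep(rnorm(K * S, 0, sqrt(vm)), each = D) +
    rnorm(K * S * D, 0, sqrt(vr)) + beta * (x - 50)
  data.frame(population = pop, sire_id = sire, y = y, x = x)
}

test_that("qst arithmetic follows the variance-ratio formula", {
  expect_equal(qst(variance_components(1, 0.25, 0.75)), 1 / 3)
  expect_equal(qst(list(V_b = 1, V_w = 1)), 1 / 3)
  expect_equal(qst(list(V_b = 0, V_w = 2)), 0)
  expect_equal(qst(list(V_b = 3, V_w = 0)), 1)
  expect_error(qst(list(V_b = 0, V_w = 0)), "undefined")
  expect_error(variance_components(-1, 0, 1), ">= 0")
})

test_that("qst is monotone in V_b and V_w", {
  vb <- seq(0.1, 5, length.out = 20)
  q1 <- vapply(vb, function(b) qst(list(V_b = b, V_w = 1)), numeric(1))
  expect_true(all(diff(q1) > 0))
  vw <- seq(0.1, 5, length.out = 20)
  q2 <- vapply(vw, function(w) qst(list(V_b = 1, V_w = w)), numeric(1))
  expect_true(all(diff(q2) < 0))
})

test_that("REML recovers configured variance components on average", {
  est <- t(vapply(1:40, function(s) {
    d <- sim_nested(1, 0.25, 0.75, seed = s)
    vc <- fit_nested_ranef(d, "y")
    c(vc$V_b, vc$V_male, vc$V_res)
  }, numeric(3)))
  m <- colMeans(est)
  expect_equal(m[1], 1, tolerance = 0.25)     # 8 populations: wide sampling
  expect_equal(m[2], 0.25, tolerance = 0.3)
  expect_equal(m[3], 0.75, tolerance = 0.1)
})

test_that("null data give near-zero population and sire components", {
  meds <- vapply(1:20, function(s) {
    d <- sim_nested(0, 0, 1, seed = 100 + s)
    vc <- fit_nested_ranef(d, "y")
    c(vc$V_b, vc$V_male) / vc$V_res
  }, numeric(2))
  expect_lt(median(meds[1, ]), 0.05)
  expect_lt(median(meds[2, ]), 0.05)
})

test_that("noise-free distinct population means put V_res at the boundary", {
  d <- sim_nested(0, 0, 0, seed = 1)
  d$y <- as.integer(factor(d$population)) * 2
  vc <- fit_nested_ranef(d, "y")
  expect_equal(vc$V_res, 0)
  expect_true(vc$boundary["V_res"])
  expect_gt(vc$V_b, 0)
})

test_that("degenerate all-identical observations are flagged", {
  d <- sim_nested(0, 0, 0, seed = 1)
  d$y <- 5
  vc <- fit_nested_ranef(d, "y")
  expect_true(vc$degenerate)
  expect_equal(vc$V_w, 0)
})

test_that("REML and method-of-moments agree on a large balanced design", {
  d <- sim_nested(1, 0.3, 1, K = 10, S = 6, D = 20, seed = 7)
  r <- fit_nested_ranef(d, "y")
  m <- fit_nested_ranef(d, "y", method = "moments")
  for (comp in c("V_b", "V_male", "V_res")) {
    expect_equal(r[[comp]], m[[comp]], tolerance = 0.05)
  }
})

test_that("a zero-slope covariate leaves the fit unchanged", {
  d <- sim_nested(1, 0.25, 0.75, seed = 11, beta = 0)
  v0 <- fit_nested_ranef(d, "y")
  v1 <- fit_nested_ranef(d, "y", covariate = "x")
  expect_equal(v1$V_b, v0$V_b, tolerance = 0.05)
  expect_equal(v1$V_res, v0$V_res, tolerance = 0.05)
  # and a real slope is removed by adjustment
  d2 <- sim_nested(1, 0.25, 0.75, seed = 11, beta = 0.5)
  v2 <- fit_nested_ranef(d2, "y", covariate = "x")
  expect_equal(v2$V_res, v0$V_res, tolerance = 0.1)
  # residualization mode agrees with in-model adjustment to first order
  v3 <- fit_nested_ranef(d2, "y", covariate = "x", adjust = "residualize")
  expect_equal(v3$V_res, v2$V_res, tolerance = 0.1)
})

test_that("pairwise Q_ST matrix is symmetric, zero-diagonal, near 0 or large as configured", {
  # identically simulated populations: median pairwise Q_ST small
  meds <- vapply(1:15, function(s) {
    d <- sim_nested(0, 0.25, 0.75, K = 2, S = 4, D = 8, seed = 200 + s)
    m <- pairwise_qst(d, "y")
    m[1, 2]
  }, numeric(1))
  expect_lt(median(meds), 0.05)
  # strongly diverged pair
  d <- sim_nested(0, 0.1, 0.2, K = 2, S = 4, D = 8, seed = 5)
  d$y <- d$y + ifelse(d$population == "P1", 0, 3 * sqrt(0.3))
  m <- pairwise_qst(d, "y")
  expect_gt(m[1, 2], 0.5)
  expect_equal(unclass(m), t(unclass(m)), ignore_attr = TRUE)
  expect_true(all(diag(m) == 0))
})
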