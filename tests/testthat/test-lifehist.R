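toy_groups <- function(seed = 1, k = 3, n = 8, delta = 0) {
  set.seed(seed)
  data.frame(population = rep(paste0("P", seq_len(k)), each = n),
             y = rnorm(k * n) + rep(delta * (seq_len(k) - 1), each = n))
}

test_that("sequential F matches the hand-computed one-way ANOVA", {
  d <- toy_groups(seed = 2, delta = 1)
  fit <- fit_trait_glm(d, "y")
  oracle <- oneway_F_oracle(d$y, d$population)
  expect_equal(fit$anova$F[1], oracle$F, tolerance = 1e-8)
  expect_equal(fit$anova$p[1], oracle$p, tolerance = 1e-8)
  expect_equal(fit$anova$df[1], oracle$df1)
  expect_equal(fit$anova$df_res[1], oracle$df2)
})

test_that("sequential sums of squares add to the total sum of squares", {
  set.seed(3)
  d <- toy_groups(seed = 3, delta = 0.5)
  d$x <- rnorm(nrow(d))
  d$y <- d$y + 0.3 * d$x
  fit <- fit_trait_glm(d, "y", "x", include_interaction = TRUE)
  at <- anova(fit$fit)
  expect_equal(sum(at$`Sum Sq`), sum((d$y - mean(d$y))^2),
               tolerance = 1e-8)
  # response identical to the covariate: once the covariate is in, the
  # population term explains (numerically) nothing
  d2 <- d; d2$y <- d2$x
  fit2 <- suppressWarnings(fit_trait_glm(d2, "y", "x"))
  at2 <- suppressWarnings(anova(fit2$fit))
  expect_lt(at2["population", "Sum Sq"], 1e-20)
})

test_that("interaction model with a single-record population errors by name", {
  d <- toy_groups()
  d <- d[-(2:8), ]   # P1 left with one record
  d$x <- rnorm(nrow(d))
  expect_error(fit_trait_glm(d, "y", "x", include_interaction = TRUE), "P1")
})

test_that("Tukey p matches the studentized-range oracle on a balanced toy", {
  d <- toy_groups(seed = 4, k = 3, n = 10, delta = 0.8)
  fit <- fit_trait_glm(d, "y")
  tk <- tukey_hsd(fit)
  mse <- sum(resid(fit$fit)^2) / fit$fit$df.residual
  means <- tapply(d$y, d$population, mean)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    po <- tukey_p_oracle(means[pair[1]], means[pair[2]], 10, 10, mse,
                         k = 3, df = fit$fit$df.residual)
    expect_equal(tk$p[pair[1], pair[2]], po, tolerance = 1e-6)
  }
})

test_that("identical groups get Tukey p = 1; adjusted p >= unadjusted", {
  d <- toy_groups(seed = 5, k = 3, n = 6, delta = 1)
  d$y[d$population == "P2"] <- d$y[d$population == "P1"]  # identical samples
  fit <- fit_trait_glm(d, "y")
  tk <- tukey_hsd(fit)
  expect_equal(tk$p["P1", "P2"], 1, tolerance = 1e-9)
  # adjusted >= unadjusted everywhere
  mse <- sum(resid(fit$fit)^2) / fit$fit$df.residual
  means <- tapply(d$y, d$population, mean)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    tstat <- abs(means[pair[1]] - means[pair[2]]) / sqrt(mse * (2 / 6))
    p_unadj <- 2 * pt(tstat, fit$fit$df.residual, lower.tail = FALSE)
    expect_gte(tk$p[pair[1], pair[2]], p_unadj - 1e-12)
  }
})

test_that("LS-means equal raw means without covariate and match the ANCOVA hand oracle", {
  d <- toy_groups(seed = 6, k = 4, n = 7, delta = 1)
  fit <- fit_trait_glm(d, "y")
  lsm <- lsmeans_populations(fit)
  expect_equal(lsm$lsmean, as.numeric(tapply(d$y, d$population, mean)),
               tolerance = 1e-10)
  # 2 groups, 1 covariate: adjusted mean_i = ybar_i + b * (xbar - xbar_i)
  set.seed(7)
  d2 <- data.frame(population = rep(c("A", "B"), each = 10),
                   x = c(rnorm(10, 4), rnorm(10, 6)))
  d2$y <- 2 + 0.8 * d2$x + ifelse(d2$population == "B", 1.5, 0) + rnorm(20, 0, 0.3)
  fit2 <- fit_trait_glm(d2, "y", "x")
  b <- coef(fit2$fit)["x"]
  xbar <- mean(d2$x)
  hand <- vapply(c("A", "B"), function(g) {
    mean(d2$y[d2$population == g]) +
      b * (xbar - mean(d2$x[d2$population == g]))
  }, numeric(1))
  lsm2 <- lsmeans_populations(fit2)
  expect_equal(lsm2$lsmean, unname(hand), tolerance = 1e-8)
})

test_that("size_corrected returns unit-scale residuals and flags degeneracy", {
  set.seed(8)
  d <- data.frame(x = rnorm(50, 10), population = "A")
  d$y <- 3 + 2 * d$x + rnorm(50)
  sc <- size_corrected(d, "y", "x")
  expect_lt(abs(mean(sc)), 1e-10)
  expect_lt(abs(sd(sc) - 1), 1e-10)
  d$y2 <- 5 * d$x
  sc2 <- size_corrected(d, "y2", "x")
  expect_true(attr(sc2, "degenerate"))
  expect_true(all(sc2 == 0))
  d$cx <- 1
  expect_error(size_corrected(d, "y", "cx"), "constant covariate")
})

test_that("trait_correlation recovers exact and null relationships", {
  x <- rnorm(30)
  expect_equal(trait_correlation(x, -x)$r, -1)
  set.seed(9)
  r <- trait_correlation(x, sample(x))$r
  expect_lt(abs(r), 0.5)
  expect_error(trait_correlation(x, rep(1, 30)), "zero variance")
})

test_that("growth filter keeps the inclusive 5-19 window", {
  b <- data.frame(n_reared = c(4, 5, 19, 20))
  kept <- filter_growth_broods(b)
  expect_equal(kept$n_reared, c(5, 19))
  expect_equal(attr(kept, "n_retained"), 2L)
  expect_equal(attr(kept, "n_excluded"), 2L)
  e <- filter_growth_broods(b[0, , drop = FALSE])
  expect_equal(nrow(e), 0L)
  expect_equal(attr(e, "n_retained"), 0L)
})

test_that("brood growth is the difference of mean lengths", {
  b <- data.frame(fry_len_day0 = c(10, 10.5), fry_len_day35 = c(14.5, 15.2))
  expect_equal(brood_growth(b, 0, 35), c(4.5, 4.7))
  expect_equal(brood_growth(b[1, ], 0, 35), 4.5)
  expect_error(brood_growth(b, 0, 70), "day 70")
})

test_that("habitat contrast reproduces the two-group ANOVA on population means", {
  lsm <- data.frame(population = paste0("P", 1:8),
                    lsmean = c(5.2, 5.8, 6.1, 5.5, 7.2, 7.9, 6.8, 7.5))
  hab <- setNames(rep(c("lake", "peripheral"), each = 4), lsm$population)
  res <- habitat_contrast(lsm, hab)
  oracle <- oneway_F_oracle(lsm$lsmean, hab)
  expect_equal(res$F, oracle$F, tolerance = 1e-10)
  expect_equal(res$df1, 1L)
  expect_equal(res$df2, 6L)   # 8 populations - 2 classes
  # identical class means: F ~ 0
  lsm0 <- lsm; lsm0$lsmean <- rep(c(1, 2, 3, 4), 2)
  expect_lt(habitat_contrast(lsm0, hab)$F, 1e-20)
  expect_error(habitat_contrast(lsm[c(1, 5, 6), ], hab), ">= 2 populations")
  expect_error(habitat_contrast(lsm[1:3, ], hab), "2 habitat classes")
})
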