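counts2 <- function(nAA, nAB, nBB) {
  m <- matrix(0L, 2, 2)
  m[1, 1] <- nAA; m[2, 1] <- nAB; m[2, 2] <- nBB
  m
}

test_that("single-allele and single-table cases are degenerate with p = 1", {
  m <- matrix(0L, 2, 2); m[1, 1] <- 12L
  res <- hwe_exact_test(m, chain_steps = 1e3, dememorization = 100, seed = 1)
  expect_equal(res$p, 1)
  expect_true(res$degenerate)
  expect_equal(hwe_exact_enumeration(m)$p, 1)
})

test_that("enumeration matches the independent biallelic parity oracle", {
  cases <- list(c(3, 2, 5), c(10, 1, 9), c(0, 4, 6), c(7, 7, 6), c(1, 0, 19))
  for (cs in cases) {
    e <- hwe_exact_enumeration(counts2(cs[1], cs[2], cs[3]))
    expect_equal(e$p, hwe_p_biallelic_oracle(cs[1], cs[2], cs[3]),
                 tolerance = 1e-12)
    expect_equal(e$total_prob, 1, tolerance = 1e-9)  # Levene probs sum to 1
  }
})

test_that("chain p-values agree with enumeration on 2- and 3-allele tables", {
  for (cs in list(c(3, 2, 5), c(10, 1, 9), c(2, 8, 2))) {
    pm <- hwe_exact_test(counts2(cs[1], cs[2], cs[3]), chain_steps = 1e5,
                         dememorization = 1e4, seed = 11)$p
    pe <- hwe_p_biallelic_oracle(cs[1], cs[2], cs[3])
    expect_lt(abs(pm - pe), 0.02)
  }
  m3 <- matrix(0L, 3, 3)
  m3[1, 1] <- 2L; m3[2, 1] <- 3L; m3[2, 2] <- 1L
  m3[3, 1] <- 1L; m3[3, 2] <- 2L; m3[3, 3] <- 1L
  e3 <- hwe_exact_enumeration(m3)
  expect_equal(e3$total_prob, 1, tolerance = 1e-9)
  m3m <- hwe_exact_test(m3, chain_steps = 1e5, dememorization = 1e4,
                        seed = 12)
  expect_lt(abs(m3m$p - e3$p), 0.02)
  expect_gt(m3m$se, 0)
})

test_that("long-run chain frequencies match the conditional distribution", {
  # biallelic: the heterozygote count identifies the table, so a
  # goodness-of-fit test on its thinned long-run histogram checks the
  # chain's stationary distribution against Levene probabilities
  nAA <- 4L; nAB <- 4L; nBB <- 4L
  n <- nAA + nAB + nBB; nA <- 2 * nAA + nAB
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  lp <- vapply(hets, function(h) {
    naa <- (nA - h) / 2; nbb <- n - naa - h
    lgamma(n + 1) - lgamma(naa + 1) - lgamma(h + 1) - lgamma(nbb + 1) +
      h * log(2) + lgamma(nA + 1) + lgamma(2 * n - nA + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  probs <- exp(lp)
  set.seed(21)
  res <- qstfst:::hwe_chain_cpp(counts2(nAA, nAB, nBB), steps = 4e5,
                                demem = 2e4, batches = 100, thin = 50L)
  obs <- res$het_hist[hets + 1]
  expect_equal(sum(res$het_hist), sum(obs))  # no off-parity states visited
  chi <- sum((obs - sum(obs) * probs)^2 / (sum(obs) * probs))
  expect_gt(pchisq(chi, df = length(hets) - 1, lower.tail = FALSE), 0.01)
})

test_that("genotype count input validation", {
  expect_error(hwe_exact_test(matrix(-1L, 2, 2)), "non-negative")
  expect_error(hwe_exact_test(matrix(1L, 2, 3)), "square")
})
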