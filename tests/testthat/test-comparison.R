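test_that("perfect concordance and rank reversal are detected exactly", {
  set.seed(14)
  q <- random_dist_matrix(7)
  f_mono <- dist_matrix(unclass(q)^2, rownames(q))       # monotone transform
  r <- spearman_permutation(q, f_mono, n_perm = 999, seed = 1)
  expect_equal(r$rho, 1, tolerance = 1e-12)
  # only label permutations that re-create the perfect ranking tie the
  # observed rho, so p sits at the bottom of the permutation distribution
  expect_lt(r$p, 0.01)
  # rank reversal
  f_rev <- dist_matrix(max(q) - unclass(q), rownames(q))
  r2 <- spearman_permutation(q, f_rev, n_perm = 99, seed = 1)
  expect_equal(r2$rho, -1, tolerance = 1e-12)
})

test_that("reported rho equals a direct Spearman computation", {
  set.seed(15)
  q <- random_dist_matrix(6)
  f <- random_dist_matrix(6)
  r <- spearman_permutation(q, f, n_perm = 99, seed = 2)
  expect_equal(r$rho, spearman_oracle(lower_pairs(q), lower_pairs(f)),
               tolerance = 1e-12)
})

test_that("p is invariant to simultaneous relabeling of both matrices", {
  set.seed(16)
  q <- random_dist_matrix(6)
  f <- random_dist_matrix(6)
  r1 <- spearman_permutation(q, f, n_perm = 499, seed = 3)
  ord <- sample(6)
  labs <- rownames(q)
  q2 <- dist_matrix(unclass(q)[ord, ord], labs[ord])
  f2 <- dist_matrix(unclass(f)[ord, ord], labs[ord])
  r2 <- spearman_permutation(q2, f2, n_perm = 499, seed = 3)
  expect_equal(r2$rho, r1$rho, tolerance = 1e-12)
  expect_lt(abs(r2$p - r1$p), 0.1)  # same distribution, different draws
})

test_that("Monte-Carlo p converges to the exhaustive enumeration on 5 populations", {
  set.seed(17)
  q <- random_dist_matrix(5)
  f <- random_dist_matrix(5)
  pe <- spearman_permutation(q, f, exact = TRUE)$p
  pm <- spearman_permutation(q, f, n_perm = 19999, seed = 4)$p
  expect_lt(abs(pm - pe), 0.01)
})

test_that("pair-level permutation mode and error handling", {
  set.seed(18)
  q <- random_dist_matrix(5)
  f <- random_dist_matrix(5)
  r <- spearman_permutation(q, f, n_perm = 199, seed = 5, unit = "pairs")
  expect_true(r$p > 0 && r$p <= 1)
  expect_error(spearman_permutation(q, random_dist_matrix(5, paste0("X", 1:5)),
                                    n_perm = 99, seed = 1), "common")
  expect_error(spearman_permutation(random_dist_matrix(3),
                                    random_dist_matrix(3), n_perm = 99,
                                    seed = 1), "common")
  expect_error(spearman_permutation(q, f, n_perm = 99), "seed")
})

test_that("selection-regime classification follows the comparison rule", {
  expect_equal(classify_selection(0.5, 0.1, 0), "directional")
  expect_equal(classify_selection(0.1, 0.5, 0), "stabilizing")
  expect_equal(classify_selection(0.3, 0.3, 0.05), "indistinguishable")
  expect_equal(classify_selection(0.32, 0.3, 0.05), "indistinguishable")
  expect_equal(classify_selection(NA, 0.3, 0), "missing")
  expect_error(classify_selection(0.3, 0.3, -0.1), "tolerance")
})
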