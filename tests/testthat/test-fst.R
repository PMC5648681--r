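test_that("theta = 1 for populations fixed for different alleles", {
  al <- array(0L, dim = c(20, 3, 2))
  al[1:10, , ] <- 1L
  al[11:20, , ] <- 2L
  gt <- genotype_table(paste0("i", 1:20), rep(c("A", "B"), each = 10), al,
                       paste0("L", 1:3))
  expect_equal(global_fst(gt), 1)
  pf <- pairwise_fst(gt)
  expect_equal(pf["A", "B"], 1)
})

test_that("components match the hand-evaluated Weir-Cockerham formulas", {
  # 2 populations, 1 biallelic locus, small and fully enumerable by hand:
  # pop A: 3x AA, 2x AB, 1x BB; pop B: 1x AA, 1x AB, 4x BB
  gt <- make_gt(list(
    A = rbind(c(1, 1), c(1, 1), c(1, 1), c(1, 2), c(1, 2), c(2, 2)),
    B = rbind(c(1, 1), c(1, 2), c(2, 2), c(2, 2), c(2, 2), c(2, 2))))
  got <- wc_components(gt, 1)
  oracle <- wc_biallelic_oracle(n_i = c(6, 6), p_i = c(8 / 12, 3 / 12),
                                h_i = c(2 / 6, 1 / 6))
  expect_equal(unname(got), unname(oracle), tolerance = 1e-10)
  expect_equal(global_fst(gt), unname(oracle["a"] / sum(oracle)),
               tolerance = 1e-10)
})

test_that("theta is invariant to allele relabeling and population order", {
  gt <- simulate_genotypes(genotype_sim_spec(
    n_populations = 3, n_per_pop = 30, n_loci = 4, alleles_per_locus = 6,
    divergence_f = 0.15, seed = 17))
  th <- global_fst(gt)
  # relabel allele codes (reverse the code order) at every locus
  al <- gt$alleles
  al[al > 0L] <- 7L - al[al > 0L]
  gt_rel <- genotype_table(gt$ids, gt$pop, al, gt$loci)
  expect_equal(global_fst(gt_rel), th, tolerance = 1e-12)
  # permute population block order
  ord <- order(as.integer(gt$pop), decreasing = TRUE)
  gt_perm <- genotype_table(gt$ids[ord],
                            factor(gt$pop[ord], levels = rev(levels(gt$pop))),
                            gt$alleles[ord, , , drop = FALSE], gt$loci)
  expect_equal(global_fst(gt_perm), th, tolerance = 1e-12)
})

test_that("multilocus theta is the ratio of sums, not the mean of ratios", {
  # construct loci with very different information content so the two
  # aggregation rules differ materially
  gt <- make_gt(list(
    A = cbind(rbind(c(1, 1), c(1, 1), c(1, 1), c(1, 1), c(1, 2), c(2, 2)),
              rbind(c(1, 1), c(1, 1), c(1, 1), c(1, 1), c(1, 1), c(1, 2))),
    B = cbind(rbind(c(2, 2), c(2, 2), c(2, 2), c(2, 2), c(1, 2), c(1, 1)),
              rbind(c(1, 1), c(1, 2), c(1, 1), c(1, 1), c(1, 1), c(1, 1)))))
  comp <- vapply(1:2, function(j) wc_components(gt, j), c(a = 0, b = 0, c = 0))
  ratio_of_sums <- sum(comp["a", ]) / sum(comp)
  mean_of_ratios <- mean(comp["a", ] / colSums(comp))
  expect_false(isTRUE(all.equal(ratio_of_sums, mean_of_ratios,
                                tolerance = 1e-3)))
  expect_equal(global_fst(gt), ratio_of_sums, tolerance = 1e-12)
})

test_that("missing genotypes are excluded per locus; empty pops excluded", {
  gt <- make_gt(list(
    A = rbind(c(1, 1), c(1, 2), c(0, 0)),
    B = rbind(c(2, 2), c(1, 2), c(2, 2)),
    C = rbind(c(0, 0), c(0, 0), c(0, 0))))
  expect_warning(pf <- pairwise_fst(gt), "no genotyped individuals")
  expect_equal(dim(unclass(pf)), c(2L, 2L))
})

test_that("unbiased H_E estimator recovers truth from known frequencies", {
  # mean sample H_E over replicates from Dirichlet-free fixed frequencies
  p <- c(0.5, 0.3, 0.2)
  he_true <- 1 - sum(p^2)
  n <- 12
  set.seed(99)
  he <- replicate(400, {
    a1 <- sample.int(3, n, TRUE, p); a2 <- sample.int(3, n, TRUE, p)
    al <- array(0L, dim = c(n, 1, 2)); al[, 1, 1] <- a1; al[, 1, 2] <- a2
    gt <- genotype_table(paste0("i", 1:n), rep("A", n), al, "L1")
    het_stats(gt)$H_E
  })
  expect_lt(abs(mean(he) - he_true), 0.01)
})

test_that("heterozygosity closed forms on tiny samples", {
  gt <- make_gt(list(A = rbind(c(1, 1), c(2, 2))))
  h <- het_stats(gt)
  expect_equal(h$H_O, 0)
  expect_equal(h$H_E, (4 / 3) * 0.5, tolerance = 1e-12)
  gt2 <- make_gt(list(A = rbind(c(1, 2), c(1, 2))))
  h2 <- het_stats(gt2)
  expect_equal(h2$H_O, 1)
  expect_equal(h2$H_E, (4 / 3) * 0.5, tolerance = 1e-12)
  gt3 <- make_gt(list(A = rbind(c(1, 1), c(1, 1))))
  h3 <- het_stats(gt3)
  expect_equal(h3$H_O, 0)
  expect_equal(h3$H_E, 0)
  # empty cell reported as n = 0 with missing statistics
  gt4 <- make_gt(list(A = rbind(c(0, 0))))
  h4 <- het_stats(gt4)
  expect_equal(h4$n, 0L)
  expect_true(is.na(h4$H_O))
})
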