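test_that("genotype simulation hits its divergence target", {
  # no divergence: theta centred on 0
  th0 <- vapply(1:20, function(s) {
    global_fst(simulate_genotypes(genotype_sim_spec(
      n_populations = 2, n_per_pop = 200, n_loci = 7,
      alleles_per_locus = 10, divergence_f = 0, seed = s)))
  }, numeric(1))
  expect_lt(abs(mean(th0)), 0.01)
  # F = 0.10: mean multilocus theta near the Balding-Nichols target
  th <- vapply(1:30, function(s) {
    global_fst(simulate_genotypes(genotype_sim_spec(
      n_populations = 2, n_per_pop = 100, n_loci = 7,
      alleles_per_locus = 10, divergence_f = 0.10, seed = 100 + s)))
  }, numeric(1))
  expect_gt(mean(th), 0.07)
  expect_lt(mean(th), 0.13)
})

test_that("duplicating a population as a second sample gives theta ~ 0", {
  gt <- simulate_genotypes(genotype_sim_spec(
    n_populations = 1, n_per_pop = 200, n_loci = 7,
    alleles_per_locus = 10, divergence_f = 0.2, seed = 3))
  al2 <- array(0L, dim = c(400, 7, 2))
  al2[1:200, , ] <- gt$alleles
  al2[201:400, , ] <- gt$alleles
  dup <- genotype_table(paste0("i", 1:400), rep(c("A", "B"), each = 200),
                        al2, gt$loci)
  expect_lte(abs(global_fst(dup)), 0.005)
})

test_that("genotype simulation is reproducible and validates its spec", {
  s <- genotype_sim_spec(n_populations = 2, n_per_pop = 10, seed = 9)
  expect_identical(simulate_genotypes(s)$alleles, simulate_genotypes(s)$alleles)
  expect_error(genotype_sim_spec(divergence_f = 1), "divergence_f")
  expect_error(genotype_sim_spec(alleles_per_locus = 1), "alleles_per_locus")
  expect_error(genotype_sim_spec(missing_rate = 1), "missing_rate")
})

test_that("experiment design yields the configured number of families", {
  ex <- simulate_experiment(experiment_sim_spec(seed = 2))
  expect_equal(nrow(ex$broods), 8 * 4 * 4)   # 128 families
  expect_equal(length(unique(ex$broods$sire_id)), 8 * 4)
  expect_equal(nrow(ex$clutches), 8 * 16)
  # total egg investment is consistent with size x count
  expect_equal(ex$clutches$total_egg_mass,
               ex$clutches$clutch_size * ex$clutches$mean_egg_mass)
  # brood truncation at the cap
  expect_true(all(ex$broods$n_reared <= 32))
})

test_that("noise-free experiment collapses to the configured means", {
  ex <- simulate_experiment(experiment_sim_spec(
    v_pop = 0, v_male = 0, v_res = 0, tl_slope = 0, seed = 4))
  expect_true(all(ex$broods$incubation_days == 17))
  expect_true(all(ex$broods$brood_size == 18))
  expect_true(all(ex$broods$fry_len_day0 == 10.5))
  expect_true(all(ex$clutches$clutch_size == 35))
})

test_that("configured trade-off correlation is recovered", {
  ex <- simulate_experiment(experiment_sim_spec(
    n_populations = 5, clutches_per_pop = 100, tradeoff_rho = -0.9,
    seed = 6))
  sc <- size_corrected(ex$clutches, "clutch_size", "female_tl")
  r <- trait_correlation(sc, ex$clutches$mean_egg_mass)$r
  expect_gt(r, -0.95)
  expect_lt(r, -0.80)
})

test_that("experiment spec validation rejects impossible settings", {
  expect_error(experiment_sim_spec(v_res = -1), ">= 0")
  expect_error(experiment_sim_spec(tradeoff_rho = -1.5), "tradeoff_rho")
  expect_error(experiment_sim_spec(tradeoff_rho = 0.5), "trade-off")
  expect_error(experiment_sim_spec(brood_cap = 0), "brood_cap")
})

test_that("climate series is periodic baseline plus noise", {
  s0 <- climate_sim_spec(n_years = 3, noise_sd = c(temperature = 0,
                                                   precipitation = 0),
                         seed = 1)
  cl <- simulate_climate(s0)
  expect_equal(nrow(cl), 36)
  expect_equal(cl$temperature[1:12], cl$temperature[13:24])  # exact period 12
  # constant profile, no noise -> Colwell C = 1, M = 0
  sc <- climate_sim_spec(
    n_years = 3, monthly_profile = list(temperature = rep(20, 12)),
    noise_sd = c(temperature = 0), seed = 1)
  cw <- colwell_stats(simulate_climate(sc)$temperature)
  expect_equal(cw$C, 1)
  expect_equal(cw$M, 0)
  expect_error(climate_sim_spec(n_years = 0), "n_years")
})

test_that("seasonality raises predictability above an i.i.d. shuffle", {
  cl <- simulate_climate(climate_sim_spec(n_years = 15, seed = 8))
  p_seasonal <- colwell_stats(cl$temperature)$P
  set.seed(1)
  p_shuffled <- colwell_stats(sample(cl$temperature))$P
  expect_gt(p_seasonal, p_shuffled)
})
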