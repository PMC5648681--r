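#' Specification for a Balding-Nichols genotype simulation
#'
#' Defines a multi-population, multiallelic genotype simulation under the
#' Balding-Nichols model: ancestral allele frequencies are drawn from a
#' symmetric Dirichlet, and each population's frequencies from a Dirichlet
#' centred on the ancestral frequencies with concentration
#' `p * (1 - F) / F`, so the expected Weir-Cockerham divergence equals the
#' target `divergence_f`.  Genotypes are formed by random union of gametes
#' within populations, so Hardy-Weinberg proportions hold by construction.
#'
#' @param n_populations number of populations (>= 1).
#' @param n_per_pop diploid individuals per population.
#' @param n_loci number of loci.
#' @param alleles_per_locus alleles segregating per locus (>= 2).
#' @param divergence_f target divergence F in `[0, 1)`.
#' @param missing_rate fraction of genotypes set missing, in `[0, 1)`.
#' @param seed integer seed.
#' @return A list of class `genotype_sim_spec`.
#' @export
genotype_sim_spec <- function(n_populations = 7L, n_per_pop = 20L,
                              n_loci = 7L, alleles_per_locus = 10L,
                              divergence_f = 0.10, missing_rate = 0,
                              seed = 1L) {
  .assert_scalar_count(n_populations, "n_populations")
  .assert_scalar_count(n_per_pop, "n_per_pop")
  .assert_scalar_count(n_loci, "n_loci")
  if (alleles_per_locus < 2L) stop("'alleles_per_locus' must be >= 2")
  if (divergence_f < 0 || divergence_f >= 1)
    stop("'divergence_f' must be in [0, 1)")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("'missing_rate' must be in [0, 1)")
  structure(list(n_populations = as.integer(n_populations),
                 n_per_pop = as.integer(n_per_pop),
                 n_loci = as.integer(n_loci),
                 alleles_per_locus = as.integer(alleles_per_locus),
                 divergence_f = divergence_f,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "genotype_sim_spec")
}

.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Simulate genotypes under the Balding-Nichols model
#'
#' @param spec a [genotype_sim_spec].
#' @return A [genotype_table]; the spec used is attached as attribute
#'   `"sim_spec"`.
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "genotype_sim_spec"))
  set.seed(spec$seed)
  K <- spec$n_populations; n <- spec$n_per_pop
  L <- spec$n_loci; A <- spec$alleles_per_locus; F <- spec$divergence_f
  N <- K * n
  al <- array(0L, dim = c(N, L, 2L))
  for (j in seq_len(L)) {
    anc <- .rdirichlet1(rep(1, A))
    for (k in seq_len(K)) {
      pk <- if (F > 0) .rdirichlet1(anc * (1 - F) / F) else anc
      rows <- ((k - 1L) * n + 1L):(k * n)
      al[rows, j, 1] <- sample.int(A, n, replace = TRUE, prob = pk)
      al[rows, j, 2] <- sample.int(A, n, replace = TRUE, prob = pk)
    }
  }
  if (spec$missing_rate > 0) {
    miss <- matrix(runif(N * L) < spec$missing_rate, N, L)
    for (j in seq_len(L)) {
      al[miss[, j], j, 1] <- 0L
      al[miss[, j], j, 2] <- 0L
    }
  }
  pops <- factor(rep(paste0("Pop", seq_len(K)), each = n),
                 levels = paste0("Pop", seq_len(K)))
  ids <- paste0(rep(paste0("Pop", seq_len(K)), each = n), "_",
                rep(seq_len(n), K))
  gt <- genotype_table(ids, pops, al, paste0("Locus", seq_len(L)))
  attr(gt, "sim_spec") <- spec
  gt
}
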