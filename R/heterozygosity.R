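#' Observed and expected heterozygosity per population and locus
#'
#' Observed heterozygosity is the fraction of genotyped individuals carrying
#' two different alleles; expected heterozygosity is the unbiased
#' (small-sample corrected) gene diversity
#' `H_E = 2n/(2n-1) * (1 - sum(p_k^2))`, with sample allele frequencies
#' computed from genotyped individuals only.  Optionally attaches the exact
#' Hardy-Weinberg test p-value for each population x locus cell.
#'
#' @param gt a [genotype_table].
#' @param hwe logical; run [hwe_exact_test] per cell.
#' @param chain_steps,dememorization chain settings for the HWE test.
#' @param seed integer seed for the HWE chains (each cell gets a derived
#'   seed so results do not depend on evaluation order).
#' @return A data.frame with columns `population`, `locus`, `n`, `H_O`,
#'   `H_E` and `p_hwe` (`NA` when `hwe = FALSE`).  Cells with no genotyped
#'   individuals are reported with `n = 0` and `NA` statistics.
#' @export
het_stats <- function(gt, hwe = FALSE, chain_steps = 1e6,
                      dememorization = 1e5, seed = NULL) {
  pops <- levels(gt$pop)
  out <- expand.grid(population = pops, locus = gt$loci,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$n <- 0L; out$H_O <- NA_real_; out$H_E <- NA_real_; out$p_hwe <- NA_real_
  for (r in seq_len(nrow(out))) {
    p <- out$population[r]; lj <- match(out$locus[r], gt$loci)
    sel <- gt$pop == p
    a1 <- gt$alleles[sel, lj, 1]; a2 <- gt$alleles[sel, lj, 2]
    keep <- a1 > 0L & a2 > 0L
    n <- sum(keep)
    out$n[r] <- n
    if (n == 0L) next
    a1 <- a1[keep]; a2 <- a2[keep]
    out$H_O[r] <- mean(a1 != a2)
    pk <- tabulate(match(c(a1, a2), sort(unique(c(a1, a2)))))
    pk <- pk / (2 * n)
    out$H_E[r] <- if (n > 0) (2 * n / (2 * n - 1)) * (1 - sum(pk^2)) else NA
    if (n == 1L) out$H_E[r] <- 2 * (1 - sum(pk^2))  # 2n/(2n-1) = 2 at n = 1
    if (hwe) {
      cs <- if (is.null(seed)) NULL else
        derive_seed(seed, paste0("hwe:", p, ":", out$locus[r]))
      gc <- genotype_counts(gt, lj, which = which(sel))
      out$p_hwe[r] <- hwe_exact_test(gc, chain_steps = chain_steps,
                                     dememorization = dememorization,
                                     seed = cs)$p
    }
  }
  out
}
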