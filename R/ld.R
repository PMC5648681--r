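#' Genotypic linkage-disequilibrium permutation test for a locus pair
#'
#' Tests association between genotypes at two loci within each population
#' using the genotypic log-likelihood-ratio (G) statistic on the two-locus
#' genotype contingency table.  The null distribution is generated by
#' permuting one locus's genotypes among individuals within the population;
#' permutations are organised in batches so a Monte-Carlo standard error of
#' the p-value can be reported.  Per-population p-values are combined across
#' populations with Fisher's method (chi-square = -2 * sum(log p) on 2k df).
#'
#' @param gt a [genotype_table].
#' @param locus_pair length-2 vector of locus names or indices.
#' @param batches number of permutation batches.
#' @param iterations_per_batch permutations per batch.
#' @param dememorization initial permutations discarded before counting
#'   (kept for interface compatibility with the classic serial samplers;
#'   permutations here are independent draws).
#' @param seed optional integer seed.
#' @return A list of class `ld_test`: `per_population` data.frame
#'   (`population`, `n`, `G`, `p`, `se`, `skipped`), `fisher_chisq`,
#'   `fisher_df`, `fisher_p`.  Populations monomorphic at either locus (or
#'   with fewer than 2 doubly genotyped individuals) are skipped and noted.
#' @export
ld_test <- function(gt, locus_pair, batches = 100L,
                    iterations_per_batch = 1000L, dememorization = 1000L,
                    seed = NULL) {
  if (length(locus_pair) != 2L) stop("'locus_pair' must name two loci")
  j1 <- if (is.character(locus_pair[1])) match(locus_pair[1], gt$loci) else
    as.integer(locus_pair[1])
  j2 <- if (is.character(locus_pair[2])) match(locus_pair[2], gt$loci) else
    as.integer(locus_pair[2])
  if (anyNA(c(j1, j2))) stop("unknown locus in 'locus_pair'")
  if (!is.null(seed)) set.seed(seed)
  pops <- levels(gt$pop)
  res <- data.frame(population = pops, n = 0L, G = NA_real_, p = NA_real_,
                    se = NA_real_, skipped = TRUE)
  nperm <- as.integer(batches) * as.integer(iterations_per_batch)
  for (pi in seq_along(pops)) {
    sel <- gt$pop == pops[pi]
    a1 <- gt$alleles[sel, j1, 1]; a2 <- gt$alleles[sel, j1, 2]
    b1 <- gt$alleles[sel, j2, 1]; b2 <- gt$alleles[sel, j2, 2]
    keep <- a1 > 0L & b1 > 0L
    n <- sum(keep)
    res$n[pi] <- n
    if (n < 2L) next
    gA <- paste(pmin(a1, a2)[keep], pmax(a1, a2)[keep])
    gB <- paste(pmin(b1, b2)[keep], pmax(b1, b2)[keep])
    cA <- factor(gA); cB <- factor(gB)
    if (nlevels(cA) < 2L || nlevels(cB) < 2L) next  # monomorphic: skip
    res$skipped[pi] <- FALSE
    iA <- as.integer(cA); iB <- as.integer(cB)
    kA <- nlevels(cA); kB <- nlevels(cB)
    gstat <- function(ib) {
      tab <- tabulate((ib - 1L) * kA + iA, nbins = kA * kB)
      tab <- matrix(tab, kA, kB)
      e <- outer(rowSums(tab), colSums(tab)) / n
      nz <- tab > 0
      2 * sum(tab[nz] * log(tab[nz] / e[nz]))
    }
    G_obs <- gstat(iB)
    res$G[pi] <- G_obs
    for (d in seq_len(dememorization)) sample.int(n)  # discarded draws
    hits <- numeric(batches)
    for (b in seq_len(batches)) {
      h <- 0L
      for (it in seq_len(iterations_per_batch)) {
        if (gstat(iB[sample.int(n)]) >= G_obs - 1e-12) h <- h + 1L
      }
      hits[b] <- h
    }
    res$p[pi] <- (1 + sum(hits)) / (nperm + 1)
    bp <- hits / iterations_per_batch
    res$se[pi] <- if (batches > 1) sd(bp) / sqrt(batches) else NA_real_
  }
  used <- !res$skipped & !is.na(res$p)
  k <- sum(used)
  chisq <- if (k > 0) -2 * sum(log(res$p[used])) else NA_real_
  structure(list(
    per_population = res,
    fisher_chisq = chisq,
    fisher_df = 2L * k,
    fisher_p = if (k > 0) pchisq(chisq, df = 2 * k, lower.tail = FALSE)
               else NA_real_
  ), class = "ld_test")
}

#' @export
print.ld_test <- function(x, ...) {
  k <- sum(!x$per_population$skipped)
  cat(sprintf(
    "genotypic LD permutation test: %d population(s) tested, Fisher chi2 = %.3f (df %d), p = %.4g\n",
    k, x$fisher_chisq, x$fisher_df, x$fisher_p))
  invisible(x)
}
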