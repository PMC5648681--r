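#' Weir-Cockerham variance components for one locus
#'
#' Computes the among-population (a), among-individual-within-population (b)
#' and within-individual (c) variance components of Weir & Cockerham's (1984)
#' theta at one multiallelic locus, summed over alleles.  Populations with no
#' genotyped individuals at the locus are excluded.
#'
#' @param gt a [genotype_table].
#' @param locus locus name or index.
#' @return Numeric vector `c(a =, b =, c =)`, or all-`NA` when fewer than two
#'   populations have data at the locus.
#' @references Weir, B.S. & Cockerham, C.C. (1984) Estimating F-statistics
#'   for the analysis of population structure. Evolution 38:1358-1370.
#' @export
wc_components <- function(gt, locus) {
  af <- allele_frequencies(gt, locus)
  keep <- af$n > 0
  if (sum(keep) < 2L || sum(af$n) < 2L)
    return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  ni <- af$n[keep]
  freq <- af$freq[keep, , drop = FALSE]
  het <- af$het[keep, , drop = FALSE]
  r <- length(ni)
  nbar <- mean(ni)
  if (nbar <= 1) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  A <- B <- C <- 0
  for (k in seq_len(ncol(freq))) {
    p <- freq[, k]
    pbar <- sum(ni * p) / (r * nbar)
    s2 <- sum(ni * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * het[, k]) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    A <- A + a; B <- B + b; C <- C + cc
  }
  c(a = A, b = B, c = C)
}

#' Multilocus Weir-Cockerham theta (global F_ST)
#'
#' Estimates theta over all populations and loci as the ratio of sums of the
#' per-locus variance components: `sum(a) / sum(a + b + c)` (not the mean of
#' per-locus ratios).  Slightly negative estimates are possible (the
#' estimator is unbiased) and are reported unclipped.
#'
#' @param gt a [genotype_table].
#' @return Numeric theta estimate.
#' @export
global_fst <- function(gt) {
  if (nlevels(gt$pop) < 2L) stop("global_fst needs >= 2 populations")
  comp <- vapply(seq_along(gt$loci), function(j) wc_components(gt, j),
                 c(a = 0, b = 0, c = 0))
  comp <- comp[, !is.na(comp["a", ]), drop = FALSE]
  if (ncol(comp) == 0L) stop("no locus with data in >= 2 populations")
  sum(comp["a", ]) / sum(comp)
}

#' Pairwise Weir-Cockerham theta matrix
#'
#' Multilocus theta for every unordered population pair, as produced by the
#' standard population-genetics tools.  Populations with no genotyped
#' individuals at any locus are excluded with a warning.
#'
#' @param gt a [genotype_table].
#' @return A [dist_matrix] of pairwise theta values (diagonal 0).
#' @export
pairwise_fst <- function(gt) {
  pops <- levels(gt$pop)
  has_data <- vapply(pops, function(p) {
    any(gt$alleles[gt$pop == p, , 1] > 0L)
  }, logical(1))
  if (any(!has_data)) {
    warning("excluding populations with no genotyped individuals: ",
            paste(pops[!has_data], collapse = ", "))
    pops <- pops[has_data]
  }
  if (length(pops) < 2L) stop("pairwise_fst needs >= 2 populations with data")
  K <- length(pops)
  m <- matrix(0, K, K, dimnames = list(pops, pops))
  for (i in seq_len(K - 1L)) for (j in (i + 1L):K) {
    sub <- gt_subset(gt, gt$pop %in% c(pops[i], pops[j]))
    m[i, j] <- m[j, i] <- global_fst(sub)
  }
  dist_matrix(m, pops)
}
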