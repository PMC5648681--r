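#' Diploid genotype table
#'
#' The central container for multiallelic (microsatellite-style) genotypes:
#' individuals by loci, with a population label per individual.  Allele calls
#' are positive integer codes; 0 denotes a missing allele.  A genotype with
#' either allele missing is treated as entirely missing at that locus (the
#' conservative convention; GENEPOP dialects vary on half-called genotypes).
#'
#' @param ids character vector of individual identifiers.
#' @param pop factor (or vector coercible to factor) of population labels,
#'   one per individual.
#' @param alleles integer array of dimension `n_individuals x n_loci x 2`
#'   holding allele codes (`0` = missing).
#' @param loci character vector of locus names (length `n_loci`).
#' @return An object of class `genotype_table`.
#' @examples
#' al <- array(c(1L, 1L, 1L, 2L), dim = c(1, 2, 2))
#' gt <- genotype_table("ind1", "A", al, c("L1", "L2"))
#' @export
genotype_table <- function(ids, pop, alleles, loci) {
  ids <- as.character(ids)
  pop <- as.factor(pop)
  if (!is.array(alleles) || length(dim(alleles)) != 3L || dim(alleles)[3] != 2L)
    stop("'alleles' must be an n x n_loci x 2 array")
  storage.mode(alleles) <- "integer"
  n <- dim(alleles)[1]
  L <- dim(alleles)[2]
  if (length(ids) != n || length(pop) != n)
    stop("length of 'ids'/'pop' must match nrow of 'alleles'")
  if (length(loci) != L) stop("length of 'loci' must match ncol of 'alleles'")
  if (anyNA(alleles)) stop("allele codes must not be NA; use 0 for missing")
  if (any(alleles < 0L)) stop("allele codes must be non-negative")
  # missing propagation: one missing allele voids the genotype
  miss <- alleles[, , 1, drop = FALSE] == 0L | alleles[, , 2, drop = FALSE] == 0L
  alleles[, , 1][miss[, , 1]] <- 0L
  alleles[, , 2][miss[, , 1]] <- 0L
  if (any(table(pop) == 0L)) pop <- droplevels(pop)
  structure(
    list(ids = ids, pop = pop, alleles = alleles, loci = as.character(loci)),
    class = "genotype_table"
  )
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d individuals, %d loci, %d populations\n",
              length(x$ids), length(x$loci), nlevels(x$pop)))
  cat("  loci:", paste(x$loci, collapse = ", "), "\n")
  tab <- table(x$pop)
  cat("  populations:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) c(length(x$ids), length(x$loci))

#' Subset a genotype table by individuals
#'
#' @param gt a [genotype_table].
#' @param i logical or integer index over individuals.
#' @return A `genotype_table` with the selected individuals.
#' @export
gt_subset <- function(gt, i) {
  genotype_table(gt$ids[i], droplevels(gt$pop[i]),
                 gt$alleles[i, , , drop = FALSE], gt$loci)
}

#' Genotype counts at one locus for a set of individuals
#'
#' Tabulates unordered genotype counts at a single locus, dropping missing
#' genotypes.  Allele codes are mapped to consecutive indices.
#'
#' @param gt a [genotype_table].
#' @param locus locus name or index.
#' @param which optional logical/integer index of individuals (default all).
#' @return A symmetric integer matrix `n_alleles x n_alleles` of genotype
#'   counts (counts stored in the lower triangle including diagonal), with
#'   allele codes as dimnames.
#' @export
genotype_counts <- function(gt, locus, which = NULL) {
  j <- if (is.character(locus)) match(locus, gt$loci) else as.integer(locus)
  if (is.na(j) || j < 1L || j > length(gt$loci)) stop("unknown locus")
  a1 <- gt$alleles[, j, 1]
  a2 <- gt$alleles[, j, 2]
  if (!is.null(which)) { a1 <- a1[which]; a2 <- a2[which] }
  keep <- a1 > 0L & a2 > 0L
  a1 <- a1[keep]; a2 <- a2[keep]
  codes <- sort(unique(c(a1, a2)))
  k <- length(codes)
  m <- matrix(0L, k, k, dimnames = list(codes, codes))
  if (k == 0L) return(m)
  i1 <- match(pmax(a1, a2), codes)  # row >= col: lower triangle
  i2 <- match(pmin(a1, a2), codes)
  for (g in seq_along(i1)) m[i1[g], i2[g]] <- m[i1[g], i2[g]] + 1L
  m
}

#' Per-population sample allele frequencies at one locus
#'
#' @param gt a [genotype_table].
#' @param locus locus name or index.
#' @return A list with `freq` (populations x alleles matrix of sample allele
#'   frequencies), `n` (genotyped individuals per population) and `het`
#'   (populations x alleles matrix of observed heterozygote proportions
#'   involving each allele).
#' @export
allele_frequencies <- function(gt, locus) {
  j <- if (is.character(locus)) match(locus, gt$loci) else as.integer(locus)
  a1 <- gt$alleles[, j, 1]
  a2 <- gt$alleles[, j, 2]
  keep <- a1 > 0L & a2 > 0L
  codes <- sort(unique(c(a1[keep], a2[keep])))
  pops <- levels(gt$pop)
  fr <- matrix(0, length(pops), length(codes), dimnames = list(pops, codes))
  ht <- fr
  nn <- setNames(integer(length(pops)), pops)
  for (p in pops) {
    sel <- keep & gt$pop == p
    nn[p] <- sum(sel)
    if (nn[p] == 0L) next
    cnt <- tabulate(match(c(a1[sel], a2[sel]), codes), nbins = length(codes))
    fr[p, ] <- cnt / (2 * nn[p])
    hsel <- sel & a1 != a2
    for (kk in seq_along(codes)) {
      ht[p, kk] <- sum(hsel & (a1 == codes[kk] | a2 == codes[kk])) / nn[p]
    }
  }
  list(freq = fr, n = nn, het = ht, codes = codes)
}
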