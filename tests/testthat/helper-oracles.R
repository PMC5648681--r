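# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately written from first principles (closed
# forms, enumeration, brute force) so it shares no code path with the
# package implementations it checks.

# Levene exact HWE p-value for a biallelic locus by direct summation over
# heterozygote counts of matching parity.
hwe_p_biallelic_oracle <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nA <- 2 * nAA + nAB
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  lp <- vapply(hets, function(h) {
    naa <- (nA - h) / 2
    nbb <- n - naa - h
    lgamma(n + 1) - lgamma(naa + 1) - lgamma(h + 1) - lgamma(nbb + 1) +
      h * log(2) + lgamma(nA + 1) + lgamma(2 * n - nA + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  pr <- exp(lp)
  obs <- pr[match(nAB, hets)]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# Build a genotype_table from a per-population list of 2-column allele
# matrices (one locus) or n x (2*L) matrices.
make_gt <- function(pop_alleles, loci = NULL) {
  mats <- lapply(pop_alleles, as.matrix)
  L <- ncol(mats[[1]]) / 2
  if (is.null(loci)) loci <- paste0("L", seq_len(L))
  n_per <- vapply(mats, nrow, integer(1))
  N <- sum(n_per)
  al <- array(0L, dim = c(N, L, 2))
  row <- 0L
  for (m in mats) {
    for (i in seq_len(nrow(m))) {
      row <- row + 1L
      for (j in seq_len(L)) {
        al[row, j, 1] <- m[i, 2 * j - 1]
        al[row, j, 2] <- m[i, 2 * j]
      }
    }
  }
  pops <- rep(names(pop_alleles) %||% paste0("P", seq_along(mats)), n_per)
  genotype_table(paste0("ind", seq_len(N)), pops, al, loci)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hand evaluation of the Weir-Cockerham (1984) per-allele components for a
# single biallelic locus in r populations, straight from the printed
# definitions.
wc_biallelic_oracle <- function(n_i, p_i, h_i) {
  r <- length(n_i)
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  comp <- function(p, h) {
    pbar <- sum(n_i * p) / (r * nbar)
    s2 <- sum(n_i * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    c(a = a, b = b, c = hbar / 2)
  }
  comp(p_i, h_i) + comp(1 - p_i, h_i)  # summed over both alleles
}

# Brute-force one-way ANOVA F from group sums of squares.
oneway_F_oracle <- function(y, g) {
  g <- factor(g)
  gm <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  df1 <- nlevels(g) - 1
  df2 <- length(y) - nlevels(g)
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, p = pf(F, df1, df2, lower.tail = FALSE), df1 = df1, df2 = df2)
}

# Tukey-Kramer adjusted p for one pair, from the studentized range
# distribution directly.
tukey_p_oracle <- function(mi, mj, ni, nj, mse, k, df) {
  q <- abs(mi - mj) / sqrt(mse / 2 * (1 / ni + 1 / nj))
  unname(ptukey(q, nmeans = k, df = df, lower.tail = FALSE))
}

# Direct Spearman rho (rank then Pearson), independent of stats::cor's
# "spearman" branch.
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Random symmetric zero-diagonal labelled matrix.
random_dist_matrix <- function(K, labels = paste0("Pop", seq_len(K))) {
  m <- matrix(0, K, K)
  m[lower.tri(m)] <- runif(K * (K - 1) / 2)
  dist_matrix(m + t(m), labels)
}
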