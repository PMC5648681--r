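#' Exact test of Hardy-Weinberg proportions (Markov chain)
#'
#' Tests deviation from Hardy-Weinberg genotype proportions at one locus,
#' conditional on the observed allele counts, using a Markov chain over
#' genotype tables with genotype-switch proposals (the approach of the
#' classic exact-test implementations).  The p-value is the proportion of
#' visited tables whose conditional (Levene) probability is less than or
#' equal to that of the observed table; ties count as extreme.
#'
#' @param counts square integer matrix of genotype counts at one locus
#'   (allele i x allele j; upper- or lower-triangle storage both accepted,
#'   as from [genotype_counts]).
#' @param chain_steps number of post-dememorization chain steps.
#' @param dememorization number of burn-in steps discarded before counting.
#' @param seed optional integer seed for the chain.
#' @param batches number of batches for the Monte-Carlo standard error.
#' @return A list of class `hwe_test`: `p` (p-value), `se` (Monte-Carlo
#'   standard error), `method`, `degenerate` (`TRUE` when fewer than two
#'   alleles are present so only one table is attainable and `p = 1`).
#' @seealso [hwe_exact_enumeration] for the full-enumeration version usable
#'   on small tables.
#' @export
hwe_exact_test <- function(counts, chain_steps = 1e6, dememorization = 1e5,
                           seed = NULL, batches = 100L) {
  counts <- .check_gcounts(counts)
  k <- nrow(counts)
  n <- sum(counts)
  pres <- .alleles_present(counts)
  if (length(pres) < 2L || n < 2L) {
    return(structure(list(p = 1, se = 0, method = "mcmc", degenerate = TRUE),
                     class = "hwe_test"))
  }
  if (!is.null(seed)) set.seed(seed)
  res <- hwe_chain_cpp(counts, as.integer(chain_steps),
                       as.integer(dememorization), as.integer(batches))
  structure(list(p = res$p, se = res$se, method = "mcmc",
                 degenerate = isTRUE(res$degenerate)),
            class = "hwe_test")
}

#' Exact test of Hardy-Weinberg proportions (full enumeration)
#'
#' Enumerates every genotype table compatible with the observed allele
#' counts and sums the Levene conditional probabilities of all tables as
#' probable or less probable than the observed one.  Exact, but feasible
#' only for few alleles and small samples; the Markov-chain version
#' [hwe_exact_test] covers the general case.
#'
#' @inheritParams hwe_exact_test
#' @return A list of class `hwe_test` with `p`, `se = 0`,
#'   `method = "enumeration"`, `n_tables` and `degenerate`.
#' @export
hwe_exact_enumeration <- function(counts) {
  counts <- .check_gcounts(counts)
  pres <- .alleles_present(counts)
  if (length(pres) < 2L || sum(counts) < 2L) {
    return(structure(list(p = 1, se = 0, method = "enumeration",
                          degenerate = TRUE, n_tables = 1L),
                     class = "hwe_test"))
  }
  # collapse to present alleles
  cc <- .fold_lower(counts)[pres, pres, drop = FALSE]
  k <- nrow(cc)
  m <- .allele_margins(cc)
  n <- sum(cc)
  logC <- lgamma(n + 1) + sum(lgamma(m + 1)) - lgamma(2 * n + 1)
  logp_obs <- logC + .table_logscore(cc)

  logs <- numeric(0)
  tab <- matrix(0L, k, k)
  rec_cell <- function(i, r) {
    if (i > k) {
      if (all(r == 0L)) logs[[length(logs) + 1L]] <<- logC + .table_logscore(tab)
      return(invisible(NULL))
    }
    for (nii in 0:(r[i] %/% 2L)) {
      tab[i, i] <<- nii
      s <- r[i] - 2L * nii
      .distribute(i, i + 1L, s, r, nii)
    }
    tab[i, i] <<- 0L
    invisible(NULL)
  }
  .distribute <- function(i, j, s, r, nii) {
    if (j > k) {
      if (s == 0L) {
        r2 <- r; r2[i] <- 0L
        rec_cell(i + 1L, r2)
      }
      return(invisible(NULL))
    }
    hi <- max(0L, min(s, r[j]))
    for (nij in 0:hi) {
      tab[j, i] <<- nij
      r2 <- r; r2[j] <- r[j] - nij
      .distribute(i, j + 1L, s - nij, r2, nii)
    }
    tab[j, i] <<- 0L
    invisible(NULL)
  }
  rec_cell(1L, m)
  probs <- exp(logs)
  p <- sum(probs[logs <= logp_obs + 1e-12])
  structure(list(p = min(1, p), se = 0, method = "enumeration",
                 degenerate = FALSE, n_tables = length(logs),
                 total_prob = sum(probs)),
            class = "hwe_test")
}

#' @export
print.hwe_test <- function(x, ...) {
  cat(sprintf("HWE exact test (%s): p = %.4g", x$method, x$p))
  if (x$method == "mcmc") cat(sprintf(" (MC s.e. %.2g)", x$se))
  if (x$degenerate) cat("  [degenerate: < 2 alleles]")
  cat("\n")
  invisible(x)
}

# ---- internals ------------------------------------------------------------

.check_gcounts <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("'counts' must be square")
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("'counts' must hold non-negative integer genotype counts")
  storage.mode(counts) <- "integer"
  counts
}

.fold_lower <- function(counts) {
  k <- nrow(counts)
  out <- matrix(0L, k, k)
  for (i in seq_len(k)) for (j in seq_len(i)) {
    out[i, j] <- counts[i, j] + if (i != j) counts[j, i] else 0L
  }
  out
}

.allele_margins <- function(lower) {
  k <- nrow(lower)
  m <- integer(k)
  for (i in seq_len(k)) {
    m[i] <- 2L * lower[i, i] +
      sum(lower[i, seq_len(i - 1L)]) +
      if (i < k) sum(lower[(i + 1L):k, i]) else 0L
  }
  m
}

.alleles_present <- function(counts) {
  lower <- .fold_lower(counts)
  which(.allele_margins(lower) > 0L)
}

.table_logscore <- function(lower) {
  # H*log2 - sum lgamma(n_ij + 1) over the lower triangle
  k <- nrow(lower)
  H <- 0L; s <- 0
  for (i in seq_len(k)) for (j in seq_len(i)) {
    s <- s + lgamma(lower[i, j] + 1)
    if (i != j) H <- H + lower[i, j]
  }
  H * log(2) - s
}
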