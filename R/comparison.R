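#' Spearman rank permutation comparison of Q_ST and F_ST matrices
#'
#' Correlates the lower triangles of a pairwise Q_ST matrix and a pairwise
#' F_ST matrix by Spearman's rank correlation (ties mid-ranked) and
#' evaluates significance by permutation.  Because matrix cells are not
#' independent, the default permutation unit is the population label:
#' one matrix's rows and columns are jointly permuted (Mantel-style)
#' `n_perm` times.  A naive pair-level permutation (shuffling the pair
#' vector itself, anti-conservative for distance matrices) is available via
#' `unit = "pairs"` for comparison with generic rank-permutation tests.
#' The two-sided p-value is smoothed,
#' `p = (1 + #permutations with |rho| >= |rho_obs|) / (n_perm + 1)`, so it
#' is never exactly 0.  With `exact = TRUE` all label permutations are
#' enumerated instead (feasible for few populations).
#'
#' @param qst_mat,fst_mat [dist_matrix] objects sharing population labels.
#' @param n_perm number of permutations (ignored when `exact = TRUE`).
#' @param seed integer seed (required for reproducibility unless exact).
#' @param unit `"labels"` (Mantel-style, default) or `"pairs"`.
#' @param exact enumerate all label permutations (unit must be `"labels"`).
#' @param trait optional trait name carried into the result.
#' @param classify_tolerance tolerance for the per-pair selection-regime
#'   classification.
#' @return A list of class `matrix_comparison`: `trait`, `rho`, `p`,
#'   `n_perm`, `unit`, `n_pairs`, and `pairs` (data.frame with per-pair
#'   Q_ST, F_ST and classification).
#' @export
spearman_permutation <- function(qst_mat, fst_mat, n_perm = 9999L,
                                 seed = NULL,
                                 unit = c("labels", "pairs"),
                                 exact = FALSE, trait = NULL,
                                 classify_tolerance = 0) {
  unit <- match.arg(unit)
  labs <- rownames(qst_mat)
  if (is.null(labs) || is.null(rownames(fst_mat)))
    stop("matrices must carry population labels")
  common <- intersect(labs, rownames(fst_mat))
  if (length(common) < 4L)
    stop("need >= 4 common populations (>= 6 pairs)")
  q <- unclass(qst_mat)[common, common]
  f <- unclass(fst_mat)[common, common]
  K <- length(common)
  lt <- lower.tri(q)
  ok <- !is.na(q) & !is.na(f)   # listwise exclusion of missing pairs
  use <- lt & ok & t(ok)
  qv <- q[use]; fv <- f[use]
  if (length(qv) < 3L) stop("too few complete pairs")
  rho_obs <- cor(qv, fv, method = "spearman")

  rho_of_perm <- function(ord) {
    qp <- q[ord, ord]
    # pairs going missing under the permutation are dropped pairwise
    cor(qp[use], f[use], method = "spearman", use = "complete.obs")
  }
  if (exact) {
    if (unit != "labels") stop("exact enumeration applies to label permutations")
    perms <- .all_perms(K)
    rhos <- vapply(perms, rho_of_perm, numeric(1))
    # observed ordering is one of the enumerated permutations
    p <- mean(abs(rhos) >= abs(rho_obs) - 1e-12)
    n_used <- length(perms)
  } else {
    if (is.null(seed)) stop("'seed' is required for the permutation test")
    set.seed(seed)
    n_perm <- as.integer(n_perm)
    hits <- 0L
    if (unit == "labels") {
      for (b in seq_len(n_perm)) {
        r <- rho_of_perm(sample.int(K))
        if (abs(r) >= abs(rho_obs) - 1e-12) hits <- hits + 1L
      }
    } else {
      for (b in seq_len(n_perm)) {
        r <- cor(qv[sample.int(length(qv))], fv, method = "spearman")
        if (abs(r) >= abs(rho_obs) - 1e-12) hits <- hits + 1L
      }
    }
    p <- (1 + hits) / (n_perm + 1)
    n_used <- n_perm
  }
  idx <- which(use, arr.ind = TRUE)
  pairs <- data.frame(
    pop1 = common[idx[, 2]], pop2 = common[idx[, 1]],
    qst = q[use], fst = f[use], stringsAsFactors = FALSE)
  pairs$classification <- mapply(classify_selection, pairs$qst, pairs$fst,
                                 MoreArgs = list(tolerance = classify_tolerance))
  structure(list(trait = trait, rho = rho_obs, p = p, n_perm = n_used,
                 unit = unit, n_pairs = length(qv), pairs = pairs),
            class = "matrix_comparison")
}

#' @export
print.matrix_comparison <- function(x, ...) {
  cat(sprintf("Q_ST-F_ST comparison%s: Spearman rho = %.3f, p = %.4g (%s permutations: %d, pairs: %d)\n",
              if (is.null(x$trait)) "" else paste0(" [", x$trait, "]"),
              x$rho, x$p, x$unit, x$n_perm, x$n_pairs))
  cls <- table(x$pairs$classification)
  cat("  pair classifications:",
      paste(sprintf("%s %d", names(cls), as.integer(cls)), collapse = ", "),
      "\n")
  invisible(x)
}

.all_perms <- function(K) {
  if (K > 8L) stop("exact enumeration limited to 8 populations")
  out <- list(seq_len(1L))
  for (k in 2:K) {
    out <- unlist(lapply(out, function(p) {
      lapply(seq_len(k), function(pos) append(p, k, after = pos - 1L))
    }), recursive = FALSE)
  }
  out
}

#' Classify the selection regime of one population pair
#'
#' Compares quantitative divergence with neutral divergence for a pair:
#' `Q_ST > F_ST + tolerance` suggests divergence beyond neutral expectation
#' (directional selection); `F_ST > Q_ST + tolerance` suggests divergence
#' below neutral expectation (stabilizing selection); otherwise the two
#' are indistinguishable.
#'
#' @param qst_value,fst_value numeric values for the pair.
#' @param tolerance non-negative band within which the two are considered
#'   indistinguishable.
#' @return One of `"directional"`, `"stabilizing"`, `"indistinguishable"`,
#'   or `"missing"` when either value is `NA`.
#' @export
classify_selection <- function(qst_value, fst_value, tolerance = 0) {
  if (is.na(qst_value) || is.na(fst_value)) return("missing")
  if (tolerance < 0) stop("'tolerance' must be >= 0")
  if (qst_value > fst_value + tolerance) "directional"
  else if (fst_value > qst_value + tolerance) "stabilizing"
  else "indistinguishable"
}
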