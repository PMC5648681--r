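#' Correlation-matrix principal component analysis
#'
#' Shared PCA engine used for trait tables and site-level environmental
#' feature tables: variables are standardised (so the decomposition is of
#' the correlation matrix), and a fixed sign convention is applied so
#' results are reproducible across platforms — on each axis the
#' largest-magnitude loading is made positive.  Loadings with magnitude
#' above `flag_threshold` are flagged, the conventional cut-off for calling
#' a variable an important contributor to an axis.
#'
#' @param x numeric matrix or data.frame (rows = observations, columns =
#'   variables).
#' @param flag_threshold absolute-loading threshold for flagging.
#' @param scale. logical; standardise columns (correlation PCA, default).
#' @return A list of class `qf_pca`: `scores`, `loadings` (columns =
#'   components), `sdev`, `var_fraction`, `flagged` (logical matrix, same
#'   shape as `loadings`).
#' @export
pca_correlation <- function(x, flag_threshold = 0.4, scale. = TRUE) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("'x' must be numeric")
  if (nrow(x) < 3L) stop("PCA needs >= 3 rows")
  if (ncol(x) < 2L) stop("PCA needs >= 2 columns")
  sds <- apply(x, 2, sd)
  if (scale. && any(sds == 0))
    stop("constant column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  pc <- prcomp(x, center = TRUE, scale. = scale.)
  # sign convention: largest-magnitude loading on each axis positive
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x, loadings = pc$rotation, sdev = pc$sdev,
                 var_fraction = vf,
                 flagged = abs(pc$rotation) > flag_threshold),
            class = "qf_pca")
}

#' @export
print.qf_pca <- function(x, ...) {
  cat(sprintf("PCA: %d observations x %d variables\n",
              nrow(x$scores), nrow(x$loadings)))
  cat("variance fractions:",
      paste(sprintf("%.3f", x$var_fraction[seq_len(min(5, length(x$var_fraction)))]),
            collapse = " "), "\n")
  invisible(x)
}

#' Trait-table PCA with loading flags
#'
#' Correlation-matrix PCA of a table of (typically size-corrected residual)
#' trait values per brood or clutch, flagging loadings above 0.4 in
#' magnitude.
#'
#' @param residual_table numeric data.frame/matrix of traits.
#' @param flag_threshold absolute-loading flag threshold.
#' @return A `qf_pca` object (see [pca_correlation]).
#' @export
trait_pca <- function(residual_table, flag_threshold = 0.4) {
  pca_correlation(residual_table, flag_threshold = flag_threshold)
}

#' Environmental site-feature ordination
#'
#' Correlation-matrix PCA of the site x feature table from
#' [summarize_site]; constant feature columns are dropped with a warning
#' (sites cannot be separated by a feature that does not vary).
#'
#' @param site_features numeric data.frame/matrix, rows = sites.
#' @param flag_threshold absolute-loading flag threshold.
#' @return A `qf_pca` object.
#' @export
env_pca <- function(site_features, flag_threshold = 0.4) {
  x <- as.matrix(site_features)
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    warning("dropping constant feature(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  pca_correlation(x, flag_threshold = flag_threshold)
}

#' Genotype ordination (individual-level PCA)
#'
#' Ordination of individuals from their multilocus genotypes: each
#' individual is encoded as allele-dosage counts (0/1/2) over every
#' (locus, allele) combination, columns are mean-centred, missing genotypes
#' are imputed at the column mean, and the centred matrix is decomposed.
#' Scores are labelled by population for plotting.
#'
#' @param gt a [genotype_table].
#' @return A list of class `qf_pca` with `scores` (rows labelled by
#'   individual, with a `population` attribute column in `$population`),
#'   `loadings`, `sdev`, `var_fraction`.
#' @export
genotype_pca <- function(gt) {
  n <- length(gt$ids)
  if (n < 3L) stop("genotype_pca needs >= 3 individuals")
  cols <- list()
  for (j in seq_along(gt$loci)) {
    a1 <- gt$alleles[, j, 1]; a2 <- gt$alleles[, j, 2]
    codes <- sort(unique(c(a1[a1 > 0L], a2[a2 > 0L])))
    for (cd in codes) {
      v <- (a1 == cd) + (a2 == cd)
      v[a1 == 0L] <- NA
      cols[[paste0(gt$loci[j], ".", cd)]] <- v
    }
  }
  x <- do.call(cbind, cols)
  all_na <- colSums(!is.na(x)) == 0L
  if (any(all_na)) {
    warning("dropping all-missing column(s): ",
            paste(colnames(x)[all_na], collapse = ", "))
    x <- x[, !all_na, drop = FALSE]
  }
  mu <- colMeans(x, na.rm = TRUE)
  x <- sweep(x, 2, mu)
  x[is.na(x)] <- 0  # column mean after centring
  sv <- svd(x)
  d <- sv$d
  scores <- sv$u %*% diag(d, nrow = length(d))
  rownames(scores) <- gt$ids
  colnames(scores) <- paste0("PC", seq_along(d))
  loadings <- sv$v
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_along(d)))
  tot <- sum(d^2)
  vf <- if (tot > 0) d^2 / tot else rep(0, length(d))
  structure(list(scores = scores, loadings = loadings,
                 sdev = d / sqrt(max(1, n - 1)), var_fraction = vf,
                 population = gt$pop),
            class = "qf_pca")
}
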