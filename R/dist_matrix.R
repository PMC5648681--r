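#' Labelled symmetric distance matrix
#'
#' Container for population-by-population divergence matrices (pairwise
#' F_ST or pairwise Q_ST): symmetric, zero diagonal, population labels fixed
#' and recorded.  Missing entries (e.g. degenerate pairwise fits) are `NA`.
#'
#' @param m square numeric matrix.
#' @param labels population labels; defaults to `rownames(m)`.
#' @return An object of class `dist_matrix` (a labelled matrix).
#' @export
dist_matrix <- function(m, labels = rownames(m)) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  if (is.null(labels)) stop("population labels required")
  ok <- is.na(m) | is.na(t(m)) | abs(m - t(m)) < 1e-10
  if (!all(ok)) stop("matrix must be symmetric")
  diag(m) <- 0
  dimnames(m) <- list(labels, labels)
  class(m) <- c("dist_matrix", "matrix")
  m
}

#' @export
print.dist_matrix <- function(x, digits = 4, ...) {
  cat(sprintf("dist_matrix over %d populations\n", nrow(x)))
  print(round(unclass(x), digits))
  invisible(x)
}

#' Lower-triangle values of a distance matrix
#'
#' @param x a [dist_matrix].
#' @return Named numeric vector of the below-diagonal entries, names
#'   `"popA|popB"`.
#' @export
lower_pairs <- function(x) {
  idx <- which(lower.tri(x), arr.ind = TRUE)
  v <- x[idx]
  names(v) <- paste(rownames(x)[idx[, 2]], rownames(x)[idx[, 1]], sep = "|")
  v
}

#' Write / read a distance matrix as labelled TSV
#'
#' @param x a [dist_matrix].
#' @param path file path.
#' @return `path` (writer) or a `dist_matrix` (reader).
#' @export
write_dist_matrix <- function(x, path) {
  df <- data.frame(population = rownames(x), unclass(x),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dist_matrix
#' @export
read_dist_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  dist_matrix(m)
}
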