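#' Colwell's predictability, constancy and contingency
#'
#' Information-theoretic seasonality statistics for a monthly series
#' (Colwell 1974).  Values are binned into `n_bins` states; a contingency
#' table is formed with rows = months-of-year (12) and columns = state
#' bins.  With row totals X, column totals Y, grand total Z and Shannon
#' entropies `H(X)`, `H(Y)`, `H(XY)` (natural log, `0*log 0 = 0`):
#' constancy `C = 1 - H(Y)/log(n_bins)`, contingency
#' `M = (H(X) + H(Y) - H(XY))/log(n_bins)`, and predictability `P = C + M`.
#' The identity `P = C + M` is exact, and all three are base-invariant
#' because of the `log(n_bins)` normalisation.
#'
#' Binning follows the equal-width convention: `n_bins` intervals of equal
#' width spanning the observed range, the maximum value falling in the top
#' bin.  `binning = "frequency"` instead uses (approximately)
#' equal-frequency bins from sample quantiles, for sensitivity analysis.
#'
#' @param values numeric vector of monthly observations, in chronological
#'   order starting in month 1 (January); at least one full year.
#' @param n_bins number of state bins (>= 2), default 10.
#' @param binning `"width"` (equal-width, default) or `"frequency"`.
#' @param months optional integer vector of month-of-year (1-12) per
#'   observation, overriding the default assumption of complete years in
#'   order.
#' @return A list of class `colwell_stats`: `P`, `C`, `M`, `n_bins`,
#'   `degenerate` (`TRUE` for a constant series, which occupies a single
#'   state so `C = 1`, `M = 0`, `P = 1`).
#' @references Colwell, R.K. (1974) Predictability, constancy, and
#'   contingency of periodic phenomena. Ecology 55:1148-1153.
#' @export
colwell_stats <- function(values, n_bins = 10L, binning = c("width", "frequency"),
                          months = NULL) {
  binning <- match.arg(binning)
  values <- as.numeric(values)
  if (anyNA(values)) stop("'values' must not contain NA")
  if (length(values) < 12L) stop("need at least one full year of monthly data")
  if (n_bins < 2L) stop("'n_bins' must be >= 2")
  if (is.null(months)) {
    months <- rep_len(1:12, length(values))
  } else if (length(months) != length(values) || !all(months %in% 1:12)) {
    stop("'months' must give a month in 1..12 for every observation")
  }
  rng <- range(values)
  degenerate <- rng[1] == rng[2]
  if (degenerate) {
    bin <- rep(1L, length(values))
  } else if (binning == "width") {
    w <- (rng[2] - rng[1]) / n_bins
    bin <- pmin(floor((values - rng[1]) / w) + 1L, n_bins)
  } else {
    br <- unique(quantile(values, probs = seq(0, 1, length.out = n_bins + 1)))
    bin <- findInterval(values, br, rightmost.closed = TRUE, all.inside = TRUE)
  }
  N <- table(factor(months, levels = 1:12), factor(bin, levels = seq_len(n_bins)))
  Z <- sum(N)
  X <- rowSums(N); Y <- colSums(N)
  ent <- function(w) { w <- w[w > 0] / Z; -sum(w * log(w)) }
  HX <- ent(X); HY <- ent(Y); HXY <- ent(as.vector(N))
  lk <- log(n_bins)
  C <- 1 - HY / lk
  M <- (HX + HY - HXY) / lk
  structure(list(P = C + M, C = C, M = M, n_bins = as.integer(n_bins),
                 degenerate = degenerate),
            class = "colwell_stats")
}

#' @export
print.colwell_stats <- function(x, ...) {
  cat(sprintf("Colwell statistics (%d bins): P = %.3f, C = %.3f, M = %.3f%s\n",
              x$n_bins, x$P, x$C, x$M,
              if (x$degenerate) "  [degenerate: constant series]" else ""))
  invisible(x)
}

#' Site-level environmental feature vector
#'
#' Summarises a site's monthly series (per variable: max, min, mean, and
#' Colwell C, M, P) together with categorical site descriptors coded 0/1
#' (water flow, proximity to deep water) and altitude — the feature set
#' used for environmental ordination of sampling sites.
#'
#' @param series a `climate_series` data.frame (columns `site`, `year`,
#'   `month`, plus one column per variable), for a single site.
#' @param flow logical/0-1: flowing water at the site.
#' @param deep_water logical/0-1: site close (< 1 km) to water deeper than
#'   20 m.
#' @param altitude site altitude (m).
#' @param n_bins bins for the Colwell statistics.
#' @return A named numeric vector: for each variable `<var>_max`,
#'   `<var>_min`, `<var>_mean`, `<var>_C`, `<var>_M`, `<var>_P`, then
#'   `flow`, `deep_water`, `altitude`.
#' @export
summarize_site <- function(series, flow, deep_water, altitude, n_bins = 10L) {
  vars <- setdiff(colnames(series), c("site", "year", "month"))
  if (length(vars) == 0L) stop("no environmental variables in 'series'")
  if (length(unique(series$site)) > 1L)
    stop("'series' must contain a single site")
  out <- numeric(0)
  for (v in vars) {
    x <- series[[v]]
    if (anyNA(x)) stop("variable '", v, "' contains missing values")
    cw <- colwell_stats(x, n_bins = n_bins, months = series$month)
    f <- c(max(x), min(x), mean(x), cw$C, cw$M, cw$P)
    names(f) <- paste0(v, "_", c("max", "min", "mean", "C", "M", "P"))
    out <- c(out, f)
  }
  c(out, flow = as.numeric(flow), deep_water = as.numeric(deep_water),
    altitude = as.numeric(altitude))
}
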