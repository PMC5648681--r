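#' Variance components of the nested half-sib model
#'
#' Builds a `variance_components` object: between-population variance
#' `V_b`, between-sire-within-population variance `V_male`, residual
#' variance `V_res`, and the derived within-population variance
#' `V_w = V_male + V_res` (the within-population variance used for Q_ST is
#' the sire variance added to the residual variance).
#'
#' @param V_b,V_male,V_res non-negative variance components (trait units^2).
#' @param method estimation method label.
#' @param boundary named logical: which components were truncated at the
#'   zero boundary.
#' @param degenerate logical: all observations identical (zero total
#'   variance).
#' @param converged logical: did the optimiser converge.
#' @return A list of class `variance_components`.
#' @export
variance_components <- function(V_b, V_male, V_res, method = "manual",
                                boundary = c(V_b = FALSE, V_male = FALSE,
                                             V_res = FALSE),
                                degenerate = FALSE, converged = TRUE) {
  if (any(c(V_b, V_male, V_res) < 0))
    stop("variance components must be >= 0")
  structure(list(V_b = V_b, V_male = V_male, V_res = V_res,
                 V_w = V_male + V_res, method = method,
                 boundary = boundary, degenerate = degenerate,
                 converged = converged),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("variance components (%s): V_b = %.4g, V_male = %.4g, V_res = %.4g (V_w = %.4g)\n",
              x$method, x$V_b, x$V_male, x$V_res, x$V_w))
  if (any(x$boundary)) cat("  at zero boundary:",
                           paste(names(x$boundary)[x$boundary], collapse = ", "),
                           "\n")
  if (x$degenerate) cat("  [degenerate: zero total variance]\n")
  invisible(x)
}

#' Fit the nested random-effects model of a half-sib common-garden design
#'
#' REML fit of the two-level nested random-intercept model
#' `trait ~ (1 | population) + (1 | sire)` with an optional fixed covariate
#' (e.g. female total length, or log10 rearing density), via `lme4::lmer`.
#' Components estimated at the zero boundary are reported as 0 with a
#' boundary flag.  When the REML fit fails or does not converge, a
#' method-of-moments fallback (unbalanced nested ANOVA, Henderson-style
#' expected mean squares) is used and flagged; it is also available
#' directly with `method = "moments"`.
#'
#' @param records data.frame with columns `population`, `sire_id`, the
#'   response, and the covariate if any.
#' @param response name of the trait column.
#' @param covariate optional name of a numeric covariate column, entered as
#'   a fixed effect (`adjust = "model"`, default) or removed by prior
#'   residualisation (`adjust = "residualize"`, for sensitivity checks).
#' @param method `"reml"` (default) or `"moments"`.
#' @param adjust covariate handling, see above.
#' @return A [variance_components] object.
#' @export
fit_nested_ranef <- function(records, response, covariate = NULL,
                             method = c("reml", "moments"),
                             adjust = c("model", "residualize")) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  for (col in c("population", "sire_id", response, covariate)) {
    if (!col %in% names(records)) stop("records lack column '", col, "'")
  }
  df <- data.frame(y = records[[response]],
                   population = factor(records$population),
                   sire = factor(paste(records$population, records$sire_id,
                                       sep = ":")))
  if (!is.null(covariate)) df$x <- records[[covariate]]
  df <- df[complete.cases(df), , drop = FALSE]
  df$population <- droplevels(df$population)
  df$sire <- droplevels(df$sire)
  if (nlevels(df$population) < 2L)
    stop("fit_nested_ranef needs >= 2 populations")
  if (var(df$y) == 0) {
    return(variance_components(0, 0, 0, method = method,
                               boundary = c(V_b = TRUE, V_male = TRUE,
                                            V_res = TRUE),
                               degenerate = TRUE))
  }
  if (!is.null(covariate) && adjust == "residualize") {
    df$y <- resid(lm(y ~ x, data = df))
    df$x <- NULL
  }
  use_cov <- "x" %in% names(df)
  if (method == "reml") {
    fm <- if (use_cov) y ~ x + (1 | population) + (1 | sire) else
      y ~ (1 | population) + (1 | sire)
    ctl <- lme4::lmerControl(
      check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4),
      check.nobs.vs.nlev = "ignore", check.nobs.vs.rankZ = "ignore",
      check.nlev.gtreq.5 = "ignore", calc.derivs = FALSE)
    fit <- tryCatch(
      suppressWarnings(suppressMessages(
        lme4::lmer(fm, data = df, REML = TRUE, control = ctl))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      vc <- as.data.frame(lme4::VarCorr(fit))
      vb <- vc$vcov[vc$grp == "population"]
      vm <- vc$vcov[vc$grp == "sire"]
      vr <- vc$vcov[vc$grp == "Residual"]
      conv <- length(fit@optinfo$conv$lme4) == 0L
      if (conv) {
        # components vanishing relative to the total variance sit on the
        # zero boundary: report as exact zeros with a flag
        thr <- 1e-8 * max(vb + vm + vr, .Machine$double.xmin)
        atb <- c(V_b = vb <= thr, V_male = vm <= thr, V_res = vr <= thr)
        return(variance_components(
          max(0, vb) * !atb[[1]], max(0, vm) * !atb[[2]],
          max(0, vr) * !atb[[3]], method = "reml", boundary = atb))
      }
    }
    method <- "moments"  # fallback, flagged via the method label
  }
  ## method-of-moments: unbalanced nested random ANOVA
  if (use_cov) df$y <- resid(lm(y ~ x, data = df))
  yb <- mean(df$y)
  N <- nrow(df)
  a <- nlevels(df$population)
  Ni <- tapply(df$y, df$population, length)
  ybar_i <- tapply(df$y, df$population, mean)
  nij <- tapply(df$y, df$sire, length)
  ybar_ij <- tapply(df$y, df$sire, mean)
  sire_pop <- sub(":.*$", "", names(nij))
  b_tot <- nlevels(df$sire)
  SSp <- sum(Ni * (ybar_i - yb)^2)
  SSs <- sum(nij * (ybar_ij - ybar_i[sire_pop])^2)
  SSw <- sum((df$y - ybar_ij[as.character(df$sire)])^2)
  dfp <- a - 1L; dfs <- b_tot - a; dfw <- N - b_tot
  MSw <- if (dfw > 0) SSw / dfw else 0
  MSs <- if (dfs > 0) SSs / dfs else MSw
  MSp <- SSp / dfp
  sum_nij2_by_pop <- tapply(nij^2, sire_pop, sum)[names(Ni)]
  k1 <- (N - sum(sum_nij2_by_pop / Ni)) / max(1L, dfs)
  k2 <- (sum(sum_nij2_by_pop / Ni) - sum(nij^2) / N) / dfp
  k3 <- (N - sum(Ni^2) / N) / dfp
  vr <- max(0, MSw)
  vm <- if (dfs > 0 && k1 > 0) max(0, (MSs - MSw) / k1) else 0
  vb <- max(0, (MSp - vr - k2 * vm) / k3)
  variance_components(vb, vm, vr, method = "moments",
                      boundary = c(V_b = vb == 0, V_male = vm == 0,
                                   V_res = vr == 0))
}

#' Q_ST from variance components
#'
#' The quantitative-genetic divergence statistic
#' `Q_ST = V_b / (2 * V_w + V_b)`, where `V_b` is the between-population
#' variance and `V_w` the within-population variance (sire variance plus
#' residual variance in the half-sib design).
#'
#' @param vc a [variance_components] object, or a list/vector with `V_b`
#'   and either `V_w` or both `V_male` and `V_res`.
#' @return Q_ST in `[0, 1]`.
#' @export
qst <- function(vc) {
  vb <- vc[["V_b"]]
  vw <- if (!is.null(vc[["V_w"]])) vc[["V_w"]] else
    vc[["V_male"]] + vc[["V_res"]]
  if (is.null(vb) || is.null(vw)) stop("need V_b and V_w (or V_male + V_res)")
  if (vb < 0 || vw < 0) stop("variance components must be >= 0")
  if (vb == 0 && vw == 0)
    stop("Q_ST undefined: all variance components are zero")
  vb / (2 * vw + vb)
}

#' Pairwise Q_ST matrix
#'
#' Computes Q_ST for every unordered population pair by refitting the
#' nested model on that pair's records only (`method = "subset"`, the
#' default), or by combining the global model's within-population variance
#' with pairwise between-population variance from the global fit's
#' population effects (`method = "global"`, offered for sensitivity since
#' the pairwise construction is a genuine modelling choice).  Pairs whose
#' fit is degenerate are reported `NA`.
#'
#' @inheritParams fit_nested_ranef
#' @param method `"subset"` (pair-subset refits) or `"global"`.
#' @return A [dist_matrix] of pairwise Q_ST values.
#' @export
pairwise_qst <- function(records, response, covariate = NULL,
                         method = c("subset", "global")) {
  method <- match.arg(method)
  pops <- levels(factor(records$population))
  K <- length(pops)
  if (K < 2L) stop("pairwise_qst needs >= 2 populations")
  m <- matrix(NA_real_, K, K, dimnames = list(pops, pops))
  diag(m) <- 0
  if (method == "subset") {
    for (i in seq_len(K - 1L)) for (j in (i + 1L):K) {
      sub <- records[records$population %in% c(pops[i], pops[j]), ,
                     drop = FALSE]
      q <- tryCatch({
        vc <- fit_nested_ranef(sub, response, covariate)
        if (vc$degenerate) NA_real_ else qst(vc)
      }, error = function(e) NA_real_)
      m[i, j] <- m[j, i] <- q
    }
  } else {
    vc <- fit_nested_ranef(records, response, covariate)
    # pairwise V_b from the two populations' mean deviation, shared V_w
    pm <- tapply(records[[response]], factor(records$population), mean,
                 na.rm = TRUE)
    for (i in seq_len(K - 1L)) for (j in (i + 1L):K) {
      vb_pair <- (pm[pops[i]] - pm[pops[j]])^2 / 2
      m[i, j] <- m[j, i] <- if (vb_pair == 0 && vc$V_w == 0) NA_real_ else
        vb_pair / (2 * vc$V_w + vb_pair)
    }
  }
  dist_matrix(m, pops)
}
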